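# Configuration and end-to-end orchestration of the analysis pipeline.

#' Analysis configuration
#'
#' Builds (and validates) the configuration driving [run_analysis()].
#' Defaults are the standard criteria of the structural analysis:
#' H-bonds at D...A <= 3.5 A and D-H...A >= 150 degrees, contacts at
#' 5.4 / 4.6 A (C-C / other), pi-pi centroid cutoff 6.5 A with pattern
#' band edges at 6.5 and 8.0 A, free-energy landscapes at 300 K, and the
#' final half of the trajectory frames as the statistics window.
#'
#' @param structure path to a structure file, or an `xtal`.
#' @param trajectory optional path to a multi-frame XYZ trajectory (or a
#'   [trajectory()]).
#' @param supercell integer triple.
#' @param axis helix axis (`NULL` = crystallographic c).
#' @param hbond,contact criteria objects.
#' @param pipi_cutoff,pipi_bands pi-pi centroid cutoff and classification
#'   band edges `c(I_max, II_max, III_min)`, Angstrom.
#' @param fel_bins `c(distance_bins, angle_bins)` for the landscape.
#' @param temperature Kelvin.
#' @param window frame window `c(first, last)` or `NULL` for the final
#'   half.
#' @param group_table group table data.frame, or path to a YAML file, or
#'   `NULL` for the packaged cyclo-WP defaults.
#' @param out_dir output directory (`NULL`: no files written).
#' @param seed integer seed recorded in the report.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(structure, trajectory = NULL,
                            supercell = c(1L, 1L, 1L), axis = NULL,
                            hbond = hbond_criteria(),
                            contact = contact_criteria(),
                            pipi_cutoff = 6.5, pipi_bands = c(6.5, 8.0, 8.0),
                            fel_bins = c(40L, 30L), temperature = 300,
                            window = NULL, group_table = NULL,
                            out_dir = NULL, seed = 1L) {
  stopifnot(inherits(hbond, "hbond_criteria"), inherits(contact, "contact_criteria"),
            length(supercell) == 3L, pipi_cutoff > 0, temperature > 0)
  if (is.character(group_table)) group_table <- read_group_table(group_table)$groups
  if (is.null(group_table)) group_table <- default_group_table()
  structure(list(structure = structure, trajectory = trajectory,
                 supercell = as.integer(supercell), axis = axis,
                 hbond = hbond, contact = contact,
                 pipi_cutoff = pipi_cutoff, pipi_bands = pipi_bands,
                 fel_bins = fel_bins, temperature = temperature,
                 window = window, group_table = group_table,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full structural analysis
#'
#' Orchestrates the pipeline: read structure, build the supercell, assign
#' groups and layers, detect H-bonds (per crystal unit), trace strands and
#' classify the supramolecular twist, fit helices, measure inner
#' diameters, detect and classify pi-pi stacking, build the stacking
#' free-energy landscape, and (when a trajectory is given) contact maps
#' and the RMSD series over the configured window. Writes TSV/JSON
#' outputs under `config$out_dir` when set.
#'
#' @param config an [analysis_config()].
#' @return list of class `analysis_report` with elements `structure`
#'   (atom/cell summary), `chirality` (a `triple_helix_metrics`),
#'   `hbonds`, `hbonds_per_unit`, `pipi` (classified pairs),
#'   `pipi_per_unit`, `fel`, `contacts` (trajectory only), `rmsd`
#'   (trajectory only), `config`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  log_stage <- function(...) message("[cyclohelix] ", ...)
  s <- config$structure
  if (is.character(s)) {
    log_stage("reading structure: ", s)
    s <- read_structure(s)
  }
  stopifnot(is_xtal(s))
  if (any(config$supercell != 1L)) {
    log_stage("building ", paste(config$supercell, collapse = "x"), " supercell")
    s <- build_supercell(s, config$supercell)
  }
  groups <- suppressWarnings(assign_groups(s, config$group_table))
  log_stage("atoms: ", nrow(s$atoms), ", molecules: ",
            length(unique(s$atoms$molecule_id)), ", n_cells: ", s$n_cells)

  chir <- tryCatch(
    triple_helix_metrics(s, axis = config$axis,
                         group_table = config$group_table,
                         criteria = config$hbond),
    error = function(e) {
      log_stage("chirality stage failed: ", conditionMessage(e),
                " (check layer/strand settings)")
      NULL
    })
  hb <- if (!is.null(chir)) chir$hbonds else detect_hbonds(s, config$hbond)
  log_stage("H-bonds: ", nrow(hb), " (", signif(per_unit(nrow(hb), s$n_cells), 4),
            " per crystal unit)")

  rings <- tryCatch(suppressWarnings(find_rings(s)), error = function(e) NULL)
  pipi <- NULL; fel <- NULL
  if (!is.null(rings) && nrow(rings) >= 2L) {
    pipi <- detect_pipi(rings, s$cell, cutoff = config$pipi_cutoff)
    if (!is.null(chir) && nrow(pipi)) {
      membership <- strand_membership(chir$strands)
      if (all(as.character(c(pipi$molecule_a, pipi$molecule_b)) %in% names(membership))) {
        pipi <- classify_pipi(pipi, membership,
                              band_I_max = config$pipi_bands[1],
                              band_II_max = config$pipi_bands[2],
                              band_III_min = config$pipi_bands[3])
      }
    }
    if (nrow(pipi)) {
      fel <- free_energy_landscape(
        pipi[, c("centroid_distance", "interplanar_angle")],
        distance_breaks = config$fel_bins[1], angle_breaks = config$fel_bins[2],
        temperature = config$temperature)
    }
    log_stage("pi-pi pairs: ", if (is.null(pipi)) 0L else nrow(pipi))
  }

  contacts <- NULL; rmsd <- NULL
  traj <- config$trajectory
  if (!is.null(traj)) {
    if (is.character(traj)) {
      log_stage("reading trajectory: ", traj)
      traj <- read_trajectory(traj, topology = s)
    }
    log_stage("trajectory: ", n_frames(traj), " frame(s)")
    contacts <- contact_map(traj, s, groups, config$contact, window = config$window)
    rmsd <- rmsd_series(traj)
  }

  report <- structure(list(
    structure = list(n_atoms = nrow(s$atoms),
                     n_molecules = length(unique(s$atoms$molecule_id)),
                     n_cells = s$n_cells,
                     cell = unclass(s$cell)[c("a", "b", "c", "alpha", "beta", "gamma")],
                     provenance = s$provenance),
    chirality = chir,
    hbonds = hb,
    hbonds_per_unit = per_unit(nrow(hb), s$n_cells),
    pipi = pipi,
    pipi_per_unit = if (is.null(pipi)) NA_real_ else per_unit(nrow(pipi), s$n_cells),
    fel = fel,
    contacts = contacts,
    rmsd = rmsd,
    config = config
  ), class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

strand_membership <- function(strands) {
  out <- integer(0)
  for (k in seq_along(strands$strands)) {
    out[as.character(strands$strands[[k]])] <- strands$helix_id[k]
  }
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("cyclohelix analysis report\n")
  cat(sprintf("  atoms %d, molecules %d, n_cells %d\n", x$structure$n_atoms,
              x$structure$n_molecules, x$structure$n_cells))
  if (!is.null(x$chirality)) {
    cat(sprintf("  twist %s (slope %.2f deg/layer), pitch %.3f A, inner diameter %.3f A\n",
                x$chirality$twist$verdict, x$chirality$twist$slope,
                x$chirality$pitch, x$chirality$inner_diameter))
  }
  cat(sprintf("  H-bonds %d (%.3f per unit)\n", nrow(x$hbonds), x$hbonds_per_unit))
  if (!is.null(x$pipi)) cat(sprintf("  pi-pi pairs %d\n", nrow(x$pipi)))
  invisible(x)
}

# machine-readable outputs: report.json + per-table TSVs
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(d, name) {
    if (is.null(d) || !nrow(d)) return(invisible(NULL))
    d <- d[, !vapply(d, is.list, logical(1)), drop = FALSE]
    utils::write.table(d, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wtsv(report$hbonds, "hbonds.tsv")
  wtsv(report$pipi, "pipi.tsv")
  ch <- report$chirality
  if (!is.null(ch) && !is.null(ch$profile)) wtsv(ch$profile, "rotation_profile.tsv")
  if (!is.null(report$fel)) {
    g <- report$fel
    grid <- expand.grid(distance = head_mids(g$distance_breaks),
                        angle = head_mids(g$angle_breaks))
    grid$P <- as.vector(g$P)
    grid$G <- as.vector(g$G)
    utils::write.table(grid, file.path(out_dir, "fel.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$contacts)) {
    utils::write.table(as.data.frame(report$contacts$probability),
                       file.path(out_dir, "contacts.tsv"), sep = "\t", quote = FALSE)
  }
  summary <- list(
    structure = report$structure,
    twist = if (!is.null(ch)) list(verdict = ch$twist$verdict,
                                   slope_deg_per_layer = ch$twist$slope,
                                   pitch_A = ch$pitch,
                                   strand_radius_A = ch$radius,
                                   diameter_axis_A = ch$diameter_axis,
                                   inner_diameter_A = ch$inner_diameter,
                                   n_strands = ch$n_strands,
                                   n_layers = ch$n_layers),
    hbonds_per_unit = report$hbonds_per_unit,
    pipi_per_unit = report$pipi_per_unit,
    seed = report$config$seed
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(out_dir)
}

head_mids <- function(breaks) (breaks[-1] + breaks[-length(breaks)]) / 2
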