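# Chemical-group model for cyclo-Trp-Pro (c-WP) molecules.
#
# Group labels follow the standard decomposition of the c-WP molecule:
#   W_mc  Trp half of the diketopiperazine main chain (N, H, CA, C, O ...)
#   W_sc  Trp side chain (CB and linkers)
#   W_aro Trp aromatic (indole) carbons
#   W_NH  indole N-H
#   P_mc  Pro half of the main chain
#   P_sc  Pro side chain (CB, CG, CD)
#   water water sites
#   other anything unmatched
# Labels are exclusive: W_aro and W_NH take precedence over W_sc, so the
# union of groups partitions the molecule.

.group_levels <- c("W_aro", "W_NH", "W_sc", "W_mc", "P_mc", "P_sc", "water", "other")

#' Default atom-name group table for cyclo-Trp-Pro
#'
#' A group table is a data.frame of `(residue, name_pattern, group)` rows;
#' patterns are regular expressions matched against atom names in order,
#' first hit wins. The default covers PDB-style Trp/Pro atom naming plus
#' common water spellings; other naming schemes can be supplied as a YAML
#' file via [read_group_table()].
#'
#' @return data.frame with columns `residue`, `name_pattern`, `group`.
#' @export
default_group_table <- function() {
  tab <- rbind(
    # indole N-H before the aromatic carbons, aromatics before side chain
    c("TRP", "^(NE1|HE1)$",                        "W_NH"),
    c("TRP", "^(CG|CD1|CD2|CE2|CE3|CZ2|CZ3|CH2)$", "W_aro"),
    c("TRP", "^(CB|HB.*|HD1|HE3|HZ.*|HH2)$",       "W_sc"),
    c("TRP", "^(N|H|HN|CA|HA|C|O|C1|O1)$",         "W_mc"),
    c("PRO", "^(CB|CG|CD|HB.*|HG.*|HD.*)$",        "P_sc"),
    c("PRO", "^(N|CA|HA|C|O|C1|O1)$",              "P_mc"),
    c("HOH|WAT|SOL", ".*",                         "water")
  )
  out <- data.frame(residue = tab[, 1], name_pattern = tab[, 2],
                    group = tab[, 3], stringsAsFactors = FALSE)
  out
}

#' Read a group table or ring definitions from YAML
#'
#' The YAML layout mirrors the shipped default (see
#' `system.file("extdata", "cwp_groups.yaml", package = "cyclohelix")`):
#' a `groups:` list of `{residue, name_pattern, group}` entries and a
#' `rings:` list of `{residue, kind, members}` entries.
#'
#' @param path YAML file.
#' @return list with elements `groups` (data.frame) and `rings`
#'   (data.frame with list-column `members`).
#' @export
read_group_table <- function(path) {
  y <- yaml::read_yaml(path)
  groups <- NULL
  rings <- NULL
  if (!is.null(y$groups)) {
    groups <- do.call(rbind, lapply(y$groups, function(g) {
      data.frame(residue = g$residue, name_pattern = g$name_pattern,
                 group = g$group, stringsAsFactors = FALSE)
    }))
    bad <- setdiff(groups$group, .group_levels)
    if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(y$rings)) {
    rings <- data.frame(
      residue = vapply(y$rings, `[[`, character(1), "residue"),
      kind = vapply(y$rings, `[[`, character(1), "kind"),
      stringsAsFactors = FALSE
    )
    rings$members <- lapply(y$rings, `[[`, "members")
  }
  list(groups = groups, rings = rings)
}

#' Assign every atom to a chemical group
#'
#' @param structure an `xtal`.
#' @param table group table (see [default_group_table()]).
#' @return factor of group labels, one per atom, levels
#'   `W_aro, W_NH, W_sc, W_mc, P_mc, P_sc, water, other`.
#' @export
assign_groups <- function(structure, table = default_group_table()) {
  stopifnot(is_xtal(structure))
  at <- structure$atoms
  out <- rep("other", nrow(at))
  assigned <- rep(FALSE, nrow(at))
  if (!is.null(table) && nrow(table)) {
    for (k in seq_len(nrow(table))) {
      hit <- !assigned &
        grepl(table$residue[k], at$residue, ignore.case = TRUE) &
        grepl(table$name_pattern[k], at$name, ignore.case = TRUE)
      out[hit] <- table$group[k]
      assigned <- assigned | hit
    }
  }
  if (any(!assigned)) {
    warning(sum(!assigned), " atom(s) matched no group pattern; labelled 'other'")
  }
  factor(out, levels = .group_levels)
}

#' Default aromatic-ring definitions for Trp
#'
#' The indole is treated as two separate rings by default (the 5-membered
#' pyrrole ring and the 6-membered benzene ring); a fused 9-atom mode is
#' available through [find_rings()]'s `fused` argument.
#'
#' @return data.frame with columns `residue`, `kind` and list-column
#'   `members` (atom names).
#' @export
default_ring_definitions <- function() {
  out <- data.frame(
    residue = c("TRP", "TRP"),
    kind = c("indole5", "indole6"),
    stringsAsFactors = FALSE
  )
  out$members <- list(
    c("CG", "CD1", "NE1", "CE2", "CD2"),
    c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
  )
  out
}

#' Locate aromatic rings
#'
#' For each molecule and each ring definition, collects the member atoms,
#' computes the centroid and the best-fit-plane normal (smallest-variance
#' principal axis, sign flipped into the +c hemisphere).
#'
#' @param structure an `xtal`.
#' @param definitions ring definitions (see [default_ring_definitions()]).
#' @param fused merge all definitions of one residue into one ring.
#' @param planarity_tol warn when the RMS out-of-plane deviation exceeds
#'   this (Angstrom); the ring is kept.
#' @return data.frame of class `ring_table`: `ring_id`, `molecule_id`,
#'   `kind`, centroid `cx, cy, cz`, normal `nx, ny, nz`, `rms_plane`, and a
#'   list-column `members` of atom ids.
#' @export
find_rings <- function(structure, definitions = default_ring_definitions(),
                       fused = FALSE, planarity_tol = 0.15) {
  stopifnot(is_xtal(structure))
  at <- structure$atoms
  pos <- unwrap_molecules(structure)
  cdir <- structure$cell$m[, 3]
  rows <- list()
  if (fused && nrow(definitions) > 1L) {
    defs <- do.call(rbind, lapply(split(definitions, definitions$residue), function(d) {
      out <- d[1, , drop = FALSE]
      out$kind <- "fused"
      out$members <- list(unique(unlist(d$members)))
      out
    }))
    definitions <- defs
  }
  for (mid in unique(at$molecule_id)) {
    sel_mol <- which(at$molecule_id == mid)
    for (k in seq_len(nrow(definitions))) {
      d_res <- definitions$residue[k]
      members <- definitions$members[[k]]
      sel <- sel_mol[grepl(d_res, at$residue[sel_mol], ignore.case = TRUE) &
                     toupper(at$name[sel_mol]) %in% toupper(members)]
      if (!length(sel)) next
      if (length(sel) < length(members)) {
        warning("molecule ", mid, ": ring ", definitions$kind[k],
                " missing member atoms; skipped")
        next
      }
      p <- pos[sel, , drop = FALSE]
      cen <- colMeans(p)
      pc <- stats::prcomp(p, center = TRUE)
      nrm <- pc$rotation[, 3]
      if (sum(nrm * cdir) < 0) nrm <- -nrm
      rms <- sqrt(mean((p %*% nrm - mean(p %*% nrm))^2))
      if (rms > planarity_tol) {
        warning("molecule ", mid, ": ring ", definitions$kind[k],
                " deviates from planarity (RMS ", signif(rms, 3), " A)")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = mid, kind = definitions$kind[k],
        cx = cen[1], cy = cen[2], cz = cen[3],
        nx = nrm[1], ny = nrm[2], nz = nrm[3],
        rms_plane = rms, stringsAsFactors = FALSE
      )
      rows[[length(rows)]]$members <- list(at$atom_id[sel])
    }
  }
  if (!length(rows)) {
    out <- data.frame(ring_id = integer(), molecule_id = integer(), kind = character(),
                      cx = numeric(), cy = numeric(), cz = numeric(),
                      nx = numeric(), ny = numeric(), nz = numeric(),
                      rms_plane = numeric())
    out$members <- list()
    class(out) <- c("ring_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- cbind(ring_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("ring_table", "data.frame")
  out
}
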