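#' Read a crystal structure
#'
#' Reads a small-molecule CIF, PDB or extended-XYZ file into the uniform
#' coordinate model, expands the asymmetric unit by the stored symmetry
#' operators, and assigns molecule ids by covalent connectivity.
#'
#' @param path file path.
#' @param format_hint `"cif"`, `"pdb"`, `"xyz"` or `"auto"` (by extension).
#' @param expand expand symmetry to the full cell (default `TRUE`).
#' @return an `xtal` (see [crystal_structure()]).
#' @export
read_structure <- function(path, format_hint = c("auto", "cif", "pdb", "xyz"),
                           expand = TRUE) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- if (format_hint == "auto") {
    switch(tolower(tools::file_ext(path)),
           cif = "cif", pdb = "pdb", ent = "pdb", xyz = "xyz",
           stop("cannot guess format of ", path, "; pass format_hint"))
  } else format_hint
  s <- switch(fmt,
              cif = read_cif(path),
              pdb = read_pdb_structure(path),
              xyz = read_xyz_structure(path))
  if (expand) s <- expand_symmetry(s) else s <- assign_molecule_ids(s)
  s
}

#' Write a crystal structure
#'
#' @param structure an `xtal`.
#' @param path output path.
#' @param format `"cif"`, `"pdb"` or `"xyz"`; default by extension.
#' @return the path, invisibly.
#' @export
write_structure <- function(structure, path,
                            format = c("auto", "cif", "pdb", "xyz")) {
  stopifnot(is_xtal(structure))
  if (!nrow(structure$atoms)) stop("refusing to write an empty structure")
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     cif = "cif", pdb = "pdb", xyz = "xyz",
                     stop("unsupported output format for ", path))
  }
  switch(format,
         cif = write_cif(structure, path),
         pdb = write_pdb_structure(structure, path),
         xyz = write_xyz_structure(structure, path))
  invisible(path)
}

# ---- PDB via bio3d ---------------------------------------------------------

read_pdb_structure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  # CRYST1 record; bio3d does not parse it, pull it directly
  cl <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  cell <- if (length(cl)) {
    v <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                      substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                      substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
    unit_cell(v[1], v[2], v[3], v[4], v[5], v[6])
  } else {
    pad_cell(cbind(at$x, at$y, at$z))
  }
  el <- at$elesy
  el[is.na(el) | !nzchar(el)] <- sub("[0-9].*$", "", at$elety[is.na(el) | !nzchar(el)])
  atoms <- data.frame(
    atom_id = seq_len(nrow(at)), element = trimws(el), name = at$elety,
    residue = at$resid, resid = at$resno, molecule_id = NA_integer_,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE
  )
  crystal_structure(atoms, cell, provenance = paste0("pdb:", path),
                    assign_molecules = FALSE)
}

write_pdb_structure <- function(structure, path) {
  at <- structure$atoms
  cell <- structure$cell
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords(structure))),
                   type = "ATOM",
                   resno = at$resid, resid = at$residue,
                   eleno = at$atom_id, elety = at$name,
                   chain = rep("A", nrow(at)),
                   elesy = at$element)
  # prepend CRYST1
  body <- readLines(path, warn = FALSE)
  writeLines(c(cryst, body), path)
  invisible(path)
}

# a padded orthorhombic cell for inputs without lattice information
pad_cell <- function(pos, pad = 20) {
  span <- unname(apply(pos, 2, function(v) diff(range(v))))
  unit_cell(span[1] + pad, span[2] + pad, span[3] + pad, 90, 90, 90)
}

# ---- extended XYZ ----------------------------------------------------------
# Comment line carries: Lattice="ax ay az bx by bz cx cy cz" [Time=ps]
# Optional per-atom trailing fields: residue resid molecule_id

xyz_comment <- function(cell, time = NULL) {
  m <- cell$m
  lat <- paste(sprintf("%.8f", c(m[, 1], m[, 2], m[, 3])), collapse = " ")
  s <- sprintf('Lattice="%s"', lat)
  if (!is.null(time)) s <- paste0(s, sprintf(" Time=%.6f", time))
  s
}

parse_xyz_comment <- function(line) {
  cell <- NULL; time <- NULL
  m <- regmatches(line, regexpr('Lattice="[^"]*"', line))
  if (length(m) && nzchar(m)) {
    v <- as.numeric(strsplit(trimws(sub('Lattice="([^"]*)"', "\\1", m)), "\\s+")[[1]])
    if (length(v) == 9) {
      mm <- matrix(v, 3, 3)  # columns a, b, c
      lengths <- sqrt(colSums(mm^2))
      ang <- function(u, v2) acos(sum(u * v2) / sqrt(sum(u^2) * sum(v2^2))) * 180 / pi
      cell <- unit_cell(lengths[1], lengths[2], lengths[3],
                        ang(mm[, 2], mm[, 3]), ang(mm[, 1], mm[, 3]),
                        ang(mm[, 1], mm[, 2]))
    }
  }
  t_m <- regmatches(line, regexpr("Time=([0-9.eE+-]+)", line))
  if (length(t_m) && nzchar(t_m)) time <- as.numeric(sub("Time=", "", t_m))
  list(cell = cell, time = time)
}

read_xyz_structure <- function(path) {
  fr <- read_xyz_frames(path, max_frames = 1L)
  fr$structure
}

write_xyz_structure <- function(structure, path) {
  at <- structure$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(at)), con)
  writeLines(xyz_comment(structure$cell), con)
  writeLines(sprintf("%-2s %14.8f %14.8f %14.8f %s %d %d",
                     at$element, at$x, at$y, at$z,
                     gsub("\\s", "_", at$residue), at$resid,
                     ifelse(is.na(at$molecule_id), 0L, at$molecule_id)), con)
  invisible(path)
}

# shared multi-frame XYZ reader; returns structure (first frame topology)
# plus per-frame coordinate matrices, cells and times
read_xyz_frames <- function(path, max_frames = Inf) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L; nl <- length(lines)
  frames <- list(); cells <- list(); times <- numeric(0)
  atoms0 <- NULL
  while (i <= nl && length(frames) < max_frames) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("bad atom count at line ", i, " of ", path)
    if (i + 1L + n > nl) stop("truncated frame ", length(frames) + 1L, " in ", path)
    hdr <- parse_xyz_comment(lines[i + 1L])
    block <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(block), "\\s+")
    el <- vapply(tok, `[`, character(1), 1L)
    pos <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(pos))) stop("unparseable coordinates in frame ",
                                   length(frames) + 1L, " of ", path)
    if (is.null(atoms0)) {
      has_meta <- all(lengths(tok) >= 7L)
      atoms0 <- data.frame(
        atom_id = seq_len(n), element = el,
        name = if (has_meta) el else el,
        residue = if (has_meta) vapply(tok, `[`, character(1), 5L) else "UNK",
        resid = if (has_meta) as.integer(vapply(tok, `[`, character(1), 6L)) else 1L,
        molecule_id = if (has_meta) {
          mid <- as.integer(vapply(tok, `[`, character(1), 7L))
          ifelse(mid == 0L, NA_integer_, mid)
        } else NA_integer_,
        x = pos[, 1], y = pos[, 2], z = pos[, 3], stringsAsFactors = FALSE
      )
    } else if (n != nrow(atoms0)) {
      stop("frame ", length(frames) + 1L, " atom count ", n,
           " differs from topology (", nrow(atoms0), ")")
    }
    frames[[length(frames) + 1L]] <- pos
    cells[[length(cells) + 1L]] <- if (is.null(hdr$cell)) pad_cell(pos) else hdr$cell
    times <- c(times, if (is.null(hdr$time)) length(frames) - 1 else hdr$time)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  structure0 <- crystal_structure(atoms0, cells[[1]],
                                  provenance = paste0("xyz:", path),
                                  assign_molecules = FALSE)
  list(structure = structure0, frames = frames, cells = cells, times = times)
}

# ---- trajectories ----------------------------------------------------------

#' Trajectory container
#'
#' @param frames list of Nx3 coordinate matrices (Angstrom).
#' @param times frame times in ps, strictly increasing.
#' @param cells list of per-frame [unit_cell()]s (or one, recycled).
#' @param topology an `xtal` sharing the atom table across frames.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(frames, times, cells, topology) {
  stopifnot(is.list(frames), length(frames) >= 1L, is_xtal(topology))
  n <- nrow(topology$atoms)
  if (any(vapply(frames, nrow, integer(1)) != n)) {
    stop("all frames must have the topology atom count (", n, ")")
  }
  if (is_unit_cell(cells)) cells <- rep(list(cells), length(frames))
  if (length(cells) != length(frames)) stop("one cell per frame required")
  if (length(times) != length(frames)) stop("one time per frame required")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(frames = frames, times = times, cells = cells,
                 topology = topology), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, t = %.3f..%.3f ps\n",
              length(x$frames), nrow(x$topology$atoms),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Read a coordinate trajectory
#'
#' Reads the plain multi-frame extended-XYZ dialect (atom count line,
#' comment line with `Lattice="..."` and optional `Time=`, then one atom
#' per line). When a `topology` structure is supplied its atom metadata
#' (names, residues, molecule ids) is carried over; the frame atom count
#' must match.
#'
#' @param coords_path path to the multi-frame XYZ file.
#' @param topology optional `xtal` with the shared atom table.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(coords_path, topology = NULL) {
  fr <- read_xyz_frames(coords_path)
  topo <- fr$structure
  if (!is.null(topology)) {
    stopifnot(is_xtal(topology))
    if (nrow(topology$atoms) != nrow(topo$atoms)) {
      stop("topology has ", nrow(topology$atoms), " atoms but trajectory frames have ",
           nrow(topo$atoms))
    }
    topo <- topology
  } else {
    topo <- assign_molecule_ids(topo)
  }
  trajectory(fr$frames, fr$times, fr$cells, topo)
}

#' Write a trajectory in the multi-frame extended-XYZ dialect
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  at <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj$frames)) {
    writeLines(as.character(nrow(at)), con)
    writeLines(xyz_comment(traj$cells[[k]], time = traj$times[k]), con)
    p <- traj$frames[[k]]
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f %s %d %d",
                       at$element, p[, 1], p[, 2], p[, 3],
                       gsub("\\s", "_", at$residue), at$resid,
                       ifelse(is.na(at$molecule_id), 0L, at$molecule_id)), con)
  }
  invisible(path)
}
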