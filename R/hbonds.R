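#' Hydrogen-bond criteria
#'
#' Geometric H-bond definition: donor-acceptor distance at most
#' `donor_acceptor_max` (default 3.5 A, i.e. 0.35 nm) and D-H...A angle at
#' the hydrogen at least `dha_angle_min` (default 150 degrees). Donors are
#' N/O atoms carrying a covalent hydrogen; acceptors are any N/O. With
#' `heavy_atom_fallback`, donors without modelled hydrogens (typically
#' water in X-ray structures) are accepted on the distance criterion alone
#' and flagged.
#'
#' @param donor_acceptor_max Angstrom.
#' @param dha_angle_min degrees.
#' @param donor_elements,acceptor_elements chemical symbols.
#' @param heavy_atom_fallback logical.
#' @return list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(donor_acceptor_max = 3.5, dha_angle_min = 150,
                           donor_elements = c("N", "O"),
                           acceptor_elements = c("N", "O"),
                           heavy_atom_fallback = TRUE) {
  stopifnot(donor_acceptor_max >= 0, dha_angle_min >= 0, dha_angle_min <= 180)
  structure(list(donor_acceptor_max = donor_acceptor_max,
                 dha_angle_min = dha_angle_min,
                 donor_elements = toupper(donor_elements),
                 acceptor_elements = toupper(acceptor_elements),
                 heavy_atom_fallback = heavy_atom_fallback),
            class = "hbond_criteria")
}

# hydrogens attached to each heavy atom; list indexed by atom row.
# Each hydrogen is assigned to its single nearest heavy atom within
# `max_xh` (1.5 A covers thermally stretched X-H bonds while staying well
# below typical H...acceptor distances of ~1.9 A).
attached_hydrogens <- function(structure, max_xh = 1.5) {
  el <- toupper(structure$atoms$element)
  hyd <- which(el == "H")
  out <- vector("list", nrow(structure$atoms))
  if (!length(hyd)) return(out)
  pr <- neighbor_pairs(structure$cell, coords(structure), max_xh)
  if (!nrow(pr)) return(out)
  i_h <- ifelse(el[pr$i] == "H", pr$i, pr$j)
  i_x <- ifelse(el[pr$i] == "H", pr$j, pr$i)
  ok <- el[i_h] == "H" & el[i_x] != "H"
  i_h <- i_h[ok]; i_x <- i_x[ok]; d <- pr$dist[ok]
  if (!length(i_h)) return(out)
  ord <- order(d)
  seen <- logical(nrow(structure$atoms))
  for (k in ord) {
    h <- i_h[k]
    if (seen[h]) next
    seen[h] <- TRUE
    out[[i_x[k]]] <- c(out[[i_x[k]]], h)
  }
  out
}

#' Detect hydrogen bonds
#'
#' All intermolecular (optionally also intramolecular) hydrogen bonds in
#' one coordinate frame under the minimum-image convention.
#'
#' @param structure an `xtal` (atom metadata + cell). For trajectory
#'   analysis pass `frame` to override the coordinates.
#' @param criteria an [hbond_criteria()].
#' @param frame optional Nx3 coordinate matrix replacing the stored ones.
#' @param cell optional [unit_cell()] replacing the stored one.
#' @param include_intramolecular logical.
#' @return data.frame of class `hbond_table`: donor/hydrogen/acceptor atom
#'   ids (hydrogen `NA` under the heavy-atom fallback), `da_distance` (A),
#'   `dha_angle` (degrees, `NA` under fallback), donor/acceptor molecule
#'   ids, `fallback` flag.
#' @export
detect_hbonds <- function(structure, criteria = hbond_criteria(),
                          frame = NULL, cell = NULL,
                          include_intramolecular = FALSE) {
  stopifnot(is_xtal(structure))
  if (!is.null(frame)) {
    structure <- `coords<-`(structure, frame)
  }
  if (!is.null(cell)) structure$cell <- cell
  at <- structure$atoms
  el <- toupper(at$element)
  pos <- coords(structure)
  hyds <- attached_hydrogens(structure)
  polar_d <- which(el %in% criteria$donor_elements)
  has_h <- lengths(hyds)[polar_d] > 0
  # heavy-atom fallback applies only to water donors without modelled
  # hydrogens (the common riding-model X-ray case); a carbonyl O, or an
  # unidentified bare heteroatom, is never a fallback donor
  mol_has_h <- tapply(el == "H", at$molecule_id, any)
  unmodelled <- !mol_has_h[as.character(at$molecule_id[polar_d])]
  is_water <- grepl("HOH|WAT|SOL", at$residue[polar_d], ignore.case = TRUE) |
    toupper(at$name[polar_d]) == "OW"
  donors <- polar_d[has_h | (criteria$heavy_atom_fallback & unmodelled & is_water)]
  fallback_donor <- !(lengths(hyds)[donors] > 0)
  acceptors <- which(el %in% criteria$acceptor_elements)
  empty <- data.frame(donor = integer(), hydrogen = integer(), acceptor = integer(),
                      da_distance = numeric(), dha_angle = numeric(),
                      donor_molecule = integer(), acceptor_molecule = integer(),
                      fallback = logical())
  class(empty) <- c("hbond_table", "data.frame")
  if (!length(donors) || !length(acceptors)) return(empty)
  # candidate D..A pairs within cutoff among polar atoms
  polar <- sort(unique(c(donors, acceptors)))
  pr <- neighbor_pairs(structure$cell, pos[polar, , drop = FALSE],
                       criteria$donor_acceptor_max)
  if (!nrow(pr)) return(empty)
  pr$i <- polar[pr$i]; pr$j <- polar[pr$j]
  # directed pairs: each orientation that is donor -> acceptor
  cand <- rbind(
    data.frame(d = pr$i, a = pr$j, dist = pr$dist),
    data.frame(d = pr$j, a = pr$i, dist = pr$dist)
  )
  keep <- cand$d %in% donors & cand$a %in% acceptors
  cand <- cand[keep, , drop = FALSE]
  if (!include_intramolecular) {
    cand <- cand[at$molecule_id[cand$d] != at$molecule_id[cand$a], , drop = FALSE]
  } else {
    cand <- cand[cand$d != cand$a, , drop = FALSE]
  }
  if (!nrow(cand)) return(empty)
  fb_lookup <- stats::setNames(fallback_donor, donors)
  n_h <- lengths(hyds)[cand$d]
  # expand candidates over the donor hydrogens, batch the minimum-image
  # geometry, and apply the angle criterion vectorized
  with_h <- cand[n_h > 0L, , drop = FALSE]
  out_h <- NULL
  if (nrow(with_h)) {
    rep_idx <- rep(seq_len(nrow(with_h)), lengths(hyds)[with_h$d])
    ex <- with_h[rep_idx, , drop = FALSE]
    ex$h <- unlist(hyds[with_h$d])
    a_img <- pos[ex$d, , drop = FALSE] +
      min_image(structure$cell, pos[ex$d, , drop = FALSE],
                pos[ex$a, , drop = FALSE])$disp
    h_pos <- pos[ex$d, , drop = FALSE] +
      min_image(structure$cell, pos[ex$d, , drop = FALSE],
                pos[ex$h, , drop = FALSE])$disp
    v1 <- pos[ex$d, , drop = FALSE] - h_pos
    v2 <- a_img - h_pos
    cosang <- rowSums(v1 * v2) / sqrt(rowSums(v1^2) * rowSums(v2^2))
    ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
    keep <- ang >= criteria$dha_angle_min
    if (any(keep)) {
      out_h <- data.frame(
        donor = ex$d[keep], hydrogen = ex$h[keep], acceptor = ex$a[keep],
        da_distance = ex$dist[keep], dha_angle = ang[keep],
        donor_molecule = at$molecule_id[ex$d[keep]],
        acceptor_molecule = at$molecule_id[ex$a[keep]],
        fallback = FALSE)
    }
  }
  out_f <- NULL
  no_h <- cand[n_h == 0L, , drop = FALSE]
  if (criteria$heavy_atom_fallback && nrow(no_h)) {
    is_fb <- vapply(no_h$d, function(d) isTRUE(fb_lookup[[as.character(d)]]),
                    logical(1))
    no_h <- no_h[is_fb, , drop = FALSE]
    if (nrow(no_h)) {
      out_f <- data.frame(
        donor = no_h$d, hydrogen = NA_integer_, acceptor = no_h$a,
        da_distance = no_h$dist, dha_angle = NA_real_,
        donor_molecule = at$molecule_id[no_h$d],
        acceptor_molecule = at$molecule_id[no_h$a],
        fallback = TRUE)
    }
  }
  out <- rbind(out_h, out_f)
  if (is.null(out) || !nrow(out)) return(empty)
  out <- out[order(out$donor, out$acceptor), ]
  rownames(out) <- NULL
  class(out) <- c("hbond_table", "data.frame")
  out
}

vec_angle <- function(u, v) {
  cu <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cu))) * 180 / pi
}
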