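#' Detect pi-pi stacking pairs
#'
#' All pairs of aromatic rings on different molecules whose minimum-image
#' centroid distance is at most `cutoff` (default 6.5 A = 0.65 nm). The
#' interplanar angle is the angle between the unsigned ring normals folded
#' into [0, 90] degrees (0 = parallel/cofacial, 90 = T-shaped).
#'
#' @param rings a ring table from [find_rings()].
#' @param cell a [unit_cell()] for minimum-image distances.
#' @param cutoff centroid distance cutoff, Angstrom.
#' @return data.frame of class `pipi_table`: `ring_a`, `ring_b`,
#'   `molecule_a`, `molecule_b`, `centroid_distance`, `interplanar_angle`.
#' @export
detect_pipi <- function(rings, cell, cutoff = 6.5) {
  stopifnot(inherits(rings, "data.frame"), is_unit_cell(cell))
  empty <- data.frame(ring_a = integer(), ring_b = integer(),
                      molecule_a = integer(), molecule_b = integer(),
                      centroid_distance = numeric(),
                      interplanar_angle = numeric())
  class(empty) <- c("pipi_table", "data.frame")
  if (nrow(rings) < 2L) return(empty)
  cen <- as.matrix(rings[, c("cx", "cy", "cz")])
  pr <- neighbor_pairs(cell, cen, cutoff)
  if (!nrow(pr)) return(empty)
  keep <- rings$molecule_id[pr$i] != rings$molecule_id[pr$j]
  pr <- pr[keep, , drop = FALSE]
  if (!nrow(pr)) return(empty)
  n1 <- as.matrix(rings[pr$i, c("nx", "ny", "nz")])
  n2 <- as.matrix(rings[pr$j, c("nx", "ny", "nz")])
  cosang <- abs(rowSums(n1 * n2) / sqrt(rowSums(n1^2) * rowSums(n2^2)))
  ang <- acos(pmin(1, cosang)) * 180 / pi
  out <- data.frame(ring_a = rings$ring_id[pr$i], ring_b = rings$ring_id[pr$j],
                    molecule_a = rings$molecule_id[pr$i],
                    molecule_b = rings$molecule_id[pr$j],
                    centroid_distance = pr$dist, interplanar_angle = ang)
  rownames(out) <- NULL
  class(out) <- c("pipi_table", "data.frame")
  out
}

#' Classify pi-pi pairs into stacking patterns
#'
#' Pattern I: inter-helix pairs closer than `band_I_max`; Pattern II:
#' inter-helix pairs between `band_I_max` and `band_II_max`; Pattern III:
#' intra-helix pairs at or beyond `band_III_min`. Everything else is
#' `unclassified`. The default band edges (6.5 and 8.0 A) sit midway
#' between the characteristic centre-of-mass distances of the three
#' stacking modes (~5, ~7.5 and ~8.5 A).
#'
#' @param pairs a `pipi_table` from [detect_pipi()].
#' @param strand_membership named vector: molecule_id -> helix/bundle id.
#' @param band_I_max,band_II_max,band_III_min Angstrom.
#' @return `pairs` with added columns `same_helix` and `pattern` (factor
#'   `I, II, III, unclassified`).
#' @export
classify_pipi <- function(pairs, strand_membership,
                          band_I_max = 6.5, band_II_max = 8.0,
                          band_III_min = 8.0) {
  stopifnot(inherits(pairs, "data.frame"))
  hx_a <- strand_membership[as.character(pairs$molecule_a)]
  hx_b <- strand_membership[as.character(pairs$molecule_b)]
  if (nrow(pairs) && any(is.na(hx_a) | is.na(hx_b))) {
    stop("strand_membership lacks helix ids for some molecules")
  }
  same <- hx_a == hx_b
  d <- pairs$centroid_distance
  pat <- rep("unclassified", nrow(pairs))
  pat[!same & d < band_I_max] <- "I"
  pat[!same & d >= band_I_max & d <= band_II_max] <- "II"
  pat[same & d >= band_III_min] <- "III"
  pairs$same_helix <- same
  pairs$pattern <- factor(pat, levels = c("I", "II", "III", "unclassified"))
  pairs
}
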