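# Synthetic stand-ins for the four cyclo-Trp-Pro crystal forms.
#
# These are idealized P6_3 models, not the deposited experimental
# structures: one rigid surrogate molecule per asymmetric unit, placed on
# the 6_3 screw axis lattice so that the published headline geometry is
# reproduced exactly at zero disorder — hexagonal cell (c-LWLP:
# a = b = 14.9474 A, c = 10.8213 A; c-LWDP: a = b = 15.1447 A,
# c = 10.8688 A), six molecules per unit cell, an interlayer
# diketopiperazine N-H...O=C hydrogen bond of 2.916 A, a Trp C-alpha
# circle of diameter 15.698 A, and (for the hydrated forms) a core water
# whose O...O=C separation is 2.959 A. The D-Trp forms are exact mirror
# images of the L-Trp forms, so the supramolecular twist flips from S to
# Z. Because the surrogate molecule is schematic, quantities that depend
# on full atomic detail (contact statistics, ring stacking) are
# qualitative only; the lattice-level geometry above is exact.

.p63_ops <- c("x,y,z", "-y,x-y,z", "-x+y,-x,z",
              "-x,-y,z+1/2", "y,-x+y,z+1/2", "x-y,x,z+1/2")

# fractional-space conjugation of the cartesian xz-plane mirror for a
# hexagonal cell in the standard orientation
.hex_mirror_frac <- matrix(c(1, -1, 0, 0, -1, 0, 0, 0, 1), 3, 3, byrow = TRUE)

#' Synthetic models of the cyclo-Trp-Pro crystal forms
#'
#' Builds an idealized hexagonal P6_3 crystal model of one of the four
#' c-WP stereoisomer forms (see the package vignette for what is exact
#' and what is schematic in these models). `c-LWLP` and `c-LWDP` are the
#' L-Trp (S-twist) forms, the latter hydrated; `c-DWLP` and `c-DWDP` are
#' their D-Trp mirror images (Z-twist).
#'
#' @param variant one of `"cLWLP"`, `"cLWDP"`, `"cDWLP"`, `"cDWDP"`.
#' @param expand return the symmetry-expanded cell (default); otherwise
#'   the asymmetric unit with its P6_3 operator list (e.g. for writing a
#'   compact CIF).
#' @param radius helix radius of the donor N atom, Angstrom.
#' @return an `xtal`.
#' @export
synthetic_cwp_crystal <- function(variant = c("cLWLP", "cLWDP", "cDWLP", "cDWDP"),
                                  expand = TRUE, radius = 7.0) {
  variant <- match.arg(variant)
  base <- switch(variant, cLWLP = "cLWLP", cDWDP = "cLWLP",
                 cLWDP = "cLWDP", cDWLP = "cLWDP")
  mirrored <- variant %in% c("cDWLP", "cDWDP")
  prm <- switch(base,
    cLWLP = list(a = 14.9474, c = 10.8213, d_no = 2.916, water = FALSE),
    cLWDP = list(a = 15.1447, c = 10.8688, d_no = 2.920, water = TRUE)
  )
  cell <- unit_cell(prm$a, prm$a, prm$c, 90, 90, 120)
  dz <- prm$c / 2                     # the 6_3 screw rise
  dth <- -60                          # L-Trp: clockwise along +c (S twist)
  tmpl <- cwp_template(radius, dth, dz, d_no = prm$d_no,
                       ca_radius = 15.698 / 2, decorations = character(0))
  z_off <- 0.5 - min(tmpl$z) # keep the molecule clear of the z = 0 face
  tmpl$z <- tmpl$z + z_off
  if (prm$water) {
    # core water: O placed 2.959 A from the carbonyl O, displaced toward
    # the screw axis, at the mean molecule height so it joins that layer
    oc <- as.numeric(tmpl[tmpl$name == "O", c("x", "y", "z")])
    zc <- mean(tmpl$z)
    dzw <- zc - oc[3]
    if (abs(dzw) >= 2.959) stop("water placement infeasible for this template")
    horiz <- sqrt(2.959^2 - dzw^2)
    hdir <- -oc[1:2] / sqrt(sum(oc[1:2]^2))
    ow <- c(oc[1:2] + horiz * hdir, zc)
    tmpl <- rbind(tmpl, data.frame(name = "OW", element = "O",
                                   residue = "HOH", x = ow[1], y = ow[2],
                                   z = ow[3], stringsAsFactors = FALSE))
  }
  at <- data.frame(
    atom_id = seq_len(nrow(tmpl)), element = tmpl$element, name = tmpl$name,
    residue = tmpl$residue, resid = 1L, molecule_id = NA_integer_,
    x = tmpl$x, y = tmpl$y, z = tmpl$z, stringsAsFactors = FALSE
  )
  ops <- lapply(.p63_ops, parse_symop)
  if (mirrored) {
    Fm <- .hex_mirror_frac
    frac <- cart_to_frac(cell, as.matrix(at[, c("x", "y", "z")])) %*% t(Fm)
    at[, c("x", "y", "z")] <- frac_to_cart(cell, frac)
    ops <- lapply(ops, function(op) {
      list(rot = Fm %*% op$rot %*% Fm, trans = drop(Fm %*% op$trans))
    })
  }
  st <- crystal_structure(at, cell, ops,
                          provenance = paste0("synthetic ", variant, " model"),
                          assign_molecules = FALSE)
  if (expand) expand_symmetry(st) else st
}
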