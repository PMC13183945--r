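#' Build a supercell
#'
#' Replicates the (symmetry-expanded) cell contents by lattice translations
#' and scales the cell accordingly. Molecule ids are re-indexed so every
#' replica is a distinct molecule; `n_cells` is multiplied by
#' `na * nb * nc` for later per-crystal-unit normalization.
#'
#' @param structure an `xtal`.
#' @param n integer triple `(na, nb, nc)`, each `>= 1`.
#' @param max_atoms guard against accidental huge expansions.
#' @return the supercell `xtal`.
#' @examples
#' \dontrun{
#' sc <- build_supercell(s, c(6, 6, 6))   # the bulk stacking model
#' }
#' @export
build_supercell <- function(structure, n = c(1L, 1L, 1L), max_atoms = 2e5) {
  stopifnot(is_xtal(structure), length(n) == 3)
  n <- as.integer(n)
  if (any(n < 1L)) stop("supercell multiples must be >= 1")
  ncop <- prod(n)
  if (nrow(structure$atoms) * ncop > max_atoms) {
    stop("supercell would exceed ", max_atoms, " atoms; raise max_atoms if intended")
  }
  at <- structure$atoms
  cell <- structure$cell
  if (ncop == 1L) {
    out <- structure
    return(out)
  }
  grid <- as.matrix(expand.grid(ia = 0:(n[1] - 1), ib = 0:(n[2] - 1), ic = 0:(n[3] - 1)))
  nmol <- max(at$molecule_id, na.rm = TRUE)
  pieces <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    shift <- frac_to_cart(cell, grid[k, ])
    a2 <- at
    a2$x <- at$x + shift[1]; a2$y <- at$y + shift[2]; a2$z <- at$z + shift[3]
    a2$molecule_id <- at$molecule_id + (k - 1L) * nmol
    pieces[[k]] <- a2
  }
  all_at <- do.call(rbind, pieces)
  all_at$atom_id <- seq_len(nrow(all_at))
  big <- unit_cell(cell$a * n[1], cell$b * n[2], cell$c * n[3],
                   cell$alpha, cell$beta, cell$gamma)
  crystal_structure(all_at, big, list(symop_identity()),
                    provenance = structure$provenance,
                    n_cells = structure$n_cells * ncop,
                    assign_molecules = FALSE)
}

#' Assign stacking layers along the helix axis
#'
#' Projects molecule centroids onto `axis` and clusters the projections by
#' 1-D single linkage: sorted projections are split wherever the gap
#' exceeds `gap_tol`. Layers are indexed from 0 in order of increasing
#' projection (the "first crystal layer" is the lowest one).
#'
#' @param structure an `xtal` with molecule ids assigned.
#' @param axis unit vector; default the crystallographic c direction (the
#'   elongation axis of the hexagonal prisms).
#' @param gap_tol split threshold in Angstrom. Default: 0.4x the median
#'   nearest-neighbour projection gap among distinct projections.
#' @return object of class `layer_assignment`: data.frame with columns
#'   `molecule_id`, `layer`, `projection`, plus attributes `axis` and
#'   `layer_spacing` (median spacing between consecutive layer means).
#' @export
assign_layers <- function(structure, axis = NULL, gap_tol = NULL) {
  stopifnot(is_xtal(structure))
  if (is.null(axis)) axis <- structure$cell$m[, 3]
  axis <- axis / sqrt(sum(axis^2))
  cen <- molecule_centroids(structure)
  proj <- drop(cen %*% axis)
  mol <- as.integer(rownames(cen))
  ord <- order(proj)
  p <- proj[ord]
  gaps <- diff(p)
  if (is.null(gap_tol)) {
    # layered data show a bimodal gap distribution: many small
    # within-layer gaps and a few large between-layer gaps near the layer
    # spacing; split a quarter of the way up from the typical small gap
    if (!length(gaps)) {
      gap_tol <- 0.5
    } else if (max(gaps) < 3 * stats::median(gaps) + 1e-9) {
      stop("layer projections show no clear gap structure ",
           "(max gap ", signif(max(gaps), 3), " A); supply gap_tol explicitly")
    } else {
      gap_tol <- (max(gaps) + stats::median(gaps)) / 4
    }
  }
  if (length(p) > 1L && max(gaps) < gap_tol) {
    stop("layer projections are not separable at gap_tol = ", signif(gap_tol, 3),
         " A; choose a different gap_tol or axis")
  }
  layer <- c(0L, cumsum(as.integer(gaps > gap_tol)))
  out <- data.frame(molecule_id = mol[ord], layer = layer, projection = p)
  out <- out[order(out$molecule_id), ]
  rownames(out) <- NULL
  means <- tapply(out$projection, out$layer, mean)
  spacing <- if (length(means) > 1L) stats::median(diff(sort(means))) else NA_real_
  attr(out, "axis") <- axis
  attr(out, "layer_spacing") <- spacing
  attr(out, "gap_tol") <- gap_tol
  class(out) <- c("layer_assignment", "data.frame")
  out
}
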