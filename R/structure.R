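# Covalent radii (Angstrom), Cordero-style consensus values for the
# elements that occur in peptide crystals and their hydrates.
.covalent_radius <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, S = 1.05, P = 1.07,
  CL = 1.02, BR = 1.20, I = 1.39, "NA" = 1.66, K = 2.03, MG = 1.41, CA = 1.76
)

covalent_radius <- function(element) {
  r <- .covalent_radius[toupper(element)]
  r[is.na(r)] <- 0.9   # conservative fallback for exotic elements
  unname(r)
}

valid_element <- function(element) {
  grepl("^[A-Za-z]{1,2}$", element)
}

#' Crystal structure container
#'
#' Bundle an atom table, a unit cell and (fractional-space) symmetry
#' operators into the coordinate model used throughout the package.
#'
#' The atom table is a `data.frame` with columns `atom_id` (integer),
#' `element` (chemical symbol), `name` (atom label, e.g. `"CA"`, `"OW"`),
#' `residue` (residue/component label), `resid` (integer residue number),
#' `molecule_id` (integer grouping atoms into one covalent molecule) and
#' Cartesian coordinates `x`, `y`, `z` in Angstrom.
#'
#' @param atoms atom `data.frame` as described above; `molecule_id` may be
#'   `NA` and is then assigned from covalent connectivity (interatomic
#'   distance below 1.2x the covalent-radius sum, minimum-image).
#' @param cell a [unit_cell()].
#' @param symmetry list of symmetry operators, each
#'   `list(rot = 3x3 matrix, trans = length-3)`, acting on fractional
#'   coordinates. Default: identity only.
#' @param provenance free-text origin note.
#' @param n_cells number of unit cells the atom table spans (used for
#'   per-crystal-unit normalization, see [per_unit()]).
#' @param assign_molecules logical; recompute `molecule_id` from
#'   connectivity.
#' @return object of class `xtal`.
#' @export
crystal_structure <- function(atoms, cell, symmetry = list(symop_identity()),
                              provenance = "", n_cells = 1L,
                              assign_molecules = any(is.na(atoms$molecule_id))) {
  stopifnot(is.data.frame(atoms), is_unit_cell(cell))
  need <- c("element", "name", "residue", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("crystal_structure: empty atom table")
  if (!all(valid_element(atoms$element))) stop("invalid element symbol in atom table")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atomic coordinate")
  }
  if (is.null(atoms$atom_id)) atoms$atom_id <- seq_len(nrow(atoms))
  if (is.null(atoms$resid)) atoms$resid <- 1L
  if (is.null(atoms$molecule_id)) atoms$molecule_id <- NA_integer_
  x <- structure(list(
    atoms = atoms, cell = cell, symmetry = symmetry,
    provenance = provenance, n_cells = as.integer(n_cells)
  ), class = "xtal")
  if (assign_molecules) x <- assign_molecule_ids(x)
  x
}

#' @export
print.xtal <- function(x, ...) {
  cat(sprintf("crystal structure: %d atoms, %d molecules, %d symmetry op(s), n_cells=%d\n",
              nrow(x$atoms), length(unique(x$atoms$molecule_id)),
              length(x$symmetry), x$n_cells))
  print(x$cell)
  invisible(x)
}

is_xtal <- function(x) inherits(x, "xtal")

coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

`coords<-` <- function(structure, value) {
  structure$atoms[, c("x", "y", "z")] <- value
  structure
}

symop_identity <- function() list(rot = diag(3), trans = c(0, 0, 0))

#' Assign molecule ids by covalent connectivity
#'
#' Two atoms are bonded when their minimum-image distance is below 1.2x the
#' sum of their covalent radii; connected components define molecules.
#' Molecule ids are integers starting at 1, ordered by first atom.
#'
#' @param structure an `xtal`.
#' @return the structure with `molecule_id` filled in.
#' @export
assign_molecule_ids <- function(structure) {
  stopifnot(is_xtal(structure))
  n <- nrow(structure$atoms)
  bonds <- bond_list(structure)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      ri <- find(bonds$i[k]); rj <- find(bonds$j[k])
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  structure$atoms$molecule_id <- as.integer(factor(roots, levels = unique(roots)))
  structure
}

# bonded atom pairs (minimum image); data.frame(i, j, dist)
bond_list <- function(structure) {
  pos <- coords(structure)
  rc <- covalent_radius(structure$atoms$element)
  maxcut <- 1.2 * 2 * max(rc)
  pr <- neighbor_pairs(structure$cell, pos, maxcut)
  if (!nrow(pr)) return(pr)
  ok <- pr$dist < 1.2 * (rc[pr$i] + rc[pr$j]) & pr$dist > 0.1
  pr[ok, , drop = FALSE]
}

# Per-molecule centroids with PBC unwrapping: atoms of one molecule are
# made contiguous by walking the bond graph and accumulating minimum-image
# displacements from a root atom.
molecule_centroids <- function(structure, unwrap = TRUE) {
  pos <- coords(structure)
  mol <- structure$atoms$molecule_id
  if (unwrap) pos <- unwrap_molecules(structure)
  t(vapply(split(seq_len(nrow(pos)), mol),
           function(ix) colMeans(pos[ix, , drop = FALSE]), numeric(3)))
}

unwrap_molecules <- function(structure) {
  pos <- coords(structure)
  mol <- structure$atoms$molecule_id
  bonds <- bond_list(structure)
  out <- pos
  if (!nrow(bonds)) return(out)
  # one vectorized minimum-image pass over all bonds, then BFS per
  # molecule accumulating the stored displacements
  disp <- min_image(structure$cell, pos[bonds$i, , drop = FALSE],
                    pos[bonds$j, , drop = FALSE])$disp
  adj_i <- c(bonds$i, bonds$j)
  adj_j <- c(bonds$j, bonds$i)
  adj_d <- rbind(disp, -disp)
  ord <- order(adj_i)
  adj_i <- adj_i[ord]; adj_j <- adj_j[ord]
  adj_d <- adj_d[ord, , drop = FALSE]
  first <- match(seq_len(nrow(pos)), adj_i)
  counts <- tabulate(adj_i, nbins = nrow(pos))
  placed <- logical(nrow(pos))
  for (ix in split(seq_len(nrow(pos)), mol)) {
    if (length(ix) == 1L) next
    placed[ix[1]] <- TRUE
    queue <- ix[1]
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (counts[cur] == 0L) next
      sl <- seq(first[cur], length.out = counts[cur])
      for (k in sl) {
        nb <- adj_j[k]
        if (placed[nb]) next
        out[nb, ] <- out[cur, ] + adj_d[k, ]
        placed[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  out
}

#' Expand the asymmetric unit by the symmetry operators
#'
#' Applies every stored symmetry operator to the atom table in fractional
#' space, wraps into the unit cell, and removes duplicates (same element
#' within 0.1 Angstrom after wrapping; standard special-position handling).
#' Idempotent: expanding an already-expanded structure adds no atoms.
#'
#' @param structure an `xtal`.
#' @param dup_tol duplicate tolerance in Angstrom.
#' @return expanded `xtal` whose `symmetry` is reset to the identity.
#' @export
expand_symmetry <- function(structure, dup_tol = 0.1) {
  stopifnot(is_xtal(structure))
  ops <- structure$symmetry
  if (!length(ops)) ops <- list(symop_identity())
  at <- structure$atoms
  frac <- cart_to_frac(structure$cell, coords(structure))
  pieces <- vector("list", length(ops))
  for (k in seq_along(ops)) {
    f2 <- wrap_frac(frac %*% t(ops[[k]]$rot) + matrix(ops[[k]]$trans, nrow(frac), 3, byrow = TRUE))
    a2 <- at
    a2[, c("x", "y", "z")] <- frac_to_cart(structure$cell, f2)
    a2$.op <- k
    pieces[[k]] <- a2
  }
  all_at <- do.call(rbind, pieces)
  # duplicate removal under minimum image
  keep <- rep(TRUE, nrow(all_at))
  pr <- neighbor_pairs(structure$cell, as.matrix(all_at[, c("x", "y", "z")]), dup_tol)
  if (nrow(pr)) {
    same <- all_at$element[pr$i] == all_at$element[pr$j]
    for (k in which(same)) keep[max(pr$i[k], pr$j[k])] <- FALSE
  }
  all_at <- all_at[keep, , drop = FALSE]
  all_at$.op <- NULL
  all_at$atom_id <- seq_len(nrow(all_at))
  all_at$molecule_id <- NA_integer_
  out <- crystal_structure(all_at, structure$cell, list(symop_identity()),
                           provenance = structure$provenance,
                           n_cells = structure$n_cells,
                           assign_molecules = TRUE)
  out
}
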