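#' Unit cell
#'
#' Construct a crystallographic unit cell from lattice lengths (Angstrom)
#' and angles (degrees). The cell matrix uses the standard crystallographic
#' orientation: \eqn{a} along x, \eqn{b} in the xy-plane, so the matrix is
#' lower-triangular with columns equal to the cell vectors and
#' `cart = M %*% frac`.
#'
#' @param a,b,c lattice lengths in Angstrom, `> 0`.
#' @param alpha,beta,gamma lattice angles in degrees, in `(0, 180)`.
#' @return An object of class `unit_cell`: list with fields `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma`, the 3x3 cell matrix `m` and its inverse
#'   `m_inv`, and the cell volume `volume` (Angstrom^3).
#' @examples
#' cell <- unit_cell(14.9474, 14.9474, 10.8213, 90, 90, 120)  # hexagonal
#' cell$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(!is.finite(c(a, b, c, alpha, beta, gamma)))) {
    stop("unit_cell: non-finite cell parameter")
  }
  if (any(c(a, b, c) <= 0)) stop("unit_cell: lattice lengths must be > 0")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180)) {
    stop("unit_cell: lattice angles must lie in (0, 180) degrees")
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  # standard lower-triangular cell matrix
  cy <- (ca - cb * cg) / sg
  cz2 <- 1 - cb^2 - cy^2
  if (cz2 <= 0) stop("unit_cell: angles do not define a valid 3D cell")
  m <- matrix(c(
    a,      b * cg, c * cb,
    0,      b * sg, c * cy,
    0,      0,      c * sqrt(cz2)
  ), nrow = 3, byrow = TRUE)
  structure(list(
    a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
    m = m, m_inv = solve(m), volume = abs(det(m))
  ), class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f A  alpha=%.2f beta=%.2f gamma=%.2f deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

is_unit_cell <- function(x) inherits(x, "unit_cell")

#' Fractional/Cartesian coordinate transforms
#'
#' @param cell a [unit_cell()].
#' @param frac,cart coordinates: length-3 vector or an Nx3 matrix.
#' @return Coordinates of the same shape in the other basis (Angstrom for
#'   Cartesian).
#' @examples
#' cell <- unit_cell(10, 10, 10, 90, 90, 120)
#' frac_to_cart(cell, c(0, 1, 0))   # (-5, 8.6603, 0)
#' @export
frac_to_cart <- function(cell, frac) {
  stopifnot(is_unit_cell(cell))
  xy <- as_coord_matrix(frac)
  out <- xy %*% t(cell$m)
  if (is.null(dim(frac))) drop(out) else out
}

#' @rdname frac_to_cart
#' @export
cart_to_frac <- function(cell, cart) {
  stopifnot(is_unit_cell(cell))
  xy <- as_coord_matrix(cart)
  out <- xy %*% t(cell$m_inv)
  if (is.null(dim(cart))) drop(out) else out
}

as_coord_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("coordinate must have length 3")
    matrix(x, nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3L) stop("coordinate matrix must have 3 columns")
    x
  }
}

# wrap fractional coordinates into [0, 1)
wrap_frac <- function(f) f - floor(f)

# perpendicular heights of the cell along a, b, c (distance between
# opposite faces); the validity bound for single-image minimum-image use
cell_heights <- function(cell) {
  m <- cell$m
  v <- abs(det(m))
  areas <- c(
    sqrt(sum(pracma_cross(m[, 2], m[, 3])^2)),
    sqrt(sum(pracma_cross(m[, 3], m[, 1])^2)),
    sqrt(sum(pracma_cross(m[, 1], m[, 2])^2))
  )
  v / areas
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# 27 lattice shifts (fractional), row per shift
shifts27 <- as.matrix(expand.grid(sa = -1:1, sb = -1:1, sc = -1:1))

#' Minimum-image displacement and distance
#'
#' Shortest displacement from `p` to `q` under periodic boundary
#' conditions, found by exact enumeration of the 27 neighbour images of the
#' fractionally wrapped difference. Exact whenever the relevant distance is
#' below half the shortest cell height (and in practice far beyond, since
#' the wrapped difference is re-minimized over all 27 images).
#'
#' @param cell a [unit_cell()].
#' @param p,q Cartesian points (length-3) or Nx3 matrices (paired rows).
#' @return list with `disp` (vector/matrix, q - p minimal image), `dist`
#'   (numeric), and `shift` (the integer lattice shift applied to `q`).
#' @examples
#' cell <- unit_cell(10, 10, 10)
#' min_image(cell, c(1, 0, 0), c(9, 0, 0))$dist  # 2
#' @export
min_image <- function(cell, p, q) {
  stopifnot(is_unit_cell(cell))
  pm <- as_coord_matrix(p); qm <- as_coord_matrix(q)
  if (nrow(pm) == 1L && nrow(qm) > 1L) pm <- pm[rep(1L, nrow(qm)), , drop = FALSE]
  if (nrow(qm) == 1L && nrow(pm) > 1L) qm <- qm[rep(1L, nrow(pm)), , drop = FALSE]
  stopifnot(nrow(pm) == nrow(qm))
  df <- cart_to_frac(cell, qm) - cart_to_frac(cell, pm)
  df <- df - round(df)                       # wrap to [-0.5, 0.5]
  n <- nrow(df)
  best_d2 <- rep(Inf, n)
  best_disp <- matrix(0, n, 3)
  best_shift <- matrix(0L, n, 3)
  for (k in seq_len(nrow(shifts27))) {
    s <- shifts27[k, ]
    cand <- frac_to_cart(cell, sweep(df, 2, s, "+"))
    cand <- as_coord_matrix(cand)
    d2 <- rowSums(cand^2)
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_disp[upd, ] <- cand[upd, , drop = FALSE]
      best_shift[upd, ] <- matrix(as.integer(s), sum(upd), 3, byrow = TRUE)
    }
  }
  # total shift includes the initial wrap
  wrap_shift <- -round(cart_to_frac(cell, qm) - cart_to_frac(cell, pm))
  list(
    disp = if (is.null(dim(p)) && is.null(dim(q)) && n == 1L) drop(best_disp) else best_disp,
    dist = sqrt(best_d2),
    shift = best_shift + wrap_shift
  )
}

# All pairs within `cutoff` under PBC, via fractional cell lists sized by
# the perpendicular cell heights (guarantees neighbours live in adjacent
# bins), then exact 27-image minimization on the candidate pairs.
# pos: Nx3 cartesian. Returns data.frame(i, j, dist) with i < j.
neighbor_pairs <- function(cell, pos, cutoff) {
  pos <- as_coord_matrix(pos)
  n <- nrow(pos)
  if (n < 2L || cutoff <= 0) {
    return(data.frame(i = integer(), j = integer(), dist = numeric()))
  }
  frac <- wrap_frac(cart_to_frac(cell, pos))
  h <- cell_heights(cell)
  nb <- pmax(1L, pmin(8L, as.integer(floor(h / cutoff))))
  bin <- sweep(floor(sweep(frac, 2, nb, "*")), 2, nb - 1L, pmin)  # guard fp edge
  bin_id <- bin[, 1] + nb[1] * (bin[, 2] + nb[2] * bin[, 3])
  ord <- order(bin_id)
  by_bin <- split(ord, bin_id[ord])
  # neighbour bin offsets, deduplicated for tiny grids
  offs <- shifts27
  cand_i <- list(); cand_j <- list(); ci <- 0L
  bin_keys <- as.integer(names(by_bin))
  key_lookup <- new.env(hash = TRUE)
  for (k in seq_along(bin_keys)) assign(as.character(bin_keys[k]), k, envir = key_lookup)
  decode <- function(id) {
    x <- id %% nb[1]; r <- id %/% nb[1]
    y <- r %% nb[2]; z <- r %/% nb[2]
    c(x, y, z)
  }
  for (k in seq_along(by_bin)) {
    b <- decode(bin_keys[k])
    seen <- character(0)
    for (o in seq_len(nrow(offs))) {
      nb3 <- (b + offs[o, ]) %% nb
      nid <- nb3[1] + nb[1] * (nb3[2] + nb[2] * nb3[3])
      nk <- get0(as.character(nid), envir = key_lookup, ifnotfound = NULL)
      if (is.null(nk) || nk < k) next
      key <- as.character(nid)
      if (key %in% seen) next
      seen <- c(seen, key)
      ii <- by_bin[[k]]; jj <- by_bin[[nk]]
      if (nk == k) {
        if (length(ii) < 2L) next
        pr <- utils::combn(ii, 2L)
        a <- pr[1, ]; bj <- pr[2, ]
      } else {
        g <- expand.grid(a = ii, b = jj)
        a <- g$a; bj <- g$b
      }
      ci <- ci + 1L
      cand_i[[ci]] <- a; cand_j[[ci]] <- bj
    }
  }
  if (ci == 0L) return(data.frame(i = integer(), j = integer(), dist = numeric()))
  a <- unlist(cand_i); b <- unlist(cand_j)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  dup <- duplicated(paste(a, b))
  a <- a[!dup]; b <- b[!dup]
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  if (!length(a)) return(data.frame(i = integer(), j = integer(), dist = numeric()))
  mi <- min_image(cell, pos[a, , drop = FALSE], pos[b, , drop = FALSE])
  ok <- mi$dist <= cutoff
  data.frame(i = a[ok], j = b[ok], dist = mi$dist[ok])
}
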