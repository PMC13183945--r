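# gas constant in kJ mol^-1 K^-1
.R_GAS <- 8.3145e-3

#' Free-energy landscape from (distance, angle) observations
#'
#' Bins the observations on a 2-D grid, normalizes to a probability
#' distribution P, and Boltzmann-inverts it: G = -RT ln P (kJ/mol), with
#' R = 8.3145e-3 kJ/(mol K). Empty bins are masked (`NA`). The global
#' minimum G = 0 occurs at the most probable bin only when that bin holds
#' all observations; in general min(G) = -RT ln max(P) >= 0.
#'
#' @param observations data.frame or 2-column matrix of (distance, angle).
#' @param distance_breaks,angle_breaks bin edges, or a single bin count.
#' @param temperature Kelvin (default 300).
#' @return object of class `fel_grid`: list with `distance_breaks`,
#'   `angle_breaks`, matrices `P` and `G` (distance bins x angle bins),
#'   `temperature`, `R`.
#' @export
free_energy_landscape <- function(observations, distance_breaks = 40,
                                  angle_breaks = 30, temperature = 300) {
  obs <- as.matrix(observations)
  if (!nrow(obs)) stop("free_energy_landscape: no observations")
  if (ncol(obs) != 2L) stop("observations must be (distance, angle) pairs")
  stopifnot(temperature > 0)
  mk_breaks <- function(v, br) {
    if (length(br) == 1L) {
      rng <- range(v)
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
      seq(rng[1], rng[2], length.out = br + 1L)
    } else br
  }
  db <- mk_breaks(obs[, 1], distance_breaks)
  ab <- mk_breaks(obs[, 2], angle_breaks)
  di <- findInterval(obs[, 1], db, rightmost.closed = TRUE, all.inside = TRUE)
  ai <- findInterval(obs[, 2], ab, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0, length(db) - 1L, length(ab) - 1L)
  for (k in seq_len(nrow(obs))) counts[di[k], ai[k]] <- counts[di[k], ai[k]] + 1
  P <- counts / sum(counts)
  G <- -.R_GAS * temperature * log(P)
  G[!is.finite(G)] <- NA
  # shift so the global minimum sits at 0, the conventional FEL gauge?
  # No: keep the raw -RT ln P so that exp(-G/RT) recovers P exactly.
  structure(list(distance_breaks = db, angle_breaks = ab, P = P, G = G,
                 temperature = temperature, R = .R_GAS),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  occ <- sum(!is.na(x$G))
  cat(sprintf("free-energy landscape: %d x %d bins (%d occupied), T = %g K, min G = %.3f kJ/mol\n",
              nrow(x$G), ncol(x$G), occ, x$temperature, min(x$G, na.rm = TRUE)))
  invisible(x)
}
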