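# Kabsch optimal superposition: rotation (and translation) minimizing the
# RMSD of mobile onto fixed. Returns the transformed mobile coordinates.
kabsch_superpose <- function(fixed, mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  A <- sweep(mobile, 2, cm)
  B <- sweep(fixed, 2, cf)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  sweep(A %*% t(R), 2, cf, "+")
}

#' Per-frame RMSD with reference to the initial frame
#'
#' All-atom root-mean-square deviation of every frame from frame 1,
#' optionally after optimal rigid-body superposition (Kabsch).
#'
#' @param traj a [trajectory()].
#' @param superpose remove rigid-body motion first.
#' @return numeric vector, one RMSD (Angstrom) per frame; the first entry
#'   is 0 by construction.
#' @export
rmsd_series <- function(traj, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  ref <- traj$frames[[1]]
  vapply(traj$frames, function(p) {
    if (nrow(p) != nrow(ref)) stop("frame atom count mismatch")
    q <- if (superpose) kabsch_superpose(ref, p) else p
    sqrt(mean(rowSums((q - ref)^2)))
  }, numeric(1))
}
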