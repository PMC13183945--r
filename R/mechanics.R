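# Mechanical-curve analysis: tensile stress-strain metrics and Hertz
# nanoindentation fits. All quantities in SI units (Pa, N, m).

#' Tensile curve container
#'
#' @param strain dimensionless strain series, non-decreasing.
#' @param stress stress series, Pa.
#' @param gauge_length,diameter optional sample geometry (m) when the
#'   series were derived from raw force-displacement data.
#' @return list of class `tensile_curve`.
#' @export
tensile_curve <- function(strain, stress, gauge_length = NA, diameter = NA) {
  stopifnot(length(strain) == length(stress))
  if (any(diff(strain) < 0)) stop("strain series must be non-decreasing")
  structure(list(strain = strain, stress = stress,
                 gauge_length = gauge_length, diameter = diameter),
            class = "tensile_curve")
}

#' Tensile metrics: modulus, fracture, work of rupture
#'
#' The tensile (Young's) modulus is the least-squares slope of stress vs
#' strain over the initial linear window (default 0-0.2% strain). Fracture
#' is at maximum stress; the work of rupture is the trapezoidal integral
#' of stress over strain up to fracture (J/m^3).
#'
#' @param curve a [tensile_curve()].
#' @param modulus_window strain window `c(lo, hi)` for the modulus fit.
#' @param min_points minimum points required inside the window.
#' @return list of class `tensile_metrics`: `modulus` (Pa),
#'   `fracture_stress` (Pa), `fracture_strain`, `work_of_rupture` (J/m^3),
#'   `window`.
#' @export
tensile_metrics <- function(curve, modulus_window = c(0, 0.002),
                            min_points = 5L) {
  stopifnot(inherits(curve, "tensile_curve"))
  eps <- curve$strain; sig <- curve$stress
  in_win <- eps >= modulus_window[1] & eps <= modulus_window[2]
  if (sum(in_win) < min_points) {
    stop("tensile_metrics: only ", sum(in_win), " point(s) in the modulus window; ",
         "need >= ", min_points)
  }
  fit <- stats::lm(sig[in_win] ~ eps[in_win])
  modulus <- unname(stats::coef(fit)[2])
  i_f <- which.max(sig)
  w <- 0
  if (i_f > 1L) {
    de <- diff(eps[1:i_f])
    w <- sum(de * (sig[1:(i_f - 1L)] + sig[2:i_f]) / 2)
  }
  structure(list(modulus = modulus, fracture_stress = sig[i_f],
                 fracture_strain = eps[i_f], work_of_rupture = w,
                 window = modulus_window), class = "tensile_metrics")
}

#' Hertz contact force
#'
#' Sphere-on-flat elastic contact: `F = (4/3) E / (1 - nu^2) sqrt(R) delta^(3/2)`.
#'
#' @param E sample Young's modulus, Pa.
#' @param nu Poisson ratio (0.3 for these crystals).
#' @param R_tip tip radius, m.
#' @param delta indentation depth, m, `>= 0` (vectorized).
#' @return force in N.
#' @examples
#' hertz_force(1, 0, 1, 1)  # reduced units: 4/3
#' @export
hertz_force <- function(E, nu, R_tip, delta) {
  stopifnot(E > 0, R_tip > 0, nu >= 0, nu < 0.5)
  if (any(delta < 0)) stop("hertz_force: negative indentation depth")
  (4 / 3) * E / (1 - nu^2) * sqrt(R_tip) * delta^1.5
}

#' Force curve container
#'
#' @param z piezo displacement series, m (increasing toward the surface).
#' @param force measured normal force series, N.
#' @param R_tip tip radius, m (nominal ~10 nm for the probes used here).
#' @param nu sample Poisson ratio.
#' @param k_c cantilever spring constant, N/m, used for deflection
#'   correction (`NA` to skip correction).
#' @return list of class `force_curve`.
#' @export
force_curve <- function(z, force, R_tip = 10e-9, nu = 0.3, k_c = 200) {
  stopifnot(length(z) == length(force), R_tip > 0, nu >= 0, nu < 0.5)
  structure(list(z = z, force = force, R_tip = R_tip, nu = nu, k_c = k_c),
            class = "force_curve")
}

# sample deformation: piezo travel past contact minus cantilever deflection
sample_indentation <- function(curve, z0) {
  d <- curve$z - z0
  if (!is.na(curve$k_c) && curve$k_c > 0) d <- d - curve$force / curve$k_c
  d
}

#' Fit the Hertz model to an approach force curve
#'
#' Fits the sample modulus `E` and the contact point `z0` jointly by
#' (optionally robust) least squares on the post-contact region. The
#' indentation is deflection-corrected, `delta = (z - z0) - F/k_c`. The
#' contact point is initialized at the first point where the force exceeds
#' 3x the pre-contact noise SD; a soft-L1 loss (default) damps snap-in
#' artifacts.
#'
#' @param curve a [force_curve()].
#' @param robust use a soft-L1 loss instead of plain least squares.
#' @return list of class `hertz_fit`: `E` (Pa), `z0` (m), `rms_residual`
#'   (N), `n_contact` points used.
#' @export
hertz_fit <- function(curve, robust = TRUE) {
  stopifnot(inherits(curve, "force_curve"))
  F <- curve$force; z <- curve$z
  if (all(abs(F) < .Machine$double.eps)) stop("hertz_fit: force curve is identically zero")
  n <- length(F)
  # contact-point initial guess from the pre-contact noise floor
  n_pre <- max(5L, floor(n * 0.1))
  noise <- stats::sd(F[seq_len(min(n_pre, n))])
  thresh <- if (is.finite(noise) && noise > 0) 3 * noise else max(F) * 0.02
  i0 <- which(F > thresh)[1]
  if (is.na(i0)) stop("hertz_fit: no post-contact data above the noise floor")
  z0_init <- z[max(1L, i0 - 1L)]
  pref <- (4 / 3) / (1 - curve$nu^2) * sqrt(curve$R_tip)
  scaleF <- max(abs(F))
  loss <- function(r) if (robust) sum(2 * (sqrt(1 + r^2) - 1)) else sum(r^2)
  obj <- function(par) {
    E <- exp(par[1]); z0 <- par[2]
    d <- sample_indentation(curve, z0)
    pred <- ifelse(d > 0, pref * E * d^1.5, 0)
    loss((pred - F) / scaleF)
  }
  # E init from the last point
  d_init <- sample_indentation(curve, z0_init)
  dmax <- max(d_init)
  E_init <- if (dmax > 0) max(F) / (pref * dmax^1.5) else 1e9
  opt <- stats::optim(c(log(E_init), z0_init), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  E <- exp(opt$par[1]); z0 <- opt$par[2]
  if (!is.finite(E) || E <= 0) stop("hertz_fit: fit failed (bad contact point?)")
  d <- sample_indentation(curve, z0)
  pred <- ifelse(d > 0, pref * E * d^1.5, 0)
  structure(list(E = E, z0 = z0,
                 rms_residual = sqrt(mean((pred - F)^2)),
                 n_contact = sum(d > 0)), class = "hertz_fit")
}

#' Point stiffness at maximum load
#'
#' Ratio of the maximum normal force to the cantilever-deflection-corrected
#' sample deformation at that point. A slope variant (least-squares slope
#' of force vs sample deformation over the top fraction of the curve) is
#' available.
#'
#' @param curve a [force_curve()].
#' @param z0 contact point, m; default from a [hertz_fit()].
#' @param method `"ratio"` (force/deformation at max load) or `"slope"`.
#' @param slope_fraction top force fraction used by the slope variant.
#' @return stiffness in N/m.
#' @export
point_stiffness <- function(curve, z0 = NULL, method = c("ratio", "slope"),
                            slope_fraction = 0.2) {
  stopifnot(inherits(curve, "force_curve"))
  method <- match.arg(method)
  if (is.null(z0)) z0 <- hertz_fit(curve)$z0
  d <- sample_indentation(curve, z0)
  i_max <- which.max(curve$force)
  if (d[i_max] <= 0) stop("point_stiffness: non-positive sample deformation at max load")
  if (method == "ratio") {
    curve$force[i_max] / d[i_max]
  } else {
    sel <- curve$force >= (1 - slope_fraction) * curve$force[i_max] & d > 0
    if (sum(sel) < 3L) stop("point_stiffness: too few points for the slope variant")
    unname(stats::coef(stats::lm(curve$force[sel] ~ d[sel]))[2])
  }
}

#' Read force / tensile curves from delimited text
#'
#' Thin wrappers over [utils::read.table()] with configurable columns.
#'
#' @param path CSV/TSV file.
#' @param z_col,force_col,strain_col,stress_col column names or indices.
#' @param sep field separator (`""` = any whitespace).
#' @param ... passed to [force_curve()] / [tensile_curve()].
#' @return a [force_curve()] or [tensile_curve()].
#' @export
read_force_curve <- function(path, z_col = 1, force_col = 2, sep = "", ...) {
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  force_curve(z = tab[[z_col]], force = tab[[force_col]], ...)
}

#' @rdname read_force_curve
#' @export
read_tensile_curve <- function(path, strain_col = 1, stress_col = 2, sep = "", ...) {
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  tensile_curve(strain = tab[[strain_col]], stress = tab[[stress_col]], ...)
}
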