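# Strand tracing, H-bond rotation-angle profiles, S/Z twist classification
# and helix fitting — the supramolecular-chirality core of the package.
#
# Sign convention, fixed once: angles in the plane perpendicular to the
# helix axis are measured counterclockwise-positive when viewed from the
# +axis tip (right-handed frame). A decreasing rotation-angle profile is a
# clockwise rotation along the axis and is called S (left-handed rope
# twist); an increasing profile is counterclockwise and is called Z
# (right-handed), as in rope-maker's and collagen nomenclature.

#' Trace H-bonded strands through the stacking layers
#'
#' Molecules are nodes; intermolecular H-bonds between consecutive layers
#' are candidate edges. Edges are accepted greedily by increasing
#' donor-acceptor distance, each molecule linking to at most one partner
#' in the next layer (ties/branches resolved by the shortest D...A
#' distance). Connected layer-monotone paths form strands, ordered by
#' increasing axis projection. Strands whose fitted axes lie within
#' `merge_radius` of each other are grouped into one helix (bundle) id.
#'
#' @param hbonds `hbond_table` from [detect_hbonds()].
#' @param structure the `xtal` the bonds were detected in.
#' @param layers a [assign_layers()] result.
#' @param merge_radius Angstrom, bundle-grouping threshold on the
#'   perpendicular distance between strand axes.
#' @return list of class `strand_set`: `strands` (list of integer vectors
#'   of molecule ids, layer-ordered), `helix_id` (integer per strand),
#'   `axis` (unit vector), `axis_points` (per-strand axis point in the
#'   perpendicular plane).
#' @export
trace_strands <- function(hbonds, structure, layers, merge_radius = 3.0) {
  stopifnot(is_xtal(structure), inherits(layers, "data.frame"))
  axis <- attr(layers, "axis")
  lay <- stats::setNames(layers$layer, layers$molecule_id)
  empty <- structure(list(strands = list(), helix_id = integer(),
                          axis = axis, axis_points = NULL, positions = NULL),
                     class = "strand_set")
  if (is.null(hbonds) || !nrow(hbonds)) return(empty)
  hb <- hbonds[hbonds$donor_molecule != hbonds$acceptor_molecule, , drop = FALSE]
  if (!nrow(hb)) return(empty)
  l1 <- lay[as.character(hb$donor_molecule)]
  l2 <- lay[as.character(hb$acceptor_molecule)]
  inter <- abs(l1 - l2) == 1L
  hb <- hb[inter, , drop = FALSE]
  if (!nrow(hb)) return(empty)
  # orient lower-layer -> upper-layer
  lo <- ifelse(l1[inter] < l2[inter], hb$donor_molecule, hb$acceptor_molecule)
  hi <- ifelse(l1[inter] < l2[inter], hb$acceptor_molecule, hb$donor_molecule)
  links <- data.frame(lo = lo, hi = hi, dist = hb$da_distance)
  links <- links[!duplicated(links[, c("lo", "hi")]), , drop = FALSE]
  links <- links[order(links$dist), , drop = FALSE]
  succ <- integer(0); pred <- integer(0)
  nxt <- new.env(hash = TRUE)
  prv <- new.env(hash = TRUE)
  dropped <- 0L
  for (k in seq_len(nrow(links))) {
    a <- as.character(links$lo[k]); b <- as.character(links$hi[k])
    if (!is.null(get0(a, envir = nxt)) || !is.null(get0(b, envir = prv))) {
      dropped <- dropped + 1L
      next
    }
    assign(a, links$hi[k], envir = nxt)
    assign(b, links$lo[k], envir = prv)
  }
  if (dropped) {
    message("trace_strands: ", dropped,
            " branching H-bond link(s) dropped in favour of shorter D...A")
  }
  # chain starts: molecules with a successor but no predecessor
  has_next <- ls(nxt)
  starts <- has_next[vapply(has_next, function(m) is.null(get0(m, envir = prv)),
                            logical(1))]
  strands <- list()
  for (s in starts) {
    chain <- as.integer(s)
    cur <- s
    repeat {
      nx <- get0(cur, envir = nxt)
      if (is.null(nx)) break
      chain <- c(chain, nx)
      cur <- as.character(nx)
    }
    strands[[length(strands) + 1L]] <- chain
  }
  if (!length(strands)) return(empty)
  # Periodic-image bookkeeping: walk each strand, shifting every molecule
  # to the lattice image nearest its predecessor's centroid, so strand
  # geometry (helix fits, axis points) is contiguous in Cartesian space;
  # then align whole strands by their fitted axis centres so strands of
  # one bundle share one axis rather than scattering across images.
  pos_u <- unwrap_molecules(structure)
  mol_rows <- split(seq_len(nrow(pos_u)), structure$atoms$molecule_id)
  cent_of <- function(m) colMeans(pos_u[mol_rows[[as.character(m)]], , drop = FALSE])
  for (chain in strands) {
    prev_c <- cent_of(chain[1])
    for (k in seq_along(chain)[-1]) {
      rows <- mol_rows[[as.character(chain[k])]]
      cur_c <- colMeans(pos_u[rows, , drop = FALSE])
      L <- prev_c + min_image(structure$cell, prev_c, cur_c)$disp - cur_c
      pos_u[rows, ] <- sweep(pos_u[rows, , drop = FALSE], 2, L, "+")
      prev_c <- cur_c + L
    }
  }
  perp <- diag(3) - tcrossprod(axis)
  strand_center <- function(mols) {
    p <- t(vapply(mols, cent_of, numeric(3))) %*% perp
    if (nrow(p) >= 4L) fit_circle_center(p, axis) else colMeans(p)
  }
  axis_pts <- t(vapply(strands, strand_center, numeric(3)))
  if (length(strands) > 1L) {
    for (s in seq_along(strands)[-1]) {
      L <- axis_pts[1, ] +
        min_image(structure$cell, axis_pts[1, ], axis_pts[s, ])$disp - axis_pts[s, ]
      rows <- unlist(mol_rows[as.character(strands[[s]])])
      pos_u[rows, ] <- sweep(pos_u[rows, , drop = FALSE], 2, L, "+")
      axis_pts[s, ] <- axis_pts[s, ] + L
    }
    # recompute after alignment
    axis_pts <- t(vapply(strands, strand_center, numeric(3)))
  }
  ns <- length(strands)
  helix_id <- seq_len(ns)
  if (ns > 1L) {
    d <- as.matrix(stats::dist(axis_pts))
    for (i in seq_len(ns - 1L)) for (j in seq(i + 1L, ns)) {
      if (d[i, j] <= merge_radius) {
        old <- helix_id[j]
        helix_id[helix_id == old] <- helix_id[i]
      }
    }
    helix_id <- as.integer(factor(helix_id, levels = unique(helix_id)))
  }
  structure(list(strands = strands, helix_id = helix_id, axis = axis,
                 axis_points = axis_pts, positions = pos_u),
            class = "strand_set")
}

# algebraic (Kasa) circle fit of points projected into the plane
# perpendicular to `axis`; returns the centre as a 3-vector in that plane
fit_circle_center <- function(p, axis) {
  e <- plane_basis(axis)
  uv <- p %*% cbind(e$e1, e$e2)
  A <- cbind(2 * uv[, 1], 2 * uv[, 2], 1)
  b <- uv[, 1]^2 + uv[, 2]^2
  sol <- tryCatch(qr.solve(A, b), error = function(e2) c(colMeans(uv), 0))
  sol[1] * e$e1 + sol[2] * e$e2
}

plane_basis <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(axis, e1)
  list(e1 = e1, e2 = e2)
}

#' H-bond rotation-angle profile along the stacking axis
#'
#' For every stacking layer, the signed angle between the projection of
#' the layer's H-bond vector (donor to acceptor) onto the plane
#' perpendicular to the axis and the projection of the reference H-bond in
#' the first (lowest) layer. Angles are counterclockwise-positive viewed
#' from the +axis tip, averaged on the circle per layer, and cumulatively
#' unwrapped (assumes the true twist is below 180 degrees/layer).
#'
#' When a `strand_set` is supplied the profile is computed per strand
#' (reference: that strand's first-layer bond, the shortest D...A one) and
#' the per-layer angles are then averaged across strands; otherwise all
#' bonds of a layer are pooled.
#'
#' @param hbonds `hbond_table`; typically pre-filtered to the main-chain
#'   main-chain bonds that define the twist (see
#'   [filter_hbonds_by_group()]).
#' @param structure the `xtal`.
#' @param layers a [assign_layers()] result.
#' @param strands optional `strand_set` from [trace_strands()].
#' @param axis unit vector; default the layer-assignment axis.
#' @return data.frame of class `rotation_profile`: `layer`, `theta`
#'   (degrees, `theta[1] = 0`), `n_bonds`, `spread` (SD of the azimuth
#'   increment into each layer across strands, degrees), `interpolated`
#'   (`TRUE` where a missing transition was filled with the mean
#'   increment); attribute `axis`.
#' @export
rotation_profile <- function(hbonds, structure, layers, strands = NULL,
                             axis = NULL) {
  stopifnot(is_xtal(structure))
  if (is.null(axis)) axis <- attr(layers, "axis")
  axis <- axis / sqrt(sum(axis^2))
  if (is.null(hbonds) || !nrow(hbonds)) {
    stop("rotation_profile: no H-bonds supplied")
  }
  lay <- stats::setNames(layers$layer, layers$molecule_id)
  # restrict to bonds between consecutive layers: these are the
  # strand-forming bonds whose azimuth advances one twist step per layer
  # (this also drops bonds wrapping around a periodic boundary)
  dl <- abs(lay[as.character(hbonds$donor_molecule)] -
              lay[as.character(hbonds$acceptor_molecule)])
  hbonds <- hbonds[!is.na(dl) & dl == 1L, , drop = FALSE]
  if (!nrow(hbonds)) stop("rotation_profile: no consecutive-layer H-bonds")
  pos <- coords(structure)
  eb <- plane_basis(axis)
  # projected, signed azimuth of each bond vector
  bvec <- t(vapply(seq_len(nrow(hbonds)), function(k) {
    min_image(structure$cell, pos[hbonds$donor[k], ], pos[hbonds$acceptor[k], ])$disp
  }, numeric(3)))
  u <- drop(bvec %*% eb$e1); v <- drop(bvec %*% eb$e2)
  planar <- sqrt(u^2 + v^2)
  ok <- planar > 1e-6
  if (any(!ok)) warning(sum(!ok), " H-bond(s) parallel to the axis skipped")
  hb <- hbonds[ok, , drop = FALSE]
  az <- atan2(v[ok], u[ok]) * 180 / pi
  bond_layer <- pmin(lay[as.character(hb$donor_molecule)],
                     lay[as.character(hb$acceptor_molecule)])
  if (!is.null(strands) && length(strands$strands)) {
    mol2strand <- integer(0)
    for (s in seq_along(strands$strands)) {
      mol2strand[as.character(strands$strands[[s]])] <- s
    }
    bond_strand <- mol2strand[as.character(hb$donor_molecule)]
    miss <- is.na(bond_strand)
    bond_strand[miss] <- mol2strand[as.character(hb$acceptor_molecule[miss])]
  } else {
    bond_strand <- rep(1L, nrow(hb))
  }
  keep <- !is.na(bond_strand) & !is.na(bond_layer)
  hb <- hb[keep, , drop = FALSE]
  az <- az[keep]; bond_layer <- bond_layer[keep]; bond_strand <- bond_strand[keep]
  if (!nrow(hb)) stop("rotation_profile: no usable H-bonds after filtering")
  # per (strand, layer) circular-mean azimuth, then per layer transition
  # the azimuth increment within each strand. Increments are reference-free,
  # so partial strands (thermal breaks) still contribute; the profile is
  # their cumulative sum from the first layer, which for a single intact
  # strand reduces to the angle from the first-layer reference bond.
  key <- paste(bond_strand, bond_layer)
  az_sl <- tapply(az, key, circ_mean_deg)
  sl <- do.call(rbind, strsplit(names(az_sl), " "))
  tab <- data.frame(strand = as.integer(sl[, 1]), layer = as.integer(sl[, 2]),
                    az = as.numeric(az_sl))
  all_layers <- seq(min(tab$layer), max(tab$layer))
  incs <- vector("list", length(all_layers) - 1L)
  for (s in unique(tab$strand)) {
    st <- tab[tab$strand == s, ]
    st <- st[order(st$layer), ]
    dl <- diff(st$layer)
    dd <- diff(st$az)
    dd <- (dd + 180) %% 360 - 180
    for (k in which(dl == 1L)) {
      idx <- st$layer[k] - all_layers[1] + 1L
      incs[[idx]] <- c(incs[[idx]], dd[k])
    }
  }
  n_inc <- lengths(incs)
  if (!any(n_inc > 0)) stop("rotation_profile: no consecutive-layer azimuth increments")
  inc_mean <- vapply(incs, function(v) if (length(v)) circ_mean_deg(v) else NA_real_,
                     numeric(1))
  inc_sd <- vapply(incs, function(v) if (length(v) > 1L) stats::sd((v - circ_mean_deg(v) + 180) %% 360 - 180) else 0,
                   numeric(1))
  filled <- is.na(inc_mean)
  inc_mean[filled] <- circ_mean_deg(unlist(incs))
  theta <- c(0, cumsum(inc_mean))
  nb <- vapply(all_layers, function(L) sum(bond_layer == L), integer(1))
  out <- data.frame(layer = all_layers, theta = theta, n_bonds = nb,
                    spread = c(0, inc_sd), interpolated = c(FALSE, filled))
  attr(out, "axis") <- axis
  class(out) <- c("rotation_profile", "data.frame")
  out
}

# circular mean of angles in degrees
circ_mean_deg <- function(a) {
  r <- a * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

# cumulative nearest-branch unwrapping of a degree series (NA gaps kept)
unwrap_deg <- function(th) {
  out <- th
  idx <- which(!is.na(th))
  if (length(idx) < 2L) return(out)
  for (k in seq(2L, length(idx))) {
    i0 <- idx[k - 1L]; i1 <- idx[k]
    d <- th[i1] - out[i0]
    d <- (d + 180) %% 360 - 180
    out[i1] <- out[i0] + d
  }
  out
}

#' Classify the supramolecular twist from a rotation profile
#'
#' Least-squares slope of the unwrapped angle versus layer index: a slope
#' below `-threshold` degrees/layer is a clockwise rotation along the axis
#' and is called S; above `+threshold`, Z; in between, undetermined.
#'
#' @param profile a [rotation_profile()] (needs >= 3 layers with data).
#' @param threshold degrees/layer.
#' @return list of class `twist_call`: `verdict` (`"S"`, `"Z"`,
#'   `"undetermined"`), `slope`, `slope_stderr`, `threshold`.
#' @export
classify_twist <- function(profile, threshold = 1.0) {
  stopifnot(inherits(profile, "data.frame"))
  ok <- !is.na(profile$theta)
  if (sum(ok) < 3L) stop("classify_twist: need >= 3 layers with angles")
  fit <- stats::lm(theta ~ layer, data = profile[ok, ])
  slope <- unname(stats::coef(fit)[2])
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[2, 2]),
                 error = function(e) NA_real_)
  verdict <- if (slope < -threshold) "S" else if (slope > threshold) "Z" else "undetermined"
  structure(list(verdict = verdict, slope = slope, slope_stderr = se,
                 threshold = threshold), class = "twist_call")
}

#' @export
print.twist_call <- function(x, ...) {
  cat(sprintf("twist: %s (slope %.3f +/- %.3f deg/layer, threshold %.2f)\n",
              x$verdict, x$slope, ifelse(is.na(x$slope_stderr), 0, x$slope_stderr),
              x$threshold))
  invisible(x)
}

#' Fit a circular helix to an ordered point sequence
#'
#' Initializes the axis from the principal component of the points, the
#' radius and centre from a circle fit in the perpendicular plane, and the
#' per-step twist/rise from consecutive differences, then refines all
#' parameters jointly by nonlinear least squares. The axis is oriented so
#' the rise per step is positive; handedness is then right-handed (Z) for
#' a positive angular step and left-handed (S) for a negative one.
#'
#' @param points Nx3 matrix of ordered positions (N >= 4).
#' @return list of class `helix_fit`: `axis_point`, `axis` (unit),
#'   `radius` (A), `delta_theta` (deg/step), `delta_z` (A/step), `pitch`
#'   (A), `handedness` (`"S"`/`"Z"`), `rms_residual` (A), `phase` (deg).
#' @export
fit_helix <- function(points) {
  p <- as_coord_matrix(points)
  n <- nrow(p)
  if (n < 4L) stop("fit_helix: need at least 4 ordered points")
  pc <- stats::prcomp(p)
  if (pc$sdev[2] < 1e-8) stop("fit_helix: degenerate helix (collinear points)")
  axis <- pc$rotation[, 1]
  i <- seq_len(n)
  proj <- drop(sweep(p, 2, colMeans(p)) %*% axis)
  if (stats::cov(proj, i) < 0) axis <- -axis
  lin <- function(y) {           # fast least-squares line y ~ i
    b <- stats::cov(y, i) / stats::var(i)
    c(mean(y) - b * mean(i), b)
  }
  # Profiled objective: for a trial axis direction all remaining helix
  # parameters (circle centre and radius, phase, twist/rise per step) have
  # closed-form estimates; optimizing the axis alone makes the joint
  # nonlinear fit a cheap 2-parameter problem, then a short full
  # refinement polishes everything.
  eval_axis <- function(sph, return_fit = FALSE) {
    ax <- c(sin(sph[1]) * cos(sph[2]), sin(sph[1]) * sin(sph[2]), cos(sph[1]))
    e <- plane_basis(ax)
    u <- drop(p %*% e$e1); v <- drop(p %*% e$e2); z <- drop(p %*% ax)
    A <- cbind(2 * u, 2 * v, 1)
    sol <- tryCatch(qr.solve(A, u^2 + v^2), error = function(e2) c(mean(u), mean(v), 0))
    cu <- sol[1]; cv <- sol[2]
    r0 <- sqrt(max(sol[3] + cu^2 + cv^2, 1e-12))
    az <- unwrap_deg(atan2(v - cv, u - cu) * 180 / pi)
    caz <- lin(az); cz <- lin(z)
    ang <- (caz[1] + caz[2] * i) * pi / 180
    sse <- sum((u - cu - r0 * cos(ang))^2 + (v - cv - r0 * sin(ang))^2 +
                 (z - cz[1] - cz[2] * i)^2)
    if (!return_fit) return(sse)
    list(sse = sse, sph = sph, cen = c(cu, cv), r = r0,
         phase = caz[1], dth = caz[2], z0 = cz[1], dz = cz[2])
  }
  sph0 <- c(acos(max(-1, min(1, axis[3]))), atan2(axis[2], axis[1]))
  opt_ax <- stats::optim(sph0, eval_axis, method = "Nelder-Mead",
                         control = list(maxit = 400, reltol = 1e-14))
  init <- eval_axis(opt_ax$par, return_fit = TRUE)
  # full joint refinement: axis polar/azimuth, centre (2), r, phase,
  # dtheta, z0, dz — model x_i = C + (z0 + i dz) u + r cos e1 + r sin e2
  par0 <- c(init$sph, init$cen, init$r, init$phase, init$dth, init$z0, init$dz)
  obj <- function(par) {
    ax <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
    e <- plane_basis(ax)
    u <- drop(p %*% e$e1); v <- drop(p %*% e$e2); z <- drop(p %*% ax)
    ang <- (par[6] + i * par[7]) * pi / 180
    sum((u - par[3] - par[5] * cos(ang))^2 +
          (v - par[4] - par[5] * sin(ang))^2 +
          (z - par[8] - i * par[9])^2)
  }
  opt <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  par <- opt$par
  ax <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
  e_fit <- plane_basis(ax)
  C <- par[3] * e_fit$e1 + par[4] * e_fit$e2
  r <- abs(par[5]); dth <- par[7]; dz <- par[9]
  if (dz < 0) { ax <- -ax; dz <- -dz; dth <- -dth }
  if (abs(dth) < 1e-12) stop("fit_helix: zero angular step (straight stack)")
  structure(list(
    axis_point = C,
    axis = ax, radius = r, delta_theta = dth, delta_z = dz,
    pitch = 360 / abs(dth) * dz,
    handedness = if (dth > 0) "Z" else "S",
    rms_residual = sqrt(opt$value / n), phase = par[6]
  ), class = "helix_fit")
}

#' @export
print.helix_fit <- function(x, ...) {
  cat(sprintf("helix: %s, radius %.3f A, pitch %.3f A (%.2f deg/step, rise %.3f A), rms %.4f A\n",
              x$handedness, x$radius, x$pitch, x$delta_theta, x$delta_z,
              x$rms_residual))
  invisible(x)
}

#' Circumcircle diameter of three points
#'
#' Diameter of the circle through three non-collinear points, computed in
#' the plane of the triangle (`abc / (2 * area)`). This is the paper-style
#' "inner diameter" when applied to the three Trp C-alpha atoms of one
#' stacking layer.
#'
#' @param p1,p2,p3 Cartesian points.
#' @return diameter in the units of the inputs.
#' @examples
#' circumcircle_diameter(c(0, 0, 0), c(10, 0, 0), c(5, 5 * sqrt(3), 0))
#' # equilateral, side 10: 2 * 10 / sqrt(3) = 11.547
#' @export
circumcircle_diameter <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  cc <- sqrt(sum((p1 - p2)^2))
  cr <- pracma_cross(p2 - p1, p3 - p1)
  area2 <- sqrt(sum(cr^2))          # 2 * triangle area
  if (area2 < 1e-9 * a * b) stop("circumcircle_diameter: collinear points")
  a * b * cc / area2
}

#' Filter an H-bond table by donor/acceptor group
#'
#' @param hbonds `hbond_table`.
#' @param groups factor from [assign_groups()].
#' @param donor_group,acceptor_group group labels (default the
#'   twist-defining Trp main-chain bonds, W_mc-W_mc).
#' @return the filtered `hbond_table`.
#' @export
filter_hbonds_by_group <- function(hbonds, groups, donor_group = "W_mc",
                                   acceptor_group = "W_mc") {
  keep <- groups[hbonds$donor] %in% donor_group &
    groups[hbonds$acceptor] %in% acceptor_group
  hbonds[keep, , drop = FALSE]
}

#' End-to-end triple-helix metrics for a structure
#'
#' Driver for the full chirality analysis: optional supercell, group
#' assignment, layer assignment, H-bond detection, main-chain bond
#' filtering, strand tracing, per-strand helix fits, the rotation-angle
#' profile with its S/Z twist call, and per-layer C-alpha inner diameters.
#'
#' @param structure an `xtal`.
#' @param supercell integer triple; `c(1, 1, 1)` analyzes the input as is.
#' @param axis helix axis; default crystallographic c.
#' @param group_table group table for [assign_groups()]; `NULL` skips the
#'   main-chain filter and uses all intermolecular H-bonds.
#' @param criteria [hbond_criteria()].
#' @param twist_threshold degrees/layer, see [classify_twist()].
#' @param gap_tol layer gap tolerance, see [assign_layers()].
#' @param trace_angle_min D-H...A angle floor (degrees) for the bonds used
#'   to trace strand connectivity and the rotation profile. Thermal
#'   disorder bends individual H-bonds below the strict 150-degree
#'   statistic without breaking the strand, so connectivity uses a relaxed
#'   floor by default; the reported H-bond table always uses the strict
#'   `criteria`.
#' @param ca_name,ca_residue atom name/residue pattern of the C-alpha
#'   marker used for the inner diameter.
#' @param fit_strands run the per-strand helix fits (disable to get only
#'   the twist call and diameters, e.g. in large screens).
#' @return list of class `triple_helix_metrics`: `twist` (a `twist_call`),
#'   `profile`, `strands`, `helix_fits`, `pitch`, `radius`,
#'   `diameter_axis` (2x mean strand radius), `inner_diameters` (per
#'   bundle/layer data.frame), `inner_diameter` (mean), `n_strands`,
#'   `n_layers`, `hbonds`.
#' @export
triple_helix_metrics <- function(structure, supercell = c(1L, 1L, 1L),
                                 axis = NULL, group_table = default_group_table(),
                                 criteria = hbond_criteria(),
                                 twist_threshold = 1.0, gap_tol = NULL,
                                 trace_angle_min = 90,
                                 ca_name = "^CA$", ca_residue = "TRP",
                                 fit_strands = TRUE) {
  stopifnot(is_xtal(structure))
  s <- if (any(supercell != 1L)) build_supercell(structure, supercell) else structure
  layers <- assign_layers(s, axis = axis, gap_tol = gap_tol)
  hb <- detect_hbonds(s, criteria)
  crit_trace <- criteria
  crit_trace$dha_angle_min <- min(criteria$dha_angle_min, trace_angle_min)
  hb_mc <- detect_hbonds(s, crit_trace)
  if (!is.null(group_table)) {
    groups <- suppressWarnings(assign_groups(s, group_table))
    flt <- filter_hbonds_by_group(hb_mc, groups)
    if (nrow(flt)) hb_mc <- flt
  }
  strands <- trace_strands(hb_mc, s, layers)
  # fit only substantial strands: a 4-point fragment has barely more
  # coordinates than the helix model has parameters
  min_fit_len <- max(4L, floor(0.6 * max(c(0L, lengths(strands$strands)))))
  fits <- list(); fit_len <- integer()
  if (!fit_strands) min_fit_len <- Inf
  for (mols in strands$strands) {
    if (length(mols) >= min_fit_len) {
      rows <- split(seq_len(nrow(s$atoms)), s$atoms$molecule_id)[as.character(mols)]
      cen <- t(vapply(rows, function(ix) {
        colMeans(strands$positions[ix, , drop = FALSE])
      }, numeric(3)))
      f <- tryCatch(fit_helix(cen), error = function(e) NULL)
      if (!is.null(f)) {
        fits[[length(fits) + 1L]] <- f
        fit_len <- c(fit_len, length(mols))
      }
    }
  }
  # discard fits the helix model cannot describe (residual far above the
  # thermal noise floor, e.g. a too-short fragment collapsing to a line)
  if (length(fits)) {
    res <- vapply(fits, `[[`, numeric(1), "rms_residual")
    keep <- res <= pmax(0.5, 5 * min(res))
    fits <- fits[keep]; fit_len <- fit_len[keep]
  }
  wmean <- function(field) {
    if (!length(fits)) return(NA_real_)
    stats::weighted.mean(vapply(fits, `[[`, numeric(1), field), fit_len)
  }
  pitch <- wmean("pitch")
  radius <- wmean("radius")
  twist <- NULL; prof <- NULL
  if (nrow(hb_mc)) {
    prof <- tryCatch(rotation_profile(hb_mc, s, layers, strands = strands),
                     error = function(e) NULL)
    if (!is.null(prof)) {
      twist <- tryCatch(classify_twist(prof, twist_threshold), error = function(e) NULL)
    }
  }
  if (is.null(twist)) {
    twist <- structure(list(verdict = "undetermined", slope = NA_real_,
                            slope_stderr = NA_real_, threshold = twist_threshold),
                       class = "twist_call")
  }
  inner <- inner_diameter_series(s, layers, strands, ca_name, ca_residue)
  structure(list(
    twist = twist, profile = prof, strands = strands, helix_fits = fits,
    pitch = pitch, radius = radius,
    diameter_axis = 2 * radius,
    inner_diameters = inner,
    inner_diameter = if (nrow(inner)) mean(inner$diameter) else NA_real_,
    n_strands = length(strands$strands),
    n_layers = length(unique(layers$layer)),
    hbonds = hb
  ), class = "triple_helix_metrics")
}

#' @export
print.triple_helix_metrics <- function(x, ...) {
  print(x$twist)
  cat(sprintf("strands: %d over %d layers; pitch %.3f A, strand radius %.3f A\n",
              x$n_strands, x$n_layers, x$pitch, x$radius))
  cat(sprintf("inner (C-alpha circle) diameter %.3f A; 2 x strand radius %.3f A\n",
              x$inner_diameter, x$diameter_axis))
  invisible(x)
}

# per-bundle, per-layer C-alpha circumcircle diameters
inner_diameter_series <- function(structure, layers, strands,
                                  ca_name = "^CA$", ca_residue = "TRP") {
  at <- structure$atoms
  out <- data.frame(helix_id = integer(), layer = integer(), diameter = numeric())
  if (!length(strands$strands)) return(out)
  pos <- strands$positions
  if (is.null(pos)) pos <- unwrap_molecules(structure)
  lay <- stats::setNames(layers$layer, layers$molecule_id)
  mol2helix <- integer(0)
  for (s in seq_along(strands$strands)) {
    mol2helix[as.character(strands$strands[[s]])] <- strands$helix_id[s]
  }
  ca_rows <- which(grepl(ca_name, at$name) & grepl(ca_residue, at$residue, ignore.case = TRUE))
  if (!length(ca_rows)) return(out)
  hx <- mol2helix[as.character(at$molecule_id[ca_rows])]
  ly <- lay[as.character(at$molecule_id[ca_rows])]
  ok <- !is.na(hx) & !is.na(ly)
  ca_rows <- ca_rows[ok]; hx <- hx[ok]; ly <- ly[ok]
  for (h in unique(hx)) for (L in unique(ly[hx == h])) {
    rows <- ca_rows[hx == h & ly == L]
    if (length(rows) != 3L) next
    d <- tryCatch(circumcircle_diameter(pos[rows[1], ], pos[rows[2], ], pos[rows[3], ]),
                  error = function(e) NA_real_)
    if (!is.na(d)) out <- rbind(out, data.frame(helix_id = h, layer = L, diameter = d))
  }
  out[order(out$helix_id, out$layer), , drop = FALSE]
}
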