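# Synthetic ground-truth generators: seeded triple-helix structures,
# jitter trajectories and mechanical curves. Every generated object
# carries a ground-truth record so analysis results can be checked
# exactly.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), -sin(r), 0, sin(r), cos(r), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Synthetic triple-helix specification
#'
#' Parameters of the rigid-molecule helical lattice emulated by
#' [gen_triple_helix()]: `n_strands` strands wind about a common axis,
#' molecule `(s, n)` sitting at azimuth `phi0 + 360 s / n_strands +
#' n * delta_theta`, height `n * delta_z`, with the molecule rotated about
#' the axis by its azimuth so donor-to-acceptor vectors co-rotate. The
#' handedness is the sign of `delta_theta` (negative = S), the pitch is
#' `360 / |delta_theta| * delta_z`.
#'
#' @param n_strands strands per bundle (3 for a triple helix).
#' @param delta_theta twist per layer, degrees (sign = handedness).
#' @param delta_z rise per layer, Angstrom (> 0).
#' @param radius helix radius of the donor N atom, Angstrom.
#' @param n_layers layers per strand.
#' @param d_no zero-jitter donor-acceptor N...O distance, Angstrom.
#' @param ca_radius radius of the C-alpha marker (inner-diameter probe);
#'   must lie within 1.47 A of `radius`.
#' @param decorations subset of `c("ring", "pro")`: attach the planar
#'   indole ring (horizontal, stacking along the axis) and/or the compact
#'   proline-like cluster. The core (N, H, C-alpha, carbonyl C, O and
#'   chain linkers) is always present.
#' @param bundle_spacing,n_bundles hexagonal bundle lattice: centre
#'   distance (A) and bundle count (1, or 3/7 for a hexagonal patch).
#' @param jitter Gaussian coordinate noise SD, Angstrom.
#' @param include_water add a water oxygen near the bundle core in every
#'   layer.
#' @param phi0 azimuth of strand 0 at layer 0, degrees.
#' @param seed RNG seed for the jitter (single RNG per generator call).
#' @return list of class `helix_spec`.
#' @export
helix_spec <- function(n_strands = 3L, delta_theta = -20, delta_z = 3.0,
                       radius = 7.8, n_layers = 8L, d_no = 2.9,
                       ca_radius = radius + 1.0, decorations = c("ring"),
                       bundle_spacing = 16, n_bundles = 1L, jitter = 0,
                       include_water = FALSE, phi0 = 0, seed = 1L) {
  stopifnot(n_strands >= 1L, delta_z > 0, radius > 0, n_layers >= 2L,
            d_no > 0, jitter >= 0)
  if (abs(delta_theta) < 1e-9) stop("helix_spec: delta_theta must be nonzero")
  if (abs(ca_radius - radius) > 1.47) {
    stop("helix_spec: ca_radius must lie within 1.47 A of radius")
  }
  structure(as.list(environment()), class = "helix_spec")
}

# ---- rigid molecule template ----------------------------------------------
# Atom positions in the rotating frame of a molecule at azimuth 0, layer 0.
# The acceptor O (and its carbonyl C) are placed so that the molecule one
# layer up (rotated by delta_theta, raised by delta_z) presents its O at
# exactly d_no from this molecule's donor N, collinear with the N-H bond.
cwp_template <- function(radius, delta_theta, delta_z, d_no = 2.9,
                         ca_radius = radius + 1.0,
                         decorations = c("ring", "pro")) {
  N <- c(radius, 0, 0)
  Nn <- drop(rot_z(delta_theta) %*% N) + c(0, 0, delta_z)
  dNN <- sqrt(sum((Nn - N)^2))
  if (dNN < d_no + 0.8) {
    stop("cwp_template: consecutive-layer N-N separation (",
         signif(dNN, 3), " A) leaves no room for the acceptor at d_no = ",
         d_no, " A; increase delta_z or |delta_theta|")
  }
  u <- (Nn - N) / dNN
  H <- N + 1.0 * u
  back <- function(p_global) drop(rot_z(-delta_theta) %*% (p_global - c(0, 0, delta_z)))
  O <- back(N + d_no * u)
  # carbonyl carbon: bonded to O, displaced inward but perpendicular to
  # the incoming H...O direction so it never crowds the donor hydrogen
  h_dir <- -drop(rot_z(-delta_theta) %*% u)
  c0 <- c(-1, 0, 0)
  cdir <- c0 - sum(c0 * h_dir) * h_dir
  if (sqrt(sum(cdir^2)) < 0.3) cdir <- pracma_cross(h_dir, c(0, 0, 1))
  cdir <- cdir / sqrt(sum(cdir^2))
  C <- O + 1.24 * cdir
  # C-alpha marker bonded to N at the requested radius, pointing away
  # from the up-facing N-H
  dx <- (ca_radius - radius) / 1.47
  CA <- N + 1.47 * c(dx, 0, -sqrt(max(0, 1 - dx^2)))
  atoms <- list(
    list("N", "N", N), list("H", "H", H), list("C", "C", C), list("O", "O", O),
    list("CA", "C", CA)
  )
  # chain linkers bridging CA..C so the molecule is one covalent unit
  g <- sqrt(sum((C - CA)^2))
  k <- max(0L, ceiling(g / 1.5) - 1L)
  if (k > 0L) {
    for (j in seq_len(k)) {
      atoms[[length(atoms) + 1L]] <-
        list(paste0("C", j), "C", CA + (j / (k + 1)) * (C - CA))
    }
  }
  if ("ring" %in% decorations) {
    ring <- indole_atoms()
    # embed the 2D indole in the horizontal plane of CA, extending
    # radially outward through the CB attachment
    for (r in ring) {
      atoms[[length(atoms) + 1L]] <-
        list(r$name, r$element,
             c(CA[1] + 1.54 + r$s, r$t, CA[3]))
    }
  }
  out <- do.call(rbind, lapply(atoms, function(a) {
    data.frame(name = a[[1]], element = a[[2]], residue = "TRP",
               x = a[[3]][1], y = a[[3]][2], z = a[[3]][3],
               stringsAsFactors = FALSE)
  }))
  if ("pro" %in% decorations) {
    out <- rbind(out, place_pro(out, C, delta_theta, delta_z))
  }
  out
}

# attach the proline-like cluster to the Trp carbonyl carbon in the
# direction that maximizes clearance from the neighbouring molecules of
# the same strand (the tight contacts in a stacked helix)
place_pro <- function(core, C_trp, delta_theta, delta_z) {
  corep <- as.matrix(core[, c("x", "y", "z")])
  nb_up <- sweep(corep %*% t(rot_z(delta_theta)), 2, c(0, 0, delta_z), "+")
  nb_dn <- sweep(corep %*% t(rot_z(-delta_theta)), 2, c(0, 0, -delta_z), "+")
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(dirs^2) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  best <- NULL; best_clear <- -Inf
  for (k in seq_len(nrow(dirs))) {
    u <- dirs[k, ]
    pro <- pro_atoms_along(C_trp, u)
    prop <- as.matrix(pro[, c("x", "y", "z")])
    neigh <- rbind(nb_up, nb_dn,
                   sweep(prop %*% t(rot_z(delta_theta)), 2, c(0, 0, delta_z), "+"),
                   sweep(prop %*% t(rot_z(-delta_theta)), 2, c(0, 0, -delta_z), "+"))
    dmin <- min(sqrt(pmax(outer(rowSums(prop^2), rowSums(neigh^2), "+") -
                            2 * prop %*% t(neigh), 0)))
    # also keep clear of the own-molecule core except the bonded carbon
    own <- sqrt(pmax(outer(rowSums(prop^2), rowSums(corep^2), "+") -
                       2 * prop %*% t(corep), 0))
    own_min <- min(own[-1, , drop = FALSE][, core$name != "C", drop = FALSE], Inf)
    score <- min(dmin, own_min)
    if (score > best_clear) { best_clear <- score; best <- pro }
  }
  if (best_clear < 1.55) {
    stop("cwp_template: no clash-free placement for the proline cluster; ",
         "drop the 'pro' decoration or open the helix geometry")
  }
  best
}

pro_atoms_along <- function(C_trp, u) {
  w <- c(0, 0, 1)
  if (abs(sum(u * w)) > 0.9) w <- c(1, 0, 0)
  w <- w - sum(u * w) * u; w <- w / sqrt(sum(w^2))
  p2 <- pro_atoms_2d()
  origin <- C_trp + 1.33 * u
  do.call(rbind, lapply(names(p2), function(nm) {
    p <- origin + (p2[[nm]][1]) * u + p2[[nm]][2] * w
    data.frame(name = nm, element = substr(nm, 1, 1), residue = "PRO",
               x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
  }))
}

# planar indole (fused 5+6 ring) in attachment coordinates: CB at the
# origin, the CB -> ring direction along +s; regular polygon geometry with
# 1.40 A aromatic bonds
indole_atoms <- function() {
  hexc <- c(0, 0)
  hx <- function(deg) 1.40 * c(cos(deg * pi / 180), sin(deg * pi / 180))
  pos <- list(
    CE2 = hx(150), CZ2 = hx(90), CH2 = hx(30), CZ3 = hx(330),
    CE3 = hx(270), CD2 = hx(210)
  )
  pc <- c(-2.175, 0)   # pentagon centre sharing the CD2-CE2 edge
  p5 <- function(deg) pc + 1.191 * c(cos(deg * pi / 180), sin(deg * pi / 180))
  pos$NE1 <- p5(108); pos$CD1 <- p5(180); pos$CG <- p5(252)
  pos$HE1 <- pos$NE1 + 1.01 * c(cos(108 * pi / 180), sin(108 * pi / 180))
  CB <- pos$CG + 1.51 * c(cos(252 * pi / 180), sin(252 * pi / 180))
  # re-express: CB at origin, CB -> hexagon centre along +s
  d <- hexc - CB; d <- d / sqrt(sum(d^2))
  R2 <- matrix(c(d[1], -d[2], d[2], d[1]), 2, 2)  # maps d to +s
  out <- lapply(names(pos), function(nm) {
    st <- drop(R2 %*% (pos[[nm]] - CB))
    list(name = nm, element = substr(nm, 1, 1), s = st[1], t = st[2])
  })
  c(list(list(name = "CB", element = "C", s = 0, t = 0)), out)
}

# compact proline-like cluster in 2D attachment coordinates: pyrrolidine
# pentagon + exocyclic carbonyl, its N at the origin, the ring extending
# along +s; N is listed first (it bonds to the Trp carbonyl carbon)
pro_atoms_2d <- function() {
  side <- 1.48
  R5 <- side / (2 * sin(36 * pi / 180))
  cen <- c(R5, 0)
  v <- function(deg) cen + R5 * c(cos(deg * pi / 180), sin(deg * pi / 180))
  p2 <- list(N = v(180), CA = v(108), CB = v(36), CG = v(-36), CD = v(-108))
  p2$C <- p2$CA + 1.52 * c(cos(108 * pi / 180), sin(108 * pi / 180))
  p2$O <- p2$C + 1.23 * c(cos(108 * pi / 180), sin(108 * pi / 180))
  lapply(p2, function(p) p - p2$N)
}

#' Generate a synthetic triple-helix structure with ground truth
#'
#' Builds the helical lattice described by a [helix_spec()]: rigid
#' molecules on `n_strands` interleaved helical strands (optionally
#' replicated on a hexagonal bundle lattice), consecutive layers linked by
#' a geometrically exact N-H...O hydrogen bond, optional core waters,
#' seeded Gaussian coordinate jitter. The cell is a padded orthorhombic
#' box (the structure is treated as a finite assembly, not a wrapped
#' crystal).
#'
#' @param spec a [helix_spec()].
#' @return list with `structure` (an `xtal`) and `truth`: handedness
#'   (`"S"`/`"Z"`), `pitch`, `radius` (N-atom helix), `centroid_radius`
#'   (molecule-centroid helix, the radius recovered by centroid-based
#'   fits), `ca_radius`, `delta_theta`, `delta_z`, `n_layers`,
#'   `n_strands`, `n_molecules`.
#' @export
gen_triple_helix <- function(spec = helix_spec()) {
  stopifnot(inherits(spec, "helix_spec"))
  tmpl <- cwp_template(spec$radius, spec$delta_theta, spec$delta_z,
                       spec$d_no, spec$ca_radius, spec$decorations)
  tpos <- as.matrix(tmpl[, c("x", "y", "z")])
  centers <- bundle_centers(spec$n_bundles, spec$bundle_spacing)
  rows <- list()
  mol <- 0L
  for (b in seq_len(nrow(centers))) {
    for (s in seq_len(spec$n_strands) - 1L) {
      for (n in seq_len(spec$n_layers) - 1L) {
        mol <- mol + 1L
        phi <- spec$phi0 + 360 * s / spec$n_strands + n * spec$delta_theta
        p <- tpos %*% t(rot_z(phi))
        p <- sweep(p, 2, c(centers[b, 1], centers[b, 2], n * spec$delta_z), "+")
        rows[[length(rows) + 1L]] <- data.frame(
          element = tmpl$element, name = tmpl$name, residue = tmpl$residue,
          resid = mol, molecule_id = mol,
          x = p[, 1], y = p[, 2], z = p[, 3], stringsAsFactors = FALSE
        )
      }
    }
    if (spec$include_water) {
      zc <- mean(tpos[, 3])
      for (n in seq_len(spec$n_layers) - 1L) {
        mol <- mol + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          element = "O", name = "OW", residue = "HOH", resid = mol,
          molecule_id = mol,
          x = centers[b, 1], y = centers[b, 2], z = n * spec$delta_z + zc,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  at <- do.call(rbind, rows)
  at$atom_id <- seq_len(nrow(at))
  cell <- pad_cell(as.matrix(at[, c("x", "y", "z")]), pad = 30)
  # clash sanity is defined on the ideal (zero-jitter) geometry
  check_clashes(crystal_structure(at, cell, provenance = "",
                                  assign_molecules = FALSE))
  if (spec$jitter > 0) {
    at[, c("x", "y", "z")] <- with_seed(spec$seed, {
      as.matrix(at[, c("x", "y", "z")]) +
        matrix(stats::rnorm(3L * nrow(at), sd = spec$jitter), ncol = 3)
    })
  }
  st <- crystal_structure(at, cell, provenance = "synthetic triple helix",
                          assign_molecules = FALSE)
  tcen <- colMeans(tpos)
  truth <- list(
    handedness = if (spec$delta_theta < 0) "S" else "Z",
    pitch = 360 / abs(spec$delta_theta) * spec$delta_z,
    radius = spec$radius,
    centroid_radius = unname(sqrt(tcen[1]^2 + tcen[2]^2)),
    ca_radius = spec$ca_radius,
    delta_theta = spec$delta_theta, delta_z = spec$delta_z,
    n_layers = spec$n_layers, n_strands = spec$n_strands,
    n_molecules = spec$n_strands * spec$n_layers * nrow(centers)
  )
  list(structure = st, truth = truth)
}

bundle_centers <- function(n_bundles, spacing) {
  if (n_bundles <= 1L) return(matrix(0, 1, 2))
  hexdirs <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2), c(-0.5, sqrt(3) / 2),
                   c(-1, 0), c(-0.5, -sqrt(3) / 2), c(0.5, -sqrt(3) / 2))
  hexdirs[seq_len(min(n_bundles, 7L)), , drop = FALSE] * spacing
}

# zero-jitter sanity: intermolecular atom pairs closer than 1.5 A are a
# template/spec error (within one rigid molecule the template is free to
# be compact)
check_clashes <- function(structure, limit = 1.5) {
  pr <- neighbor_pairs(structure$cell, coords(structure), limit)
  if (!nrow(pr)) return(invisible(TRUE))
  mol <- structure$atoms$molecule_id
  bad <- pr[mol[pr$i] != mol[pr$j], , drop = FALSE]
  if (nrow(bad)) {
    stop("synthetic structure has ", nrow(bad),
         " non-bonded contact(s) below ", limit, " A (closest ",
         signif(min(bad$dist), 3), " A); adjust the spec")
  }
  invisible(TRUE)
}

#' Mirror a structure through a plane containing the helix axis
#'
#' Reflects all Cartesian coordinates through the xz-plane (y -> -y). For
#' periodic structures the lattice must be invariant under this reflection
#' (orthorhombic cells, and hexagonal cells in the standard a-along-x
#' orientation, are); otherwise an error is raised. Symmetry-unexpanded
#' structures are expanded first. An exact isometry: all interatomic
#' distances are preserved and every twist verdict flips.
#'
#' @param structure an `xtal`.
#' @return the mirrored `xtal`.
#' @export
mirror_structure <- function(structure) {
  stopifnot(is_xtal(structure))
  if (length(structure$symmetry) > 1L) structure <- expand_symmetry(structure)
  cell <- structure$cell
  m <- cell$m
  S <- diag(c(1, -1, 1))
  # lattice must map onto itself under the reflection
  sm <- S %*% m
  fr <- cell$m_inv %*% sm
  if (max(abs(fr - round(fr))) > 1e-6) {
    stop("mirror_structure: lattice is not invariant under the xz-plane reflection")
  }
  p <- coords(structure) %*% S    # S symmetric
  structure$atoms[, c("x", "y", "z")] <- p
  structure$provenance <- paste0("mirror of: ", structure$provenance)
  structure
}

#' Jitter trajectory around a reference structure
#'
#' Frames are the reference coordinates plus iid Gaussian displacements of
#' SD `sigma` per coordinate, all from one seeded RNG; the cell is fixed.
#'
#' @param structure an `xtal`.
#' @param sigma displacement SD, Angstrom (`>= 0`).
#' @param n_frames frame count.
#' @param seed RNG seed.
#' @param dt frame spacing, ps.
#' @return a [trajectory()].
#' @export
gen_jitter_trajectory <- function(structure, sigma, n_frames, seed = 1L,
                                  dt = 10) {
  stopifnot(is_xtal(structure), sigma >= 0, n_frames >= 1L)
  ref <- coords(structure)
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(k) {
      if (k == 1L) ref else
        ref + matrix(stats::rnorm(length(ref), sd = sigma), ncol = 3)
    })
  })
  trajectory(frames, times = dt * (seq_len(n_frames) - 1L),
             cells = structure$cell, topology = structure)
}

#' Synthetic Hertz indentation curve with ground truth
#'
#' Forward model: before contact zero force; past the contact point the
#' measured force solves `F = (4/3) E/(1-nu^2) sqrt(R) ((z - z0) - F/k_c)^(3/2)`
#' (the cantilever deflection reduces the sample indentation). Seeded
#' multiplicative Gaussian noise is applied to the force.
#'
#' @param E sample modulus, Pa.
#' @param nu Poisson ratio.
#' @param R_tip tip radius, m.
#' @param delta_max maximum sample indentation, m.
#' @param k_c cantilever spring constant, N/m.
#' @param noise_frac multiplicative force noise SD.
#' @param seed RNG seed.
#' @param n points.
#' @param z0 true contact point, m.
#' @return list with `curve` (a [force_curve()]) and `truth`
#'   (`E`, `z0`, `stiffness` = F_max / delta_max).
#' @export
gen_indent_curve <- function(E, nu = 0.3, R_tip = 10e-9, delta_max = 20e-9,
                             k_c = 200, noise_frac = 0, seed = 1L,
                             n = 300L, z0 = 10e-9) {
  stopifnot(E > 0, R_tip > 0, delta_max > 0, noise_frac >= 0)
  pref <- (4 / 3) * E / (1 - nu^2) * sqrt(R_tip)
  F_max <- pref * delta_max^1.5
  z_max <- z0 + delta_max + F_max / k_c
  z <- seq(0, z_max, length.out = n)
  F <- vapply(z, function(zz) {
    if (zz <= z0) return(0)
    f <- function(Fi) pref * max(0, (zz - z0) - Fi / k_c)^1.5 - Fi
    stats::uniroot(f, c(0, pref * (zz - z0)^1.5 + 1e-12), tol = 1e-18)$root
  }, numeric(1))
  if (noise_frac > 0) {
    F <- with_seed(seed, F * (1 + stats::rnorm(n, sd = noise_frac)))
  }
  list(curve = force_curve(z, F, R_tip = R_tip, nu = nu, k_c = k_c),
       truth = list(E = E, z0 = z0, stiffness = F_max / delta_max))
}

#' Synthetic tensile stress-strain curve with ground truth
#'
#' Linear-elastic loading to brittle fracture: `sigma = E epsilon` up to
#' `fracture_strain`, with seeded multiplicative noise.
#'
#' @param modulus Young's modulus, Pa.
#' @param fracture_strain strain at fracture.
#' @param noise_frac multiplicative stress noise SD.
#' @param seed RNG seed.
#' @param n points.
#' @return list with `curve` (a [tensile_curve()]) and `truth` (`modulus`,
#'   `fracture_stress`, `fracture_strain`, `work_of_rupture` = the
#'   triangle area).
#' @export
gen_tensile_curve <- function(modulus, fracture_strain = 0.01,
                              noise_frac = 0, seed = 1L, n = 200L) {
  stopifnot(modulus > 0, fracture_strain > 0, noise_frac >= 0)
  eps <- seq(0, fracture_strain, length.out = n)
  sig <- modulus * eps
  if (noise_frac > 0) {
    sig <- with_seed(seed, sig * (1 + stats::rnorm(n, sd = noise_frac)))
    sig[1] <- 0
  }
  sf <- modulus * fracture_strain
  list(curve = tensile_curve(eps, sig),
       truth = list(modulus = modulus, fracture_stress = sf,
                    fracture_strain = fracture_strain,
                    work_of_rupture = 0.5 * sf * fracture_strain))
}
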