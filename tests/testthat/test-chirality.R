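# strand tracing, rotation profiles, twist classification, helix fitting

metrics_of <- function(structure, ...) {
  suppressMessages(triple_helix_metrics(structure, ...))
}

test_that("strands follow the H-bond graph through the layers", {
  g <- gen_triple_helix(helix_spec(n_layers = 8, seed = 1))
  s <- g$structure
  layers <- assign_layers(s)
  hb <- detect_hbonds(s)
  # zero jitter: exactly one interlayer bond per molecule per strand
  expect_equal(nrow(hb), 3L * 7L)
  st <- trace_strands(hb, s, layers)
  expect_equal(length(st$strands), 3L)
  expect_true(all(lengths(st$strands) == 8L))
  expect_equal(length(unique(st$helix_id)), 1L)
  # no bonds -> no strands
  st0 <- trace_strands(hb[0, ], s, layers)
  expect_equal(length(st0$strands), 0L)
})

test_that("well-separated bundles get distinct helix ids", {
  g <- gen_triple_helix(helix_spec(n_layers = 6, seed = 2, n_bundles = 3L,
                                   bundle_spacing = 40,
                                   decorations = character(0)))
  s <- g$structure
  layers <- assign_layers(s)
  st <- trace_strands(detect_hbonds(s), s, layers)
  expect_equal(length(st$strands), 9L)
  expect_equal(length(unique(st$helix_id)), 3L)
})

test_that("the rotation profile reproduces a constructed twist", {
  g <- gen_triple_helix(helix_spec(delta_theta = -60, delta_z = 5.0,
                                   radius = 7, n_layers = 5, seed = 3,
                                   decorations = character(0)))
  s <- g$structure
  layers <- assign_layers(s)
  hb <- detect_hbonds(s)
  st <- trace_strands(hb, s, layers)
  pr <- rotation_profile(hb, s, layers, strands = st)
  expect_equal(pr$theta, c(0, -60, -120, -180), tolerance = 1e-8)
})

test_that("parallel bonds in every layer give a flat profile", {
  # five stacked molecules whose N-H points at the O of the molecule one
  # layer up; every bond vector shares one azimuth
  u <- c(0.49, 0, 0.87); u <- u / sqrt(sum(u^2))
  o_local <- 2.66 * u - c(0, 0, 3.5)
  rows <- list()
  for (k in 0:4) {
    rows[[k + 1]] <- make_atoms(c("N", "H", "O"),
                                x = c(0, u[1], o_local[1]),
                                y = c(0, u[2], o_local[2]),
                                z = 3.5 * k + c(0, u[3], o_local[3]),
                                residue = "TRP", name = c("N", "H", "O"),
                                molecule_id = rep(k + 1L, 3))
  }
  at <- do.call(rbind, rows); at$atom_id <- seq_len(nrow(at))
  s <- crystal_structure(at, big_box(), assign_molecules = FALSE)
  layers <- assign_layers(s, axis = c(0, 0, 1), gap_tol = 1.0)
  hb <- detect_hbonds(s)
  expect_equal(nrow(hb), 4L)
  pr <- rotation_profile(hb, s, layers)
  expect_equal(pr$theta, rep(0, 4), tolerance = 1e-9)
})

test_that("twist verdicts follow the sign convention", {
  mk <- function(theta) {
    structure(data.frame(layer = seq_along(theta) - 1L, theta = theta),
              class = c("rotation_profile", "data.frame"))
  }
  expect_equal(classify_twist(mk(c(0, -60, -120, -180)))$verdict, "S")
  expect_equal(classify_twist(mk(c(0, 60, 120, 180)))$verdict, "Z")
  expect_equal(classify_twist(mk(c(0, 0.1, -0.1, 0)), threshold = 1)$verdict,
               "undetermined")
  expect_error(classify_twist(mk(c(0, 1))), ">= 3")
})

test_that("helix fits recover constructed parameters and mirror exactly", {
  p <- t(sapply(0:9, function(n) {
    c(7.8 * cos(36 * n * pi / 180), 7.8 * sin(36 * n * pi / 180), 3.6 * n)
  }))
  f <- fit_helix(p)
  expect_equal(f$radius, 7.8, tolerance = 1e-6)
  expect_equal(f$pitch, 36.0, tolerance = 1e-6)
  expect_equal(f$handedness, "Z")
  expect_equal(f$delta_z, 3.6, tolerance = 1e-6)
  pm <- p; pm[, 2] <- -pm[, 2]
  fm <- fit_helix(pm)
  expect_equal(fm$handedness, "S")
  expect_equal(fm$radius, f$radius, tolerance = 1e-9)
  expect_equal(fm$pitch, f$pitch, tolerance = 1e-9)
  # collinear points are degenerate
  line <- cbind(1:6, 1:6, 1:6)
  expect_error(fit_helix(line), "degenerate")
  expect_error(fit_helix(p[1:3, ]), "at least 4")
})

test_that("jittered helix fits stay within 1% of truth", {
  # noise at the level seen by strand fits (molecule-centroid jitter:
  # sigma 0.1 A per atom over ~7 atoms -> ~0.04 A on the centroid)
  for (seed in 1:10) {
    set.seed(seed)
    r <- runif(1, 5, 9); dth <- 25; dz <- 3.5
    n <- 0:15
    p <- cbind(r * cos(dth * n * pi / 180), r * sin(dth * n * pi / 180), dz * n) +
      matrix(rnorm(48, sd = 0.04), ncol = 3)
    f <- fit_helix(p)
    expect_lt(abs(f$radius - r) / r, 0.01)
    expect_lt(abs(f$pitch - 360 / dth * dz) / (360 / dth * dz), 0.01)
  }
})

test_that("the circumcircle diameter has its closed forms", {
  s <- 10
  eq <- circumcircle_diameter(c(0, 0, 0), c(s, 0, 0), c(s / 2, s * sqrt(3) / 2, 0))
  expect_equal(eq, 2 * s / sqrt(3), tolerance = 1e-12)
  expect_equal(eq, 11.547, tolerance = 1e-3)
  # Thales: right triangle, hypotenuse = diameter
  expect_equal(circumcircle_diameter(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)), 5)
  # rigid rotation invariance
  R <- random_rotation(12)
  p1 <- c(1, 2, 3); p2 <- c(4, -1, 2); p3 <- c(0, 5, -2)
  expect_equal(circumcircle_diameter(drop(R %*% p1), drop(R %*% p2), drop(R %*% p3)),
               circumcircle_diameter(p1, p2, p3), tolerance = 1e-10)
  expect_error(circumcircle_diameter(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")
})

test_that("end-to-end metrics match generator ground truth", {
  g <- gen_triple_helix(helix_spec(delta_theta = -20, delta_z = 3.0,
                                   radius = 7.8, n_layers = 8, seed = 4))
  m <- metrics_of(g$structure)
  expect_equal(m$twist$verdict, "S")
  expect_equal(m$twist$slope, -20, tolerance = 1e-6)
  expect_equal(m$pitch, 54.0, tolerance = 1e-4)
  expect_equal(m$radius, g$truth$centroid_radius, tolerance = 1e-4)
  expect_equal(m$n_strands, 3L)
  expect_equal(m$n_layers, 8L)
  expect_equal(m$inner_diameter, 2 * g$truth$ca_radius, tolerance = 1e-4)
  # per-strand handedness agrees with the profile verdict
  for (f in m$helix_fits) expect_equal(f$handedness, m$twist$verdict)
})

test_that("twist calls and helix metrics are invariant under rigid motion", {
  g <- gen_triple_helix(helix_spec(n_layers = 6, seed = 5))
  m1 <- metrics_of(g$structure)
  R <- random_rotation(21)
  s2 <- transform_structure(g$structure, R, c(10, 4, -6))
  m2 <- metrics_of(s2, axis = drop(R %*% c(0, 0, 1)))
  expect_equal(m2$twist$verdict, m1$twist$verdict)
  expect_equal(m2$twist$slope, m1$twist$slope, tolerance = 1e-6)
  expect_equal(m2$pitch, m1$pitch, tolerance = 1e-6)
  expect_equal(m2$radius, m1$radius, tolerance = 1e-6)
  expect_equal(m2$inner_diameter, m1$inner_diameter, tolerance = 1e-6)
})

test_that("mirroring flips every classified twist exactly", {
  for (seed in 1:6) {
    set.seed(seed)
    dth <- sample(c(-1, 1), 1) * runif(1, 10, 80)
    g <- gen_triple_helix(helix_spec(delta_theta = dth, delta_z = 4.5,
                                     n_layers = 6, jitter = 0.05, seed = seed,
                                     decorations = character(0)))
    m <- metrics_of(g$structure)
    mm <- metrics_of(mirror_structure(g$structure))
    expect_equal(m$twist$verdict, g$truth$handedness)
    expect_equal(mm$twist$verdict, setdiff(c("S", "Z"), m$twist$verdict))
    expect_equal(mm$twist$slope, -m$twist$slope, tolerance = 1e-9)
  }
})

test_that("the synthetic crystal models reproduce the deposited-form geometry", {
  m <- metrics_of(synthetic_cwp_crystal("cLWLP"), supercell = c(1, 1, 3))
  expect_equal(m$twist$verdict, "S")
  expect_equal(m$twist$slope, -60, tolerance = 1e-6)
  expect_equal(m$inner_diameter, 15.698, tolerance = 1e-4)
  expect_equal(m$pitch, 6 * 10.8213 / 2, tolerance = 1e-4)  # the 6_3 screw pitch
  m2 <- metrics_of(synthetic_cwp_crystal("cDWLP"), supercell = c(1, 1, 3))
  expect_equal(m2$twist$verdict, "Z")
})
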