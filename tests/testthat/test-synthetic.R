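# the seeded ground-truth generators

test_that("molecule counts and ground truth follow the spec", {
  g <- gen_triple_helix(helix_spec(n_strands = 3, n_layers = 8, seed = 1))
  expect_equal(length(unique(g$structure$atoms$molecule_id)), 24L)
  expect_equal(g$truth$n_molecules, 24L)
  gw <- gen_triple_helix(helix_spec(n_strands = 3, n_layers = 8,
                                    include_water = TRUE, seed = 1))
  expect_equal(length(unique(gw$structure$atoms$molecule_id)), 24L + 8L)
  expect_equal(sum(gw$structure$atoms$residue == "HOH"), 8L)
  # pitch and handedness from the twist parameters
  g2 <- gen_triple_helix(helix_spec(delta_theta = -20, delta_z = 3.0, seed = 1))
  expect_equal(g2$truth$pitch, 54.0)
  expect_equal(g2$truth$handedness, "S")
  expect_equal(gen_triple_helix(helix_spec(delta_theta = 20, delta_z = 3.0,
                                           seed = 1))$truth$handedness, "Z")
})

test_that("zero jitter produces exactly one interlayer bond per molecule pair", {
  g <- gen_triple_helix(helix_spec(n_layers = 6, seed = 2))
  hb <- detect_hbonds(g$structure)
  expect_equal(nrow(hb), 3L * 5L)
  expect_true(all(abs(hb$da_distance - 2.9) < 1e-9))
  expect_true(all(abs(hb$dha_angle - 180) < 1e-5))
  # each donor molecule appears once
  expect_false(any(duplicated(hb$donor_molecule)))
})

test_that("geometrically impossible specs are rejected", {
  # rise too small: the acceptor would sit on the next donor
  expect_error(gen_triple_helix(helix_spec(delta_theta = -10, delta_z = 2.5,
                                           radius = 8.5)), "d_no|room")
  # overlapping bundles clash
  expect_error(gen_triple_helix(helix_spec(n_bundles = 2L, bundle_spacing = 3,
                                           decorations = character(0))),
               "contact")
  expect_error(helix_spec(delta_theta = 0), "nonzero")
  expect_error(helix_spec(ca_radius = 20), "ca_radius")
})

test_that("mirroring is an exact isometry and involution", {
  g <- gen_triple_helix(helix_spec(n_layers = 5, jitter = 0.1, seed = 3))
  s <- g$structure
  m <- mirror_structure(s)
  mm <- mirror_structure(m)
  expect_equal(as.matrix(mm$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]), tolerance = 1e-12)
  # all interatomic distances preserved
  i <- sample(nrow(s$atoms), 50); j <- sample(nrow(s$atoms), 50)
  d0 <- sqrt(rowSums((as.matrix(s$atoms[i, c("x", "y", "z")]) -
                        as.matrix(s$atoms[j, c("x", "y", "z")]))^2))
  d1 <- sqrt(rowSums((as.matrix(m$atoms[i, c("x", "y", "z")]) -
                        as.matrix(m$atoms[j, c("x", "y", "z")]))^2))
  expect_equal(d0, d1, tolerance = 1e-12)
})

test_that("jitter trajectories are seeded and statistically calibrated", {
  g <- gen_triple_helix(helix_spec(n_layers = 3, seed = 4))
  t1 <- gen_jitter_trajectory(g$structure, sigma = 0.2, n_frames = 5, seed = 11)
  t2 <- gen_jitter_trajectory(g$structure, sigma = 0.2, n_frames = 5, seed = 11)
  expect_identical(t1$frames, t2$frames)
  t3 <- gen_jitter_trajectory(g$structure, sigma = 0.2, n_frames = 5, seed = 12)
  expect_false(identical(t1$frames[[2]], t3$frames[[2]]))
  # sigma = 0: RMSD identically zero
  t0 <- gen_jitter_trajectory(g$structure, sigma = 0, n_frames = 4)
  expect_equal(rmsd_series(t0, superpose = FALSE), rep(0, 4))
  # per-atom RMS displacement approaches sigma * sqrt(3) (5% at 500 frames)
  tb <- gen_jitter_trajectory(g$structure, sigma = 0.1, n_frames = 500, seed = 13)
  ref <- tb$frames[[1]]
  disp <- vapply(tb$frames[-1], function(p) mean(rowSums((p - ref)^2)), numeric(1))
  expect_equal(sqrt(mean(disp)), 0.1 * sqrt(3), tolerance = 0.05)
})

test_that("synthetic curves invert through the analysis functions", {
  gt <- gen_tensile_curve(2e9, fracture_strain = 0.012, noise_frac = 0, seed = 1)
  tm <- tensile_metrics(gt$curve)
  expect_equal(tm$modulus, 2e9, tolerance = 1e-9)
  expect_equal(tm$fracture_stress, gt$truth$fracture_stress, tolerance = 1e-9)
  expect_equal(tm$work_of_rupture, gt$truth$work_of_rupture, tolerance = 1e-4)
  gi <- gen_indent_curve(5e9, noise_frac = 0, seed = 1)
  expect_lt(abs(hertz_fit(gi$curve)$E - 5e9) / 5e9, 1e-3)
  # seeded reproducibility
  a <- gen_tensile_curve(1e9, noise_frac = 0.02, seed = 7)
  b <- gen_tensile_curve(1e9, noise_frac = 0.02, seed = 7)
  expect_identical(a$curve$stress, b$curve$stress)
})

test_that("generator output survives structure round trips", {
  g <- gen_triple_helix(helix_spec(n_layers = 3, jitter = 0.05, seed = 5))
  tf <- tempfile(fileext = ".xyz")
  write_structure(g$structure, tf)
  s2 <- read_structure(tf, expand = FALSE)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(g$structure$atoms[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
})
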