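# H-bond, contact, FEL and RMSD analysis

collinear_fixture <- function(a_x) {
  at <- make_atoms(c("N", "H", "O"), c(0, 1.0, a_x), c(0, 0, 0), c(0, 0, 0),
                   molecule_id = c(1L, 1L, 2L))
  crystal_structure(at, big_box(), assign_molecules = FALSE)
}

test_that("the geometric H-bond criterion gates on distance and angle", {
  hb <- detect_hbonds(collinear_fixture(2.9))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$da_distance, 2.9)
  expect_equal(hb$dha_angle, 180)
  expect_false(hb$fallback)
  # beyond 3.5 A: no bond
  expect_equal(nrow(detect_hbonds(collinear_fixture(3.6))), 0L)
  # 140-degree D-H...A angle at 2.9 A: no bond
  ang <- 40 * pi / 180
  at <- make_atoms(c("N", "H", "O"),
                   c(0, 1.0, 1.0 + 1.93 * cos(ang)),
                   c(0, 0, 1.93 * sin(ang)), c(0, 0, 0),
                   molecule_id = c(1L, 1L, 2L))
  s <- crystal_structure(at, big_box(), assign_molecules = FALSE)
  d <- sqrt(sum((as.numeric(at[3, c("x", "y", "z")]))^2))
  expect_lt(d, 3.5)
  hb <- detect_hbonds(s)
  expect_equal(nrow(hb), 0L)
  expect_equal(nrow(detect_hbonds(s, hbond_criteria(dha_angle_min = 130))), 1L)
})

test_that("heavy-atom fallback accepts hydrogen-free water donors only", {
  at <- rbind(
    make_atoms(c("N", "H", "C", "O"), c(0, 1, 4, 5.2), c(0, 0, 0, 0),
               c(0, 0, 0, 0), residue = "TRP", molecule_id = rep(1L, 4)),
    make_atoms("O", 2.9, 0, 0, name = "OW", residue = "HOH", molecule_id = 2L)
  )
  at$atom_id <- seq_len(nrow(at))
  s <- crystal_structure(at, big_box(), assign_molecules = FALSE)
  hb <- detect_hbonds(s)
  fb <- hb[hb$fallback, ]
  expect_true(all(fb$donor == 5L))          # only the water O
  expect_true(any(fb$acceptor == 1L & fb$da_distance == 2.9))
  hb2 <- detect_hbonds(s, hbond_criteria(heavy_atom_fallback = FALSE))
  expect_false(any(hb2$fallback))
})

test_that("H-bond detection equals the brute-force oracle on random frames", {
  for (seed in 1:10) {
    s <- random_frame(n_mol = 40, seed = seed)
    expect_equal(hb_key(detect_hbonds(s)), hb_key(brute_hbonds(s)),
                 info = paste("seed", seed))
  }
})

test_that("contact cutoffs are element-pair specific", {
  two <- function(e1, e2, d) {
    at <- make_atoms(c(e1, e2), c(0, d), c(0, 0), c(0, 0),
                     molecule_id = c(1L, 2L))
    crystal_structure(at, big_box(), assign_molecules = FALSE)
  }
  expect_equal(nrow(cyclohelix:::frame_contacts(two("C", "C", 5.3))), 1L)
  expect_equal(nrow(cyclohelix:::frame_contacts(two("C", "N", 5.0))), 0L)
  expect_equal(nrow(cyclohelix:::frame_contacts(two("C", "N", 4.5))), 1L)
  expect_equal(nrow(cyclohelix:::frame_contacts(two("C", "H", 1.9))), 0L)
})

test_that("contact detection equals the brute-force oracle on random frames", {
  for (seed in 1:6) {
    s <- random_frame(n_mol = 30, seed = 100 + seed)
    got <- cyclohelix:::frame_contacts(s)
    got <- got[order(got$i, got$j), ]
    want <- brute_contacts(s)
    expect_equal(paste(got$i, got$j), paste(want$i, want$j),
                 info = paste("seed", seed))
    expect_equal(got$dist, want$dist, tolerance = 1e-9)
  }
})

test_that("a static trajectory gives binary probabilities and exact means", {
  s <- random_frame(n_mol = 20, seed = 42)
  grp <- factor(sample(c("W_mc", "W_aro", "P_sc"), nrow(s$atoms), replace = TRUE),
                levels = cyclohelix:::.group_levels)
  frames <- rep(list(as.matrix(s$atoms[, c("x", "y", "z")])), 3)
  cm <- contact_map(frames, s, grp, window = c(1, 3))
  expect_true(all(cm$probability %in% c(0, 1)))
  inst <- cyclohelix:::frame_contacts(s)
  gi <- as.integer(grp)
  expect_equal(sum(cm$mean_count) ,
               2 * nrow(inst) - sum(gi[inst$i] == gi[inst$j]))
  # symmetry of the map
  expect_equal(cm$mean_count, t(cm$mean_count))
  expect_equal(cm$probability, t(cm$probability))
  expect_error(contact_map(frames, s, grp, window = c(2, 5)), "window")
})

test_that("per-unit normalization is plain division", {
  expect_equal(per_unit(432, 216), 2)
  expect_equal(per_unit(0, 10), 0)
  expect_equal(per_unit(2 * 7.3, 4), 2 * per_unit(7.3, 4))
  expect_error(per_unit(1, 0), "n_cells")
})

test_that("free-energy landscapes Boltzmann-invert the bin probabilities", {
  # all mass in one bin: G = 0 there
  one <- free_energy_landscape(cbind(rep(5, 10), rep(20, 10)),
                               distance_breaks = c(0, 10),
                               angle_breaks = c(0, 45), temperature = 300)
  expect_equal(one$G[1, 1], 0)
  # two equal bins at 300 K: G = -RT ln 0.5 = 1.729 kJ/mol (RT = 2.4943)
  two <- free_energy_landscape(cbind(c(2, 2, 8, 8), c(10, 10, 10, 10)),
                               distance_breaks = c(0, 5, 10),
                               angle_breaks = c(0, 45), temperature = 300)
  expect_equal(8.3145e-3 * 300, 2.49435, tolerance = 1e-5)
  expect_equal(two$G[1, 1], 1.729, tolerance = 1e-3)
  expect_equal(two$G[2, 1], 1.729, tolerance = 1e-3)
  # exp(-G/RT) recovers P exactly on occupied bins
  set.seed(8)
  obs <- cbind(runif(500, 3, 9), runif(500, 0, 90))
  fel <- free_energy_landscape(obs, 10, 6, temperature = 300)
  P2 <- exp(-fel$G / (fel$R * fel$temperature))
  expect_equal(P2[!is.na(P2)], fel$P[fel$P > 0], tolerance = 1e-12)
  # the minimum of G sits at the most probable bin
  expect_equal(which.min(fel$G), which.max(fel$P))
  expect_error(free_energy_landscape(obs[0, , drop = FALSE]), "no observations")
})

test_that("RMSD series is zero for identity and removes rigid motion", {
  g <- gen_triple_helix(helix_spec(n_layers = 3, seed = 6))
  ref <- as.matrix(g$structure$atoms[, c("x", "y", "z")])
  shifted <- sweep(ref, 2, c(1, 0, 0), "+")
  traj <- trajectory(list(ref, ref, shifted), times = c(0, 1, 2),
                     cells = g$structure$cell, topology = g$structure)
  expect_equal(rmsd_series(traj, superpose = FALSE), c(0, 0, 1))
  expect_equal(rmsd_series(traj, superpose = TRUE), c(0, 0, 0), tolerance = 1e-9)
  # random rigid rotation+translation vanishes under superposition
  R <- random_rotation(77)
  moved <- sweep(ref %*% t(R), 2, c(5, -3, 2), "+")
  traj2 <- trajectory(list(ref, moved), times = c(0, 1),
                      cells = g$structure$cell, topology = g$structure)
  expect_equal(rmsd_series(traj2, superpose = TRUE)[2], 0, tolerance = 1e-6)
  # cross-check against the independent bio3d implementation
  got <- rmsd_series(traj2, superpose = TRUE)[2]
  want <- bio3d::rmsd(as.numeric(t(ref)), as.numeric(t(moved)), fit = TRUE)
  expect_equal(got, as.numeric(want), tolerance = 1e-4)
})
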