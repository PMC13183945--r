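# chemical-group assignment and aromatic-ring location

test_that("the default table partitions a cyclo-WP-style molecule", {
  g <- gen_triple_helix(helix_spec(n_layers = 2, seed = 1,
                                   decorations = c("ring", "pro")))
  s <- g$structure
  grp <- assign_groups(s)
  expect_equal(length(grp), nrow(s$atoms))
  # partition: every atom labelled, sizes sum to the atom count
  expect_equal(sum(table(grp)), nrow(s$atoms))
  at <- s$atoms
  expect_true(all(grp[at$name == "NE1"] == "W_NH"))
  expect_true(all(grp[at$name == "HE1"] == "W_NH"))
  expect_true(all(grp[at$name == "CD2" & at$residue == "TRP"] == "W_aro"))
  expect_true(all(grp[at$name == "CB" & at$residue == "TRP"] == "W_sc"))
  expect_true(all(grp[at$name == "N" & at$residue == "TRP"] == "W_mc"))
  expect_true(all(grp[at$name == "CA" & at$residue == "TRP"] == "W_mc"))
  expect_true(all(grp[at$residue == "PRO" & at$name == "CG"] == "P_sc"))
  expect_true(all(grp[at$residue == "PRO" & at$name == "CA"] == "P_mc"))
})

test_that("water atoms map to the water group", {
  at <- make_atoms("O", 1, 2, 3, name = "OW", residue = "HOH")
  s <- crystal_structure(at, big_box(), assign_molecules = FALSE)
  expect_equal(as.character(assign_groups(s)), "water")
})

test_that("an empty table labels everything other with a warning", {
  at <- make_atoms(c("C", "N"), c(0, 1.4), c(0, 0), c(0, 0))
  s <- crystal_structure(at, big_box(), assign_molecules = FALSE)
  expect_warning(grp <- assign_groups(s, table = NULL), "no group")
  expect_true(all(grp == "other"))
})

test_that("the shipped YAML table equals the in-code default", {
  path <- system.file("extdata", "cwp_groups.yaml", package = "cyclohelix")
  y <- read_group_table(path)
  expect_equal(y$groups, default_group_table())
  expect_equal(y$rings$kind, default_ring_definitions()$kind)
  expect_equal(y$rings$members, default_ring_definitions()$members)
})

test_that("a regular hexagon yields its centroid and a z normal", {
  ang <- seq(0, 300, by = 60) * pi / 180
  at <- make_atoms(rep("C", 6), 1.39 * cos(ang) + 4, 1.39 * sin(ang) - 2,
                   rep(1.5, 6),
                   name = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"),
                   residue = "TRP", molecule_id = rep(1L, 6))
  s <- crystal_structure(at, big_box(), assign_molecules = FALSE)
  rings <- suppressWarnings(find_rings(s))   # the 5-ring is absent here
  expect_equal(nrow(rings), 1L)
  expect_equal(c(rings$cx, rings$cy, rings$cz), c(4, -2, 1.5), tolerance = 1e-9)
  expect_equal(abs(rings$nz), 1, tolerance = 1e-9)
  expect_equal(rings$rms_plane, 0, tolerance = 1e-12)
})

test_that("an indole gives two rings per molecule, or one fused", {
  g <- gen_triple_helix(helix_spec(n_layers = 2, seed = 2))
  rings <- find_rings(g$structure)
  expect_equal(nrow(rings), 2L * 6L)        # 5- and 6-ring for 6 molecules
  expect_setequal(unique(rings$kind), c("indole5", "indole6"))
  fused <- find_rings(g$structure, fused = TRUE)
  expect_equal(nrow(fused), 6L)
  expect_true(all(lengths(fused$members) == 9L))
  # normals are unit vectors
  nn <- sqrt(rings$nx^2 + rings$ny^2 + rings$nz^2)
  expect_equal(nn, rep(1, nrow(rings)), tolerance = 1e-9)
})

test_that("ring centroids translate with the molecule", {
  g <- gen_triple_helix(helix_spec(n_layers = 2, seed = 3))
  r1 <- find_rings(g$structure)
  s2 <- g$structure
  s2$atoms[, c("x", "y", "z")] <- s2$atoms[, c("x", "y", "z")] +
    matrix(rep(c(1, 2, 3), each = nrow(s2$atoms)), ncol = 3)
  r2 <- find_rings(s2)
  expect_equal(as.matrix(r2[, c("cx", "cy", "cz")]),
               as.matrix(r1[, c("cx", "cy", "cz")]) +
                 matrix(rep(c(1, 2, 3), each = nrow(r1)), ncol = 3),
               tolerance = 1e-9)
})
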