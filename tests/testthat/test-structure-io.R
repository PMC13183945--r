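# structure and trajectory I/O: CIF/PDB/XYZ round trips, symmetry
# expansion, the fixture trajectory dialect

minimal_cif <- function(path, ops = "x,y,z",
                        atoms = c("N1 N MOL 0.10 0.20 0.30",
                                  "O1 O MOL 0.40 0.50 0.60")) {
  writeLines(c(
    "data_test",
    "_cell_length_a    10.0",
    "_cell_length_b    11.0",
    "_cell_length_c    12.0",
    "_cell_angle_alpha 90.0",
    "_cell_angle_beta  90.0",
    "_cell_angle_gamma 90.0",
    "loop_",
    "_space_group_symop_operation_xyz",
    sprintf("  '%s'", ops),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_residue",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    atoms
  ), path)
  path
}

test_that("a minimal P1 CIF parses to the stated cell and atoms", {
  tf <- minimal_cif(tempfile(fileext = ".cif"))
  s <- read_structure(tf)
  expect_s3_class(s, "xtal")
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$cell$a, 10.0)
  expect_equal(s$cell$b, 11.0)
  expect_equal(s$atoms$element, c("N", "O"))
  expect_equal(cart_to_frac(s$cell, c(s$atoms$x[1], s$atoms$y[1], s$atoms$z[1])),
               c(0.1, 0.2, 0.3), tolerance = 1e-6)
})

test_that("symmetry expansion yields one atom per non-coincident operator", {
  tf <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "_cell_length_a    10.0",
    "_cell_length_b    10.0",
    "_cell_length_c    12.0",
    "_cell_angle_alpha 90.0",
    "_cell_angle_beta  90.0",
    "_cell_angle_gamma 120.0",
    "loop_",
    "_space_group_symop_operation_xyz",
    "  'x,y,z'",
    "  '-y,x-y,z'",
    "  '-x+y,-x,z'",
    "  '-x,-y,z+1/2'",
    "  'y,-x+y,z+1/2'",
    "  'x-y,x,z+1/2'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "C1 C 0.31 0.07 0.11"
  ), tf)
  s <- read_structure(tf)
  expect_equal(nrow(s$atoms), 6L)
  # expanding an already-expanded structure adds nothing
  s2 <- expand_symmetry(s)
  expect_equal(nrow(s2$atoms), 6L)
})

test_that("symmetry operator strings parse rotation and translation", {
  op <- parse_symop("-y, x-y, z+1/2")
  expect_equal(op$rot, matrix(c(0, -1, 0, 1, -1, 0, 0, 0, 1), 3, 3, byrow = TRUE))
  expect_equal(op$trans, c(0, 0, 0.5))
  expect_error(parse_symop("x,y"), "malformed")
})

test_that("the packaged synthetic c-LWLP CIF reads back its lattice constants", {
  path <- system.file("extdata", "cLWLP_synthetic.cif", package = "cyclohelix")
  s <- read_structure(path)
  expect_equal(s$cell$a, 14.9474)
  expect_equal(s$cell$c, 10.8213)
  expect_equal(s$cell$gamma, 120)
  expect_equal(length(unique(s$atoms$molecule_id)), 6L)
})

test_that("write -> read round trips preserve coordinates per format", {
  g <- gen_triple_helix(helix_spec(n_layers = 3, seed = 5))
  s <- g$structure
  for (ext in c("cif", "xyz", "pdb")) {
    tf <- tempfile(fileext = paste0(".", ext))
    write_structure(s, tf)
    s2 <- read_structure(tf, expand = FALSE)
    expect_equal(nrow(s2$atoms), nrow(s$atoms))
    tol <- if (ext == "pdb") 2e-3 else 1e-3
    expect_lt(max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                        as.matrix(s$atoms[, c("x", "y", "z")]))), tol)
    expect_equal(s2$cell$a, s$cell$a, tolerance = 1e-2)
  }
})

test_that("a hexagonal cell survives the CIF round trip", {
  s <- synthetic_cwp_crystal("cLWLP", expand = FALSE)
  tf <- tempfile(fileext = ".cif")
  write_structure(s, tf)
  s2 <- read_structure(tf)
  expect_equal(s2$cell$a, s2$cell$b)
  expect_equal(s2$cell$gamma, 120)
  expect_equal(length(unique(s2$atoms$molecule_id)), 6L)
})

test_that("writing an empty structure or unknown format errors", {
  g <- gen_triple_helix(helix_spec(n_layers = 2, seed = 1))
  expect_error(write_structure(g$structure, tempfile(fileext = ".foo")),
               "unsupported")
  s <- g$structure
  s$atoms <- s$atoms[0, ]
  expect_error(write_structure(s, tempfile(fileext = ".xyz")), "empty")
})

test_that("trajectory round trips and validates", {
  g <- gen_triple_helix(helix_spec(n_layers = 3, seed = 2))
  traj <- gen_jitter_trajectory(g$structure, sigma = 0.1, n_frames = 3, seed = 9)
  tf <- tempfile(fileext = ".xyz")
  write_trajectory(traj, tf)
  traj2 <- read_trajectory(tf, topology = g$structure)
  expect_equal(length(traj2$frames), 3L)
  # bit-compatible at the written precision (1e-8 A)
  for (k in 1:3) expect_equal(traj2$frames[[k]], unname(traj$frames[[k]]),
                              tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(traj2$times, traj$times)
  # identical frames -> zero displacement
  traj0 <- gen_jitter_trajectory(g$structure, sigma = 0, n_frames = 3)
  expect_equal(max(abs(traj0$frames[[3]] - traj0$frames[[1]])), 0)
  # atom-count mismatch against a different topology
  small <- gen_triple_helix(helix_spec(n_layers = 2, seed = 2))$structure
  expect_error(read_trajectory(tf, topology = small), "atoms")
  # empty file has no frames
  empty <- tempfile(fileext = ".xyz")
  writeLines(character(0), empty)
  expect_error(read_trajectory(empty), "no frames")
})
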