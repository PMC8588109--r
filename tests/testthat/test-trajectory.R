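test_that("center of mass follows the mass-weighted mean", {
  # single atom: identity
  expect_equal(unname(center_of_mass(atoms_tbl(1, 2, 3))), c(1, 2, 3))
  # equal masses at +-1 on x: symmetry
  expect_equal(unname(center_of_mass(atoms_tbl(c(-1, 1), c(0, 0), c(0, 0)))),
               c(0, 0, 0))
  # masses 1 and 3 at 0 and 4: hand value sum(m r)/sum(m) = 12/4
  a <- atoms_tbl(c(0, 4), c(0, 0), c(0, 0), mass = c(1, 3))
  expect_equal(unname(center_of_mass(a)), c(3, 0, 0))
  expect_error(center_of_mass(atoms_tbl(1, 1, 1, mass = 0)), "zero")
  expect_error(center_of_mass(atoms_tbl(numeric(), numeric(), numeric())), "empty")
})

test_that("trajectory constructor enforces structural invariants", {
  m <- matrix(rnorm(9), 3)
  tr <- traj_from_coords(m)
  expect_s3_class(tr, "dendri_trajectory")
  expect_equal(n_frames(tr), 1)
  expect_equal(n_atoms(tr), 3)
  # non-finite positions rejected
  bad <- tibble::tibble(frame = 1, atom_id = 1, x = NaN, y = 0, z = 0)
  expect_error(new_trajectory(bad), "finite")
  # mismatched frame sizes rejected
  bad2 <- tibble::tibble(frame = c(1, 1, 2), atom_id = c(1, 2, 1),
                         x = 0, y = 0, z = 0)
  expect_error(new_trajectory(bad2), "atom counts")
  expect_error(new_trajectory(tibble::tibble(frame = 1, atom_id = 1, x = 0,
                                             y = 0, z = 0),
                              tibble::tibble(atom_id = 1, role = "wizard")),
               "unknown role")
})

test_that("xyz round-trip preserves positions, order and attributes", {
  tr <- gen_dendrimer(25, 1, terminal_count = 4, spacer_charge_sites = 3,
                      seed = 11)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tr, f)
  back <- read_configuration(f)
  expect_equal(back$frames$x, tr$frames$x, tolerance = 1e-5)
  expect_equal(back$frames$atom_id, tr$frames$atom_id)
  expect_equal(back$topology$charge, tr$topology$charge)
  expect_equal(back$topology$element, tr$topology$element)
  # multi-frame round trip
  m <- matrix(rnorm(9), 3)
  tr2 <- traj_from_coords(list(m, m + 1), box_edge = 5)
  f2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tr2, f2)
  back2 <- read_configuration(f2)
  expect_equal(n_frames(back2), 2)
  expect_equal(back2$box_edge, 5)
  expect_equal(back2$frames$z, tr2$frames$z, tolerance = 1e-5)
})

test_that("pdb coordinates are converted from Angstrom to nm", {
  lines <- c(
    "ATOM      1  N   ALA A   1      10.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       0.000   5.000   0.000  1.00  0.00           C",
    "END"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  tr <- read_configuration(f, "pdb")
  expect_equal(n_atoms(tr), 2)
  fr <- frame_atoms(tr, 1)
  expect_equal(fr$x[1], 1.0)   # 10 A -> 1 nm
  expect_equal(fr$y[2], 0.5)
  expect_equal(fr$element, c("N", "C"))
})

test_that("pdb reader agrees with bio3d on a fixture", {
  skip_if_not_installed("bio3d")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      10.000   2.500  -3.125  1.00  0.00           N",
    "ATOM      2  O   ALA A   1      -1.250   5.000   7.750  1.00  0.00           O",
    "END"), f)
  ours <- frame_atoms(read_configuration(f, "pdb"), 1)
  ref <- bio3d::read.pdb(f)
  expect_equal(as.vector(t(cbind(ours$x, ours$y, ours$z)) * 10),
               as.vector(ref$xyz))
})

test_that("gro reader parses fixed columns and flags inconsistent frames", {
  gro <- c(
    "demo t= 0.0",
    "    2",
    "    1ALA      N    1   1.000   2.000   3.000",
    "    1ALA      C    2   0.500   0.250   0.125",
    "   5.00000   5.00000   5.00000"
  )
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, f)
  tr <- read_configuration(f, "gro")
  expect_equal(frame_atoms(tr, 1)$x, c(1, 0.5))
  expect_equal(tr$box_edge, 5)
  # second frame with a different atom count is a structural error
  gro2 <- c(gro, "demo t= 1.0", "    1",
            "    1ALA      N    1   1.000   2.000   3.000",
            "   5.00000   5.00000   5.00000")
  f2 <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro2, f2)
  expect_error(read_configuration(f2, "gro"), "inconsistent atom counts")
})

test_that("malformed xyz reports the offending line", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "comment", "C 0 0 0", "C 1 abc 0"), f)
  expect_error(read_configuration(f), "line")
})

test_that("topology attachment sets roles/charges and validates references", {
  tr <- traj_from_coords(matrix(rnorm(3 * 50), ncol = 3))
  spec <- list(atoms = list(
    list(ids = "1-16", role = "terminal_N", charge = 1, element = "N"),
    list(ids = "17-44", role = "dendrimer", charge = 1),
    list(ids = "45-50", role = "counterion", charge = -1, element = "Cl")
  ))
  tr <- attach_topology(tr, spec)
  expect_equal(sum(tr$topology$role == "terminal_N"), 16)
  # charge bookkeeping: Qend + Qins = Qbare
  expect_equal(q_bare(tr), 44)
  # zero-charge spec gives zero bare charge
  tr0 <- attach_topology(traj_from_coords(matrix(rnorm(9), 3)),
                         list(atoms = list(list(ids = "1-3", role = "dendrimer",
                                                charge = 0))))
  expect_equal(q_bare(tr0), 0)
  # dangling reference
  expect_error(
    attach_topology(tr, list(atoms = list(list(ids = "60-61", role = "guest")))),
    "unknown atom id"
  )
})

test_that("collinear planar triples are rejected at attach time", {
  m <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  tr <- traj_from_coords(m)
  expect_error(
    attach_topology(tr, list(planar_groups = list(
      list(group_id = 1, triple = c(1, 2, 3))))),
    "collinear"
  )
})

test_that("topology specs round-trip through yaml and json", {
  spec <- list(atoms = list(list(ids = "1-4", role = "terminal_N", charge = 1)),
               donors = c(1, 2), acceptors = c(3, 4))
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(spec, fy)
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(spec, fj, auto_unbox = TRUE)
  tr <- traj_from_coords(matrix(rnorm(12), ncol = 3))
  for (f in c(fy, fj)) {
    tt <- attach_topology(tr, f)
    expect_equal(q_bare(tt), 4)
    expect_equal(tt$selections$donors, c(1L, 2L))
  }
})
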