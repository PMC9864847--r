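one_residue <- function(atom_name, element, xyz_by_frame, resname = "ALA") {
  n <- length(atom_name)
  top <- as_topology(data.frame(
    atom_id = seq_len(n), atom_name = atom_name, element = element,
    residue_id = 1, residue_name = resname, molecule_id = 1,
    molecule_class = "peptide"))
  list(topology = top, frames = frame_series(xyz_by_frame))
}

test_that("a static single-atom residue gives a constant series", {
  coords <- array(rep(c(0, 0, 10), each = 1), dim = c(1, 3, 4))
  coords[1, , ] <- c(0, 0, 10)
  m <- one_residue("CB", "C", coords)
  b <- com_z_series(m$topology, m$frames, 1, z_reference = "absolute")
  expect_equal(b$z, rep(10, 4))
  expect_equal(burial_average(b), 10)
})

test_that("the COM is mass weighted: 12 amu at z=0 with 16 amu at z=14 gives 8", {
  xyz <- matrix(c(0, 0, 0,
                  0, 0, 14), 2, 3, byrow = TRUE)
  m <- one_residue(c("CB", "OG"), c("C", "O"), xyz, resname = "SER")
  b <- com_z_series(m$topology, m$frames, 1, z_reference = "absolute")
  expect_equal(b$z, atom_mass("O") * 14 / (atom_mass("C") + atom_mass("O")))
  expect_equal(b$z, 8, tolerance = 0.01)
})

test_that("glycine-like residues without side-chain heavy atoms error helpfully", {
  xyz <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3, byrow = TRUE)
  m <- one_residue(c("N", "CA", "C"), c("N", "C", "C"), xyz, "GLY")
  expect_error(com_z_series(m$topology, m$frames, 1),
               class = "raftpath_selection_error")
  # all-atom mode works
  b <- com_z_series(m$topology, m$frames, 1, side_chain = FALSE,
                    z_reference = "absolute")
  expect_equal(nrow(b), 1)
})

test_that("planted burial depths are recovered within 0.15 A and in order", {
  sys <- default_sys()
  avg <- vapply(c("Y6", "H9", "H10"), function(r) {
    burial_average(com_z_series(sys$topology, sys$frames, r,
                                z_reference = "absolute"))
  }, numeric(1))
  planted <- sys$truth$burial_avg[names(avg)]
  expect_lt(max(abs(avg - planted)), 0.15)
  expect_true(avg[["Y6"]] < avg[["H9"]])
  expect_true(avg[["H9"]] < avg[["H10"]])
})

test_that("burial average equals the plain mean of per-frame values", {
  sys <- small_sys()
  b <- com_z_series(sys$topology, sys$frames, "H9", z_reference = "absolute")
  expect_identical(burial_average(b), mean(b$z))
})

test_that("a planted 20% dip below the glucose ceiling is recovered", {
  spec <- synthetic_spec(
    seed = 31, dip = list(residue = "Y6", moiety = "glucose",
                          fraction = 0.20))
  sys <- generate_system(spec)
  moi <- annotate_moieties(sys$topology)
  ref <- bilayer_center(sys$topology, sys$frames, moi)
  bench <- protrusion_series(sys$topology, sys$frames, moi, reference = ref)
  b <- com_z_series(sys$topology, sys$frames, "Y6", reference = ref,
                    z_reference = "bilayer-center")
  cr <- benchmark_crossings(b, bench, "glucose")
  expect_equal(crossing_fraction(cr), sys$truth$dip_fraction,
               tolerance = 0.02 / sys$truth$dip_fraction)
  expect_lt(abs(crossing_fraction(cr) - 0.20), 0.02)
})

test_that("crossing fractions respect bounds and the tie convention", {
  tm <- raftpath:::gm1_atom_template(synthetic_spec()$moiety_ceilings)
  n <- nrow(tm)
  top <- as_topology(data.frame(
    atom_id = seq_len(n + 1),
    atom_name = c(tm$atom_name, "CB"),
    element = c(tm$element, "C"),
    residue_id = c(rep(1, n), 2),
    residue_name = c(rep("GM1", n), "ALA"),
    molecule_id = c(rep(1, n), 2),
    molecule_class = c(rep("ganglioside", n), "peptide")))
  make_case <- function(res_z) {
    coords <- array(0, dim = c(n + 1, 3, length(res_z)))
    for (f in seq_along(res_z)) {
      coords[seq_len(n), 3, f] <- tm$dz
      coords[n + 1, 3, f] <- res_z[f]
    }
    frame_series(coords)
  }
  moi <- annotate_moieties(top)
  # always above -> fraction 0
  fr <- make_case(c(40, 40, 40))
  bench <- protrusion_series(top, fr, moi, z_reference = "absolute")
  b <- com_z_series(top, fr, 2, z_reference = "absolute")
  expect_equal(crossing_fraction(benchmark_crossings(b, bench, "glucose")), 0)
  # exactly equal -> ties count as reaching (fraction 1)
  fr <- make_case(c(23, 23))
  bench <- protrusion_series(top, fr, moi, z_reference = "absolute")
  b <- com_z_series(top, fr, 2, z_reference = "absolute")
  expect_equal(crossing_fraction(benchmark_crossings(b, bench, "glucose")), 1)
})

test_that("mismatched frame windows raise an alignment error", {
  sys <- small_sys()
  moi <- annotate_moieties(sys$topology)
  bench <- protrusion_series(sys$topology, sys$frames, moi,
                             z_reference = "absolute")
  b <- com_z_series(sys$topology, sys$frames, "Y6", z_reference = "absolute",
                    window = c(0, 10))
  expect_error(benchmark_crossings(b, bench[bench$frame > 40, ], "glucose"),
               class = "raftpath_alignment_error")
})

test_that("a static residue has a zero-length trail", {
  coords <- array(0, dim = c(1, 3, 5))
  coords[1, , ] <- c(3, 4, 5)
  m <- one_residue("CB", "C", coords)
  tr <- travel_trail(m$topology, m$frames, 1)
  expect_equal(attr(tr, "path_length"), 0)
  expect_equal(attr(tr, "end_to_end"), 0)
  expect_equal(nrow(tr), 5)
})

test_that("a planted 30 A lateral migration shows in the trail end-to-end", {
  spec <- synthetic_spec(periphery_x = 30, approach_height = 0, t_attach = 0,
                         seed = 21)
  sys <- generate_system(spec)
  tr <- travel_trail(sys$topology, sys$frames, "H9")
  start <- colMeans(as.matrix(tr[tr$time < 25, c("x", "y", "z")]))
  finish <- colMeans(as.matrix(tr[tr$time >= 45, c("x", "y", "z")]))
  expect_equal(sqrt(sum((finish - start)^2)), 30, tolerance = 1 / 30)
})

test_that("the most buried residue attains the minimum trail z", {
  sys <- default_sys()
  zmin <- vapply(c("Y6", "H9", "H10"), function(r) {
    tr <- travel_trail(sys$topology, sys$frames, r)
    min(tr$z)
  }, numeric(1))
  expect_equal(names(which.min(zmin)), "Y6")
})

test_that("rigid translation moves a trail identically (COM linearity)", {
  sys <- small_sys()
  tr1 <- travel_trail(sys$topology, sys$frames, "H10")
  shifted <- sys$frames
  shifted$coords <- shifted$coords + c(3)
  tr2 <- travel_trail(sys$topology, shifted, "H10")
  expect_equal(tr2$x, tr1$x + 3, tolerance = 1e-10)
  expect_equal(tr2$z, tr1$z + 3, tolerance = 1e-10)
  expect_equal(attr(tr2, "path_length"), attr(tr1, "path_length"),
               tolerance = 1e-10)
})

test_that("trail PDB export writes one model per frame", {
  sys <- small_sys()
  tr <- travel_trail(sys$topology, sys$frames, "Y6")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trail_pdb(tr, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^MODEL", lines)), nrow(tr))
})
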