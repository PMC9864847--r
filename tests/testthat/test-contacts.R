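pair_system <- function(d, box = c(100, 100, 100)) {
  top <- as_topology(data.frame(
    atom_id = 1:2, atom_name = c("CB", "GLC1"), element = c("C", "C"),
    residue_id = 1:2, residue_name = c("ALA", "GM1"), molecule_id = 1:2,
    molecule_class = c("peptide", "ganglioside")))
  fr <- frame_series(matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE),
                     box = box)
  list(topology = top, frames = fr)
}

test_that("the contact cutoff is a closed boundary", {
  m <- pair_system(2.9)
  cs <- contact_series(m$topology, m$frames, 1, 2, cutoff = 3.0)
  expect_equal(nrow(cs$pairs), 1)
  m2 <- pair_system(3.1)
  cs2 <- contact_series(m2$topology, m2$frames, 1, 2, cutoff = 3.0)
  expect_equal(nrow(cs2$pairs), 0)
  m3 <- pair_system(3.0)
  expect_equal(nrow(contact_series(m3$topology, m3$frames, 1, 2)$pairs), 1)
})

test_that("minimum-image distances wrap across the box", {
  m <- pair_system(48, box = c(50, 50, 50))   # image distance 2
  cs <- contact_series(m$topology, m$frames, 1, 2, cutoff = 3.0)
  expect_equal(nrow(cs$pairs), 1)
  expect_equal(cs$pairs$distance, 2)
})

test_that("random atom groups match the brute-force pair oracle exactly", {
  withr::with_seed(99, {
    for (rep in 1:6) {
      n <- 120
      box <- c(22, 25, 28)
      xyz <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
                   runif(n, 0, box[3]))
      rows_a <- 1:50
      rows_b <- 51:120
      mine <- raftpath:::find_pairs(xyz, box, rows_a, rows_b, 3.5)
      got <- data.frame(ai = mine$ai, bi = mine$bi, dist = mine$dist)
      got <- got[order(got$ai, got$bi), ]
      want <- oracle_pairs(xyz, box, rows_a, rows_b, 3.5)
      expect_identical(got$ai, want$ai)
      expect_identical(got$bi, want$bi)
      expect_equal(got$dist, want$dist, tolerance = 1e-12)
    }
  })
})

test_that("overlapping or empty contact groups are rejected", {
  m <- pair_system(2.0)
  expect_error(contact_series(m$topology, m$frames, 1:2, 2),
               class = "raftpath_precondition_error")
  expect_error(contact_series(m$topology, m$frames, integer(), 2),
               class = "raftpath_precondition_error")
  expect_error(contact_series(m$topology, m$frames, 1, 2, cutoff = -1),
               class = "raftpath_precondition_error")
})

# --- interaction classification -------------------------------------------

test_that("a textbook salt bridge is both hydrogen bond and electrostatic", {
  # lysine N-H ... carboxylate O, 2.8 A donor-acceptor, near-linear
  top <- as_topology(data.frame(
    atom_id = 1:3,
    atom_name = c("NZ", "HZ1", "SO1"),
    element = c("N", "H", "O"),
    residue_id = c(1, 1, 2),
    residue_name = c("LYS", "LYS", "GM1"),
    molecule_id = c(1, 1, 2),
    molecule_class = c("peptide", "peptide", "ganglioside")))
  xyz <- matrix(c(0, 0, 0,
                  1.0, 0, 0,
                  2.8, 0, 0), 3, 3, byrow = TRUE)
  fr <- frame_series(xyz)
  cs <- contact_series(top, fr, 1:2, 3, cutoff = 3.0)
  tags <- classify_interactions(top, fr, cs)
  nz <- tags[tags$atom_a == 1, ]
  expect_true(nz$hydrogen_bond)
  expect_true(nz$electrostatic)
  expect_false(nz$van_der_waals)
})

test_that("apolar carbon pairs classify as van der Waals", {
  top <- as_topology(data.frame(
    atom_id = 1:2, atom_name = c("CG1", "CER2"), element = c("C", "C"),
    residue_id = 1:2, residue_name = c("VAL", "GM1"), molecule_id = 1:2,
    molecule_class = c("peptide", "ganglioside")))
  fr <- frame_series(matrix(c(0, 0, 0, 2.8, 0, 0), 2, 3, byrow = TRUE))
  cs <- contact_series(top, fr, 1, 2, cutoff = 3.0)
  tags <- classify_interactions(top, fr, cs)
  expect_false(tags$hydrogen_bond)
  expect_false(tags$electrostatic)
  expect_true(tags$van_der_waals)
})

test_that("a bad donor angle defeats the hydrogen-bond call", {
  # H pointing away from the acceptor: angle ~ 0 degrees at H
  top <- as_topology(data.frame(
    atom_id = 1:3,
    atom_name = c("OG", "HG1", "GLC2"),
    element = c("O", "H", "O"),
    residue_id = c(1, 1, 2),
    residue_name = c("SER", "SER", "GM1"),
    molecule_id = c(1, 1, 2),
    molecule_class = c("peptide", "peptide", "ganglioside")))
  xyz <- matrix(c(0, 0, 0,
                  -1.0, 0, 0,
                  3.2, 0, 0), 3, 3, byrow = TRUE)
  fr <- frame_series(xyz)
  cs <- contact_series(top, fr, 1:2, 3, cutoff = 3.5)
  tags <- classify_interactions(top, fr, cs)
  expect_false(any(tags$hydrogen_bond))
})

test_that("planted mixed frames recover 5 hydrogen bonds and 5 apolar contacts", {
  # 5 serine OH -> sugar O geometries + 5 valine C -> ceramide C contacts
  rows <- list()
  xyz <- NULL
  id <- 0
  for (k in 1:5) {
    off <- c(0, 10 * k, 0)
    xyz <- rbind(xyz,
                 off,                    # OG donor
                 off + c(1, 0, 0),       # HG1
                 off + c(3.0, 0, 0),     # acceptor GLC2 (O)
                 off + c(0, 4, 20),      # CG1
                 off + c(2.9, 4, 20))    # CER2 (C)
  }
  n <- nrow(xyz)
  top <- as_topology(data.frame(
    atom_id = 1:n,
    atom_name = rep(c("OG", "HG1", "GLC2", "CG1", "CER2"), 5),
    element = rep(c("O", "H", "O", "C", "C"), 5),
    residue_id = as.vector(vapply(seq(0, 16, by = 4), function(o) {
      o + c(1, 1, 2, 3, 4)
    }, numeric(5))),
    residue_name = rep(c("SER", "SER", "GM1", "VAL", "GM1"), 5),
    molecule_id = as.vector(vapply(seq(0, 16, by = 4), function(o) {
      o + c(1, 1, 2, 3, 4)
    }, numeric(5))),
    molecule_class = rep(c("peptide", "peptide", "ganglioside", "peptide",
                           "ganglioside"), 5)))
  fr <- frame_series(xyz)
  pep <- which(top$molecule_class == "peptide" & top$element != "H")
  gm <- which(top$molecule_class == "ganglioside")
  cs <- contact_series(top, fr, pep, gm, cutoff = 3.0)
  tags <- classify_interactions(top, fr, cs)
  expect_equal(sum(tags$hydrogen_bond), 5)
  expect_equal(sum(tags$van_der_waals), 5)
  expect_equal(sum(tags$electrostatic), 0)
})

test_that("missing hydrogens downgrade to a distance-only call with a record", {
  top <- as_topology(data.frame(
    atom_id = 1:2, atom_name = c("NZ", "GLC2"), element = c("N", "O"),
    residue_id = 1:2, residue_name = c("LYS", "GM1"), molecule_id = 1:2,
    molecule_class = c("peptide", "ganglioside")))
  fr <- frame_series(matrix(c(0, 0, 0, 2.9, 0, 0), 2, 3, byrow = TRUE))
  cs <- contact_series(top, fr, 1, 2, cutoff = 3.0)
  tags <- classify_interactions(top, fr, cs)
  expect_true(tags$hydrogen_bond)
  expect_gt(nrow(attr(tags, "warnings")), 0)
})

# --- ring stacking ---------------------------------------------------------

his_pair <- function(centroid_dist, angle_deg) {
  ring <- raftpath:::his_ring
  a <- raftpath:::ring_atoms_vertical(c(0, 0, 0), 0, ring)
  b <- raftpath:::ring_atoms_vertical(c(0, centroid_dist, 0), angle_deg,
                                      ring)
  top <- as_topology(data.frame(
    atom_id = 1:10,
    atom_name = rep(ring$names, 2),
    element = rep(ring$elements, 2),
    residue_id = rep(c(9, 10), each = 5),
    residue_name = "HSD",
    molecule_id = 1,
    molecule_class = "peptide"))
  list(topology = top, frames = frame_series(rbind(a, b)))
}

test_that("parallel rings 4 A apart stack; distant rings do not", {
  m <- his_pair(4, 0)
  s <- ring_stacking(m$topology, m$frames, 9, 10)
  expect_true(s$stacked)
  expect_equal(s$distance, 4, tolerance = 1e-6)
  expect_lt(s$angle, 1)
  m2 <- his_pair(8, 0)
  expect_false(ring_stacking(m2$topology, m2$frames, 9, 10)$stacked)
  m3 <- his_pair(4, 80)
  s3 <- ring_stacking(m3$topology, m3$frames, 9, 10)
  expect_false(s3$stacked)
  expect_equal(s3$angle, 80, tolerance = 1)
})

test_that("non-aromatic residues are rejected for stacking", {
  top <- as_topology(data.frame(
    atom_id = 1:2, atom_name = c("CB", "CB"), element = "C",
    residue_id = 1:2, residue_name = "ALA", molecule_id = 1,
    molecule_class = "peptide"))
  fr <- frame_series(matrix(0, 2, 3))
  expect_error(ring_stacking(top, fr, 1, 2),
               class = "raftpath_precondition_error")
})

test_that("the planted late-stage stacked fraction of 0.6 is recovered", {
  sys <- default_sys()
  s <- ring_stacking(sys$topology, sys$frames, "H9", "H10")
  late <- sys$frames$time >= 45
  frac <- mean(s$stacked[late])
  expect_equal(frac, sys$truth$stack_fraction,
               tolerance = 0.05 / sys$truth$stack_fraction)
  expect_lt(abs(frac - 0.6), 0.05)
})
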