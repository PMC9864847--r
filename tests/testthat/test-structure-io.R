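test_that("a toy single-water PDB loads as one molecule and one frame", {
  atom_line <- function(id, name, x, y, z, elem) {
    sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            id, name, "HOH", "X", 1, x, y, z, elem)
  }
  pdb <- c(
    "CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1           1",
    atom_line(1, "OH2", 0, 0, 0, "O"),
    atom_line(2, "H1", 0.957, 0, 0, "H"),
    atom_line(3, "H2", -0.240, 0.927, 0, "H"),
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  ld <- load_system(f)
  expect_equal(nrow(ld$topology), 3)
  expect_equal(unique(ld$topology$molecule_class), "water")
  expect_equal(unique(ld$topology$molecule_id), 1)
  expect_equal(n_frames(ld$frames), 1)
  expect_equal(ld$frames$time, 0)
  expect_equal(frame_box(ld$frames, 1), c(50, 50, 50))
})

test_that("a GRO topology loads with nm-to-Angstrom conversion", {
  gro <- c("toy water", "    3",
           "    1SOL    OW1    1   0.000   0.000   0.000",
           "    1SOL    HW2    2   0.095   0.000   0.000",
           "    1SOL    HW3    3  -0.024   0.092   0.000",
           "   5.00000   5.00000   5.00000")
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, f)
  ld <- load_system(f)
  expect_equal(nrow(ld$topology), 3)
  expect_equal(unique(ld$topology$molecule_class), "water")
  expect_equal(frame_coords(ld$frames, 1)[2, 1], 0.95)
  expect_equal(frame_box(ld$frames, 1), c(50, 50, 50))
})

test_that("generated systems round-trip through PDB + DCD losslessly", {
  spec <- synthetic_spec(n_frames = 4, n_waters = 25, shell_waters_base = 8,
                         seed = 13)
  dir <- withr::local_tempdir()
  sys <- generate_system(spec, write_to = dir)
  ld <- load_system(file.path(dir, "system.pdb"),
                    file.path(dir, "traj.dcd"), stride_ns = spec$stride_ns)
  expect_equal(nrow(ld$topology), nrow(sys$topology))
  expect_equal(ld$topology$molecule_class, sys$topology$molecule_class)
  expect_equal(ld$topology$molecule_id, sys$topology$molecule_id)
  expect_equal(n_frames(ld$frames), 4)
  # DCD stores float32; PDB prints three decimals
  expect_lt(max(abs(ld$frames$coords - sys$frames$coords)), 1e-3)
  # moiety labels survive the round trip
  m1 <- annotate_moieties(ld$topology)
  expect_equal(m1$moiety, sys$truth$moieties$moiety)
  expect_equal(m1$atom_id, sys$truth$moieties$atom_id)
})

test_that("a multi-model PDB is accepted as a trajectory dialect", {
  spec <- synthetic_spec(n_frames = 3, n_waters = 10, shell_waters_base = 5,
                         n_ganglioside = 3, n_phospholipid = 8, seed = 2)
  sys <- generate_system(spec)
  dir <- withr::local_tempdir()
  write_system_pdb(sys$topology, sys$frames, file.path(dir, "mm.pdb"))
  write_system_pdb(sys$topology, subset_frames(sys$frames, 1),
                   file.path(dir, "top.pdb"))
  ld <- load_system(file.path(dir, "top.pdb"), file.path(dir, "mm.pdb"))
  expect_equal(n_frames(ld$frames), 3)
  expect_lt(max(abs(ld$frames$coords - sys$frames$coords)), 1e-3)
})

test_that("atom-count mismatch between topology and trajectory errors", {
  spec <- synthetic_spec(n_frames = 2, n_waters = 10, shell_waters_base = 5,
                         n_ganglioside = 3, n_phospholipid = 8, seed = 2)
  sys <- generate_system(spec)
  dir <- withr::local_tempdir()
  write_system_pdb(sys$topology, sys$frames, file.path(dir, "mm.pdb"))
  top2 <- sys$topology[-1, ]
  fr2 <- frame_series(sys$frames$coords[-1, , 1, drop = FALSE], time = 0,
                      box = frame_box(sys$frames, 1))
  write_system_pdb(top2, fr2, file.path(dir, "short.pdb"))
  expect_error(load_system(file.path(dir, "short.pdb"),
                           file.path(dir, "mm.pdb")),
               class = "raftpath_structural_error")
})

test_that("unreadable topology input raises a parse error", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("broken", "  nope"), f)
  expect_error(load_system(f), class = "raftpath_parse_error")
  expect_error(load_system("does-not-exist.pdb"),
               class = "raftpath_parse_error")
})

test_that("moiety annotation reproduces planted labels and flags strays", {
  sys <- small_sys()
  m <- annotate_moieties(sys$topology)
  expect_equal(m$moiety, sys$truth$moieties$moiety)
  expect_equal(nrow(attr(m, "unmatched")), 0)
  # every ganglioside carries all six moieties
  per_mol <- table(m$molecule_id, m$moiety)
  expect_true(all(per_mol >= 1))

  # one stray atom: reported, not fatal
  top <- sys$topology
  i <- which(top$molecule_class == "ganglioside")[1]
  top$atom_name[i] <- "XX9"
  expect_warning(m2 <- annotate_moieties(top), "no moiety rule")
  expect_equal(nrow(attr(m2, "unmatched")), 1)
  expect_equal(attr(m2, "unmatched")$atom_id, top$atom_id[i])
})

test_that("annotation preconditions are enforced", {
  top <- toy_topology(c("OH2", "H1", "H2"), c("O", "H", "H"), "TIP3",
                      "water", residue_id = c(1, 1, 1),
                      molecule_id = c(1, 1, 1))
  expect_error(annotate_moieties(top), class = "raftpath_precondition_error")

  # a ganglioside whose atoms match no rule at all is an annotation error
  gm <- toy_topology(c("QQ1", "QQ2"), c("C", "C"), "GM1", "ganglioside",
                     residue_id = c(1, 1), molecule_id = c(1, 1))
  expect_error(annotate_moieties(gm), class = "raftpath_annotation_error")
})

test_that("loading is deterministic: identical bytes in, identical data out", {
  spec <- synthetic_spec(n_frames = 2, n_waters = 10, shell_waters_base = 5,
                         n_ganglioside = 3, n_phospholipid = 8, seed = 6)
  dir <- withr::local_tempdir()
  generate_system(spec, write_to = dir)
  a <- load_system(file.path(dir, "system.pdb"), file.path(dir, "traj.dcd"))
  b <- load_system(file.path(dir, "system.pdb"), file.path(dir, "traj.dcd"))
  expect_identical(a$topology, b$topology)
  expect_identical(a$frames$coords, b$frames$coords)
})
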