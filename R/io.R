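#' Load a topology and (optionally) a trajectory
#'
#' Reads a PDB or GRO topology and, when given, a DCD trajectory or a
#' multi-model PDB used as a trajectory dialect.  Molecule classes are
#' inferred from residue names through `class_dict`; atoms of consecutive
#' amino-acid residues in the same chain are grouped into one peptide
#' molecule, every other residue is its own molecule.
#'
#' @param topology_path path to a `.pdb` or `.gro` file.
#' @param trajectory_path optional path to a `.dcd` or multi-model `.pdb`
#'   file; when absent the topology coordinates become a single frame at
#'   t = 0.
#' @param class_dict residue-name to class dictionary
#'   ([default_class_dict()]).
#' @param stride_ns time between stored frames in ns, used to synthesise
#'   frame times (DCD headers are not trusted for time units).
#' @param box optional length-3 box override (Angstrom).
#' @return A list with elements `topology` (tibble) and `frames`
#'   ([frame_series()]).
#' @export
load_system <- function(topology_path, trajectory_path = NULL,
                        class_dict = default_class_dict(),
                        stride_ns = 1, box = NULL) {
  if (!file.exists(topology_path)) {
    abort(paste0("Topology file not found: ", topology_path),
          class = "raftpath_parse_error")
  }
  ext <- tolower(tools::file_ext(topology_path))
  parsed <- switch(ext,
    pdb = read_pdb_system(topology_path),
    gro = read_gro_system(topology_path),
    abort(paste0("Unsupported topology format '.", ext,
                 "' (use PDB or GRO)."), class = "raftpath_parse_error")
  )
  topology <- build_topology(parsed$atoms, class_dict)
  nat <- nrow(topology)
  if (is.null(box)) box <- parsed$box %||% c(NA_real_, NA_real_, NA_real_)

  if (is.null(trajectory_path)) {
    coords <- array(parsed$coords, dim = c(nat, 3L, 1L))
    frames <- frame_series(coords, time = 0, box = box)
  } else {
    text <- tolower(tools::file_ext(trajectory_path))
    xyz <- switch(text,
      dcd = bio3d::read.dcd(trajectory_path, verbose = FALSE),
      pdb = read_multimodel_xyz(trajectory_path),
      xtc = abort("XTC trajectories are not supported; convert to DCD.",
                  class = "raftpath_parse_error"),
      abort(paste0("Unsupported trajectory format '.", text, "'."),
            class = "raftpath_parse_error")
    )
    if (ncol(xyz) != 3L * nat) {
      abort(sprintf(
        "Trajectory atom count (%d) does not match topology (%d).",
        ncol(xyz) / 3, nat), class = "raftpath_structural_error")
    }
    nf <- nrow(xyz)
    coords <- array(0, dim = c(nat, 3L, nf))
    for (f in seq_len(nf)) {
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    }
    frames <- frame_series(coords, time = (seq_len(nf) - 1) * stride_ns,
                           box = box)
  }
  list(topology = topology, frames = frames)
}

read_pdb_system <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) abort(paste0("Failed to parse PDB '", path, "': ",
                                     conditionMessage(e)),
                              class = "raftpath_parse_error"))
  a <- pdb$atom
  a <- a[!is.na(a$resno) & !is.na(a$x), , drop = FALSE]
  if (!nrow(a)) {
    abort(paste0("PDB '", path, "' contains no parseable ATOM records."),
          class = "raftpath_parse_error")
  }
  elem <- trimws(a$elesy)
  missing_e <- is.na(elem) | elem == ""
  if (any(missing_e)) {
    elem[missing_e] <- substr(gsub("[^A-Za-z].*", "", trimws(a$elety[missing_e])), 1, 1)
  }
  atoms <- tibble(
    atom_id = a$eleno,
    atom_name = trimws(a$elety),
    element = toupper(elem),
    residue_id = a$resno,
    residue_name = toupper(trimws(a$resid)),
    chain = ifelse(is.na(a$chain), "", a$chain)
  )
  box <- read_cryst1(path)
  list(atoms = atoms,
       coords = cbind(a$x, a$y, a$z),
       box = box)
}

read_cryst1 <- function(path) {
  lines <- grep("^CRYST1", readLines(path, n = 200, warn = FALSE),
                value = TRUE)
  if (!length(lines)) return(NULL)
  f <- as.numeric(c(substr(lines[1], 7, 15), substr(lines[1], 16, 24),
                    substr(lines[1], 25, 33), substr(lines[1], 34, 40),
                    substr(lines[1], 41, 47), substr(lines[1], 48, 54)))
  if (any(is.finite(f[4:6]) & abs(f[4:6] - 90) > 1e-3)) {
    abort("Only orthorhombic boxes are supported (CRYST1 angles must be 90).",
          class = "raftpath_structural_error")
  }
  f[1:3]
}

read_multimodel_xyz <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) abort(paste0("Failed to parse PDB '", path, "': ",
                                     conditionMessage(e)),
              class = "raftpath_parse_error"))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  xyz
}

# GRO (GROMACS) coordinate file: fixed-width columns, nm units.
read_gro_system <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) {
    abort(paste0("GRO file '", path, "' is truncated."),
          class = "raftpath_parse_error")
  }
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat) || length(lines) < nat + 3) {
    abort(paste0("GRO file '", path, "': bad atom count at line 2."),
          class = "raftpath_parse_error")
  }
  body <- lines[3:(2 + nat)]
  resno <- as.integer(substr(body, 1, 5))
  resnm <- toupper(trimws(substr(body, 6, 10)))
  atnm <- trimws(substr(body, 11, 15))
  atid <- as.integer(substr(body, 16, 20))
  x <- as.numeric(substr(body, 21, 28)) * 10
  y <- as.numeric(substr(body, 29, 36)) * 10
  z <- as.numeric(substr(body, 37, 44)) * 10
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    bad <- which(is.na(x) | is.na(y) | is.na(z))[1] + 2L
    abort(paste0("GRO file '", path, "': unreadable coordinates at line ",
                 bad, "."), class = "raftpath_parse_error")
  }
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[nat + 3]),
                                               "\\s+")[[1]]))
  box <- if (length(boxv) >= 3) boxv[1:3] * 10 else NULL
  elem <- substr(gsub("[^A-Za-z].*", "", atnm), 1, 1)
  atoms <- tibble(atom_id = atid, atom_name = atnm, element = toupper(elem),
                  residue_id = resno, residue_name = resnm, chain = "")
  list(atoms = atoms, coords = cbind(x, y, z), box = box)
}

# Assign molecule classes and molecule ids from the parsed atom records.
build_topology <- function(atoms, class_dict) {
  cls <- unname(class_dict[atoms$residue_name])
  unknown <- is.na(cls)
  if (any(unknown)) {
    abort(paste0("Residue name(s) not in class dictionary: ",
                 paste(unique(atoms$residue_name[unknown]), collapse = ", ")),
          class = "raftpath_parse_error")
  }
  atoms$molecule_class <- cls
  key <- paste(atoms$chain, atoms$residue_id)
  newres <- c(TRUE, key[-1] != key[-length(key)])
  same_pep_chain <- c(FALSE, cls[-1] == "peptide" &
                        cls[-length(cls)] == "peptide" &
                        atoms$chain[-1] == atoms$chain[-length(key)])
  newmol <- newres & !same_pep_chain
  atoms$molecule_id <- cumsum(newmol)
  atoms$chain <- NULL
  as_topology(atoms)
}

#' Write a system (topology + frames) as PDB
#'
#' Writes a PDB with a `CRYST1` record; when `frames` has more than one
#' frame, one `MODEL` block is written per frame (the multi-model
#' trajectory dialect accepted by [load_system()]).
#'
#' @param topology atom table.
#' @param frames a [frame_series()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_system_pdb <- function(topology, frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  b <- frame_box(frames, 1)
  if (all(is.finite(b))) {
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      b[1], b[2], b[3], 90, 90, 90), con)
  }
  nf <- n_frames(frames)
  chain <- pdb_chain_letters(topology)
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(frames, f)
    lines <- sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      topology$atom_id %% 100000, format_atom_name(topology$atom_name),
      substr(topology$residue_name, 1, 4), chain,
      topology$residue_id %% 10000, xyz[, 1], xyz[, 2], xyz[, 3],
      topology$element)
    writeLines(lines, con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

format_atom_name <- function(x) {
  ifelse(nchar(x) < 4, paste0("", x), x)
}

# Distinct chain letter per peptide molecule; all non-peptide atoms share
# one chain so residue numbering stays unambiguous per (chain, residue).
pdb_chain_letters <- function(topology) {
  chain <- rep("X", nrow(topology))
  pep <- topology$molecule_class == "peptide"
  if (any(pep)) {
    ids <- unique(topology$molecule_id[pep])
    for (i in seq_along(ids)) {
      chain[topology$molecule_id == ids[i]] <- LETTERS[i]
    }
  }
  chain
}

#' Write a frame series as a CHARMM-style DCD trajectory
#'
#' Minimal single-precision DCD writer (no unit-cell records; the box
#' travels in the companion PDB's `CRYST1`).  Round-trips through
#' `bio3d::read.dcd()`.
#'
#' @param frames a [frame_series()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_dcd <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(frames)
  nat <- n_atoms(frames)
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- nf; icntrl[2] <- 0L; icntrl[3] <- 1L; icntrl[4] <- nf
    icntrl[20] <- 24L
    writeBin(icntrl, con, size = 4, endian = "little")
  }, 84)
  title <- formatC("Written by raftpath", width = -80)
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(nat), con, size = 4, endian = "little"), 4)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(frames, f)
    for (k in 1:3) {
      rec(function() writeBin(as.numeric(xyz[, k]), con, size = 4,
                              endian = "little"), 4 * nat)
    }
  }
  invisible(path)
}

#' Export a residue trail as a multi-model pseudo-atom PDB
#'
#' One `MODEL` per frame containing a single pseudo-atom at the residue's
#' centre of mass, so external viewers can render the travel trail.
#'
#' @param trail tibble from [travel_trail()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_trail_pdb <- function(trail, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(trail))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf(
      "ATOM      1  CA  TRL X   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
      trail$x[i], trail$y[i], trail$z[i]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
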