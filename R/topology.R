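#' Default residue-name to molecule-class dictionary
#'
#' Maps residue names (upper-case) to one of the six molecule classes:
#' ganglioside, sterol, phospholipid, water, ion, peptide.  Standard
#' amino-acid residue names map to peptide.  Force fields differ in their
#' residue codes, so the dictionary is a plain named character vector that
#' callers can extend or replace, or load from a YAML file with
#' [read_class_dict()].
#'
#' @return Named character vector: names are residue codes, values classes.
#' @export
default_class_dict <- function() {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO",
          "SER", "THR", "TRP", "TYR", "VAL")
  c(
    setNames(rep("ganglioside", 2), c("GM1", "CER")),
    setNames(rep("sterol", 3), c("CHL1", "CHOL", "CLOL")),
    setNames(rep("phospholipid", 3), c("POPC", "POPE", "DPPC")),
    setNames(rep("water", 5), c("TIP3", "TIP4", "HOH", "SOL", "WAT")),
    setNames(rep("ion", 6), c("SOD", "CLA", "NA", "CL", "POT", "K")),
    setNames(rep("peptide", length(aa)), aa)
  )
}

#' Read a residue-class dictionary from a YAML file
#'
#' The file maps residue codes to classes, e.g. `GM1: ganglioside`.
#'
#' @param path path to a YAML key-value file.
#' @return Named character vector usable as `class_dict`.
#' @export
read_class_dict <- function(path) {
  d <- yaml::read_yaml(path)
  unlist(d)
}

molecule_classes <- c("ganglioside", "sterol", "phospholipid", "water",
                      "ion", "peptide")

# Atomic masses (amu) and Bondi van-der-Waals radii (Angstrom) by element.
element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, NA. = 22.990, CL = 35.45,
                    K = 39.098, MG = 24.305, CA = 40.078, F = 18.998)
bondi_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80,
                 S = 1.80, NA. = 2.27, CL = 1.75, K = 2.75, MG = 1.73,
                 CA = 2.31, F = 1.47)

element_key <- function(element) {
  e <- toupper(element)
  e[e == "NA"] <- "NA."
  e
}

#' Atomic mass / van-der-Waals radius lookup
#' @param element character vector of element symbols.
#' @return Numeric vector (amu or Angstrom).
#' @export
atom_mass <- function(element) {
  m <- element_masses[element_key(element)]
  if (anyNA(m)) {
    abort(paste0("No mass for element(s): ",
                 paste(unique(element[is.na(m)]), collapse = ", ")),
          class = "raftpath_element_error")
  }
  unname(m)
}

#' @rdname atom_mass
#' @export
vdw_radius <- function(element) {
  r <- bondi_radii[element_key(element)]
  if (anyNA(r)) {
    abort(paste0("No van-der-Waals radius for element(s): ",
                 paste(unique(element[is.na(r)]), collapse = ", ")),
          class = "raftpath_element_error")
  }
  unname(r)
}

#' Build and validate an atom table
#'
#' The atom table (the package's `Topology`) is a tibble with one row per
#' atom and columns `atom_id`, `atom_name`, `element`, `mass`, `residue_id`,
#' `residue_name`, `molecule_id`, `molecule_class`.
#'
#' @param df data frame with at least `atom_id`, `atom_name`, `element`,
#'   `residue_id`, `residue_name`, `molecule_id`, `molecule_class`; `mass`
#'   is filled from `element` when absent.
#' @return A validated tibble of class `raft_topology`.
#' @export
as_topology <- function(df) {
  df <- as_tibble(df)
  req <- c("atom_id", "atom_name", "element", "residue_id", "residue_name",
           "molecule_id", "molecule_class")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    abort(paste0("Atom table lacks column(s): ", paste(miss, collapse = ", ")),
          class = "raftpath_structural_error")
  }
  if (!"mass" %in% names(df)) df$mass <- atom_mass(df$element)
  if (anyDuplicated(df$atom_id)) {
    abort("atom_id values must be unique.", class = "raftpath_structural_error")
  }
  if (any(df$mass <= 0)) {
    abort("Atom masses must be strictly positive.",
          class = "raftpath_structural_error")
  }
  bad <- setdiff(unique(df$molecule_class), molecule_classes)
  if (length(bad)) {
    abort(paste0("Unknown molecule class(es): ", paste(bad, collapse = ", ")),
          class = "raftpath_structural_error")
  }
  ncl <- dplyr::n_distinct(paste(df$molecule_id, df$molecule_class))
  if (ncl != dplyr::n_distinct(df$molecule_id)) {
    abort("Each molecule must have exactly one class.",
          class = "raftpath_structural_error")
  }
  class(df) <- c("raft_topology", class(df))
  df
}

#' Atom indices (row positions) for a set of molecules or a class
#'
#' @param topology atom table from [as_topology()] / [load_system()].
#' @param molecule_id integer molecule ids, or `NULL`.
#' @param molecule_class one of the six classes, or `NULL`.
#' @return Integer vector of row positions into the atom table.
#' @export
atom_rows <- function(topology, molecule_id = NULL, molecule_class = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(molecule_id)) keep <- keep & topology$molecule_id %in% molecule_id
  if (!is.null(molecule_class)) keep <- keep & topology$molecule_class %in% molecule_class
  which(keep)
}

backbone_names <- c("N", "CA", "C", "O", "OXT", "H", "HA", "HN",
                    "H1", "H2", "H3")

#' Resolve a peptide residue selector
#'
#' Selectors are either an integer `residue_id`, or a compact string such
#' as `"Y6"` (one-letter amino-acid code + residue number), checked against
#' the residue actually present.
#'
#' @param topology atom table.
#' @param residue selector (integer or string like `"H9"`).
#' @param molecule_id restrict to one peptide molecule (default: the first
#'   peptide molecule containing the residue).
#' @return Integer vector of atom-table row positions for the residue.
#' @export
residue_rows <- function(topology, residue, molecule_id = NULL) {
  one_letter <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
                  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  want_name <- NULL
  if (is.character(residue)) {
    m <- regmatches(residue, regexec("^([A-Za-z])([0-9]+)$", residue))[[1]]
    if (length(m) != 3) {
      abort(paste0("Cannot parse residue selector '", residue, "'."),
            class = "raftpath_selection_error")
    }
    want_name <- one_letter[[toupper(m[2])]]
    residue <- as.integer(m[3])
  }
  rows <- which(topology$molecule_class == "peptide" &
                  topology$residue_id == residue)
  if (!is.null(molecule_id)) {
    rows <- rows[topology$molecule_id[rows] %in% molecule_id]
  } else if (length(rows)) {
    first_mol <- topology$molecule_id[rows[1]]
    rows <- rows[topology$molecule_id[rows] == first_mol]
  }
  if (!length(rows)) {
    abort(paste0("Residue ", residue, " not found in any peptide."),
          class = "raftpath_selection_error")
  }
  if (!is.null(want_name)) {
    have <- unique(topology$residue_name[rows])
    ok <- want_name == have |
      (want_name == "HIS" & have %in% c("HSD", "HSE", "HSP"))
    if (!any(ok)) {
      abort(paste0("Residue ", residue, " is ", have[1], ", not ", want_name, "."),
            class = "raftpath_selection_error")
    }
  }
  rows
}

# Side-chain heavy-atom rows of a residue (backbone and hydrogens dropped).
side_chain_rows <- function(topology, rows, side_chain = TRUE,
                            heavy_only = TRUE) {
  keep <- rows
  if (side_chain) {
    keep <- keep[!toupper(topology$atom_name[keep]) %in% backbone_names]
  }
  if (heavy_only) keep <- keep[topology$element[keep] != "H"]
  keep
}
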