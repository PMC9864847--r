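#' Moiety labels of a ganglioside headgroup
#'
#' The six chemically meaningful parts of a GM1-like ganglioside: the
#' ceramide anchor and the five sugar units of the headgroup (glucose,
#' inner galactose, N-acetylgalactosamine, terminal galactose, sialic
#' acid).
#'
#' @return Character vector of the six labels, in anchor-to-tip order.
#' @export
moiety_levels <- function() {
  c("ceramide", "glucose", "galactose-inner", "GalNAc",
    "galactose-terminal", "sialic-acid")
}

#' Default atom-name patterns assigning ganglioside atoms to moieties
#'
#' Force fields differ in their GM1 atom naming, so moiety assignment is
#' rule-driven: each rule is a regular expression tried against the atom
#' name, first match wins.  The defaults match the prefix scheme used by
#' the synthetic generator (`CER*`, `GLC*`, `GLI*`, `GNC*`, `GLT*`,
#' `SIA*`/`SO*`) plus common CHARMM-style carbohydrate prefixes; override
#' them for other naming schemes.
#'
#' @return Tibble with columns `moiety` and `pattern`.
#' @export
default_moiety_rules <- function() {
  tibble(
    moiety = moiety_levels(),
    pattern = c("^CER|^C[0-9]+$|^O1$", "^GLC|^BGL", "^GLI|^GAL1|^GA1",
                "^GNC|^NAG|^GN", "^GLT|^GAL2|^GA2", "^SIA|^SO|^NEU")
  )
}

#' Read moiety rules from a YAML file
#'
#' The file maps moiety labels to regular-expression patterns.
#'
#' @param path path to a YAML key-value file.
#' @return Tibble usable as `rules` in [annotate_moieties()].
#' @export
read_moiety_rules <- function(path) {
  d <- yaml::read_yaml(path)
  tibble(moiety = names(d), pattern = unlist(d, use.names = FALSE))
}

#' Assign every ganglioside atom to a headgroup moiety
#'
#' @param topology atom table.
#' @param rules tibble of (`moiety`, `pattern`) regular-expression rules,
#'   tried in order; see [default_moiety_rules()].
#' @return A tibble of class `moiety_map` with columns `atom_id`,
#'   `molecule_id`, `moiety`.  Ganglioside atoms matching no rule are
#'   reported in the `unmatched` attribute (a tibble) and via a warning.
#' @export
annotate_moieties <- function(topology, rules = default_moiety_rules()) {
  g <- which(topology$molecule_class == "ganglioside")
  if (!length(g)) {
    abort("Topology contains no ganglioside molecules.",
          class = "raftpath_precondition_error")
  }
  bad_moiety <- setdiff(rules$moiety, moiety_levels())
  if (length(bad_moiety)) {
    abort(paste0("Unknown moiety label(s) in rules: ",
                 paste(bad_moiety, collapse = ", ")),
          class = "raftpath_annotation_error")
  }
  names_g <- toupper(topology$atom_name[g])
  lab <- rep(NA_character_, length(g))
  for (i in seq_len(nrow(rules))) {
    hit <- is.na(lab) & grepl(rules$pattern[i], names_g)
    lab[hit] <- rules$moiety[i]
  }
  unmatched <- tibble(
    atom_id = topology$atom_id[g[is.na(lab)]],
    atom_name = topology$atom_name[g[is.na(lab)]],
    molecule_id = topology$molecule_id[g[is.na(lab)]]
  )
  # a molecule with no matched atoms at all is an annotation failure
  per_mol <- split(lab, topology$molecule_id[g])
  dead <- names(per_mol)[vapply(per_mol, function(v) all(is.na(v)), logical(1))]
  if (length(dead)) {
    abort(paste0("No moiety rule matched any atom of ganglioside molecule(s): ",
                 paste(dead, collapse = ", ")),
          class = "raftpath_annotation_error")
  }
  if (nrow(unmatched)) {
    warn(sprintf("%d ganglioside atom(s) matched no moiety rule; see attr(x, 'unmatched').",
                 nrow(unmatched)))
  }
  out <- tibble(
    atom_id = topology$atom_id[g[!is.na(lab)]],
    molecule_id = topology$molecule_id[g[!is.na(lab)]],
    moiety = lab[!is.na(lab)]
  )
  attr(out, "unmatched") <- unmatched
  class(out) <- c("moiety_map", class(out))
  out
}

# Row positions (into the atom table) of ganglioside atoms carrying a given
# moiety label, optionally restricted to some molecules.
moiety_rows <- function(topology, moieties, moiety, molecule_id = NULL) {
  ids <- moieties$atom_id[moieties$moiety %in% moiety]
  if (!is.null(molecule_id)) {
    ids <- intersect(ids, moieties$atom_id[moieties$molecule_id %in% molecule_id])
  }
  which(topology$atom_id %in% ids)
}
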