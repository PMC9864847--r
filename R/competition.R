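#' First-contact time of peptides with the ganglioside cluster
#'
#' The first contact is the time of the first frame opening a run of at
#' least `persistence` consecutive frames in which the peptide makes at
#' least one atom-atom contact (within `cutoff`) with a ganglioside atom;
#' single-frame grazing touches are thereby filtered out.
#'
#' @param topology atom table.
#' @param frames a [frame_series()].
#' @param peptides molecule ids of the peptides to score (default: all
#'   peptide molecules).
#' @param ganglioside_rows atom-table rows of the ganglioside group
#'   (default: all ganglioside atoms).
#' @param cutoff contact cutoff (Angstrom).
#' @param persistence minimum run length in frames.
#' @return Tibble with columns `molecule_id`, `first_contact_ns` (`NA`
#'   when the peptide never makes persistent contact).
#' @export
first_contact_time <- function(topology, frames, peptides = NULL,
                               ganglioside_rows = NULL, cutoff = 3.0,
                               persistence = 3) {
  if (is.null(peptides)) {
    peptides <- unique(topology$molecule_id[topology$molecule_class == "peptide"])
  }
  if (is.null(ganglioside_rows)) {
    ganglioside_rows <- atom_rows(topology, molecule_class = "ganglioside")
  }
  purrr::map_dfr(peptides, function(pid) {
    prows <- atom_rows(topology, molecule_id = pid)
    if (length(intersect(prows, ganglioside_rows))) {
      abort("Peptide and ganglioside atom sets overlap.",
            class = "raftpath_precondition_error")
    }
    nf <- n_frames(frames)
    touch <- vapply(seq_len(nf), function(f) {
      p <- find_pairs(frame_coords(frames, f), frame_box(frames, f),
                      prows, ganglioside_rows, cutoff)
      length(p$ai) > 0
    }, logical(1))
    i <- first_persistent(touch, persistence)
    tibble(molecule_id = pid,
           first_contact_ns = if (is.na(i)) NA_real_ else frames$time[i])
  })
}

#' Intramolecular masking report for aromatic residues
#'
#' Quantifies the "U-folding" effect in which a peptide's intramolecular
#' packing hides its aromatic residues from the gangliosides.  An
#' intramolecular contact is a contact (within `cutoff`) between a
#' residue atom and a peptide atom at least `min_seq_sep` residues away
#' in sequence; the masking fraction of a residue is the fraction of
#' frames with at least one intramolecular contact and zero ganglioside
#' contacts.
#'
#' @param topology atom table.
#' @param frames a [frame_series()].
#' @param peptide molecule id of the peptide.
#' @param residues residue selectors to score (e.g. `c("H9", "H10")`).
#' @param ganglioside_rows ganglioside atom rows (default: all).
#' @param cutoff contact cutoff (Angstrom).
#' @param min_seq_sep minimum residue-sequence separation defining
#'   "intramolecular".
#' @return List with `summary` (tibble: `residue`, `masking_fraction`,
#'   `intra_fraction`, `inter_fraction`) and `counts` (tibble per frame
#'   and residue: `n_intra`, `n_inter`).
#' @export
masking_report <- function(topology, frames, peptide, residues,
                           ganglioside_rows = NULL, cutoff = 3.0,
                           min_seq_sep = 3) {
  if (is.null(ganglioside_rows)) {
    ganglioside_rows <- atom_rows(topology, molecule_class = "ganglioside")
  }
  prows_all <- atom_rows(topology, molecule_id = peptide)
  if (!length(prows_all) ||
      topology$molecule_class[prows_all[1]] != "peptide") {
    abort("`peptide` must be the molecule id of a peptide.",
          class = "raftpath_selection_error")
  }
  nf <- n_frames(frames)
  counts <- purrr::map_dfr(residues, function(r) {
    rrows <- residue_rows(topology, r, molecule_id = peptide)
    rid <- topology$residue_id[rrows[1]]
    distal <- prows_all[abs(topology$residue_id[prows_all] - rid) >= min_seq_sep]
    purrr::map_dfr(seq_len(nf), function(f) {
      xyz <- frame_coords(frames, f)
      box <- frame_box(frames, f)
      n_intra <- if (length(distal)) {
        length(find_pairs(xyz, box, rrows, distal, cutoff)$ai)
      } else 0L
      n_inter <- length(find_pairs(xyz, box, rrows, ganglioside_rows,
                                   cutoff)$ai)
      tibble(frame = f, time = frames$time[f], residue = as.character(r),
             n_intra = n_intra, n_inter = n_inter)
    })
  })
  summ <- counts |>
    group_by(.data$residue) |>
    summarise(
      masking_fraction = mean(.data$n_intra >= 1 & .data$n_inter == 0),
      intra_fraction = mean(.data$n_intra >= 1),
      inter_fraction = mean(.data$n_inter >= 1),
      .groups = "drop")
  list(summary = summ, counts = counts)
}

#' Lateral spread of ganglioside sugar headgroups
#'
#' Per frame, projects each ganglioside's sugar-headgroup centre of mass
#' (all non-ceramide moiety atoms, mass weighted) onto the xy plane and
#' averages, over molecules, the distance to the nearest neighbouring
#' headgroup (lateral minimum image).  Larger values mean the headgroups
#' are spread apart, e.g. by an accommodated peptide.
#'
#' @param topology atom table.
#' @param frames a [frame_series()].
#' @param moieties a [annotate_moieties()] map.
#' @param molecule_id restrict to a subset of ganglioside molecules.
#' @return Tibble with columns `frame`, `time`, `spread` (Angstrom); the
#'   time-average is `attr(x, "average")`.
#' @export
headgroup_spread <- function(topology, frames, moieties,
                             molecule_id = NULL) {
  gm_ids <- sort(unique(moieties$molecule_id))
  if (!is.null(molecule_id)) gm_ids <- intersect(gm_ids, molecule_id)
  if (length(gm_ids) < 2) {
    abort("Headgroup spread needs at least two ganglioside molecules.",
          class = "raftpath_precondition_error")
  }
  sugar_rows <- lapply(gm_ids, function(id) {
    moiety_rows(topology, moieties, setdiff(moiety_levels(), "ceramide"),
                molecule_id = id)
  })
  weights <- lapply(sugar_rows, function(rows) topology$mass[rows])
  nf <- n_frames(frames)
  nmol <- length(gm_ids)
  spread <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(frames, f)
    box <- frame_box(frames, f)
    com <- t(vapply(seq_len(nmol), function(i) {
      colSums(xyz[sugar_rows[[i]], 1:2, drop = FALSE] * weights[[i]]) /
        sum(weights[[i]])
    }, numeric(2)))
    dx <- outer(com[, 1], com[, 1], "-")
    dy <- outer(com[, 2], com[, 2], "-")
    if (is.finite(box[1])) dx <- dx - box[1] * round(dx / box[1])
    if (is.finite(box[2])) dy <- dy - box[2] * round(dy / box[2])
    d <- sqrt(dx^2 + dy^2)
    diag(d) <- Inf
    spread[f] <- mean(apply(d, 1, min))
  }
  out <- tibble(frame = seq_len(nf), time = frames$time, spread = spread)
  attr(out, "average") <- mean(spread)
  class(out) <- c("spread_series", class(out))
  out
}
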