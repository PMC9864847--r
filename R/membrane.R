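#' Per-frame bilayer centre
#'
#' Locates the bilayer midplane in each frame as the midpoint between the
#' mean z of upper-leaflet and lower-leaflet headgroup-reference atoms.
#' Reference atoms are the phosphorus of each phospholipid, the topmost
#' ceramide atom of each ganglioside, and the oxygen of each sterol;
#' leaflet membership is decided by the sign of z relative to the mean z
#' of all lipid atoms in the frame.
#'
#' @param topology atom table.
#' @param frames a [frame_series()].
#' @param moieties optional [annotate_moieties()] map; computed with
#'   default rules when gangliosides are present and `moieties` is `NULL`.
#' @return Tibble of class `membrane_frame` with columns `frame`, `time`,
#'   `z0` (Angstrom).
#' @export
bilayer_center <- function(topology, frames, moieties = NULL) {
  lipid_rows <- atom_rows(topology,
                          molecule_class = c("ganglioside", "sterol",
                                             "phospholipid"))
  n_lip <- dplyr::n_distinct(topology$molecule_id[lipid_rows])
  if (n_lip < 2) {
    abort("Bilayer centre needs at least two lipid molecules.",
          class = "raftpath_precondition_error")
  }
  has_gm <- any(topology$molecule_class == "ganglioside")
  if (is.null(moieties) && has_gm) {
    moieties <- suppressWarnings(annotate_moieties(topology))
  }

  p_rows <- which(topology$molecule_class == "phospholipid" &
                    topology$element == "P")
  o_rows <- which(topology$molecule_class == "sterol" &
                    topology$element == "O")
  cer_groups <- list()
  if (has_gm) {
    cer <- moiety_rows(topology, moieties, "ceramide")
    cer_groups <- split(cer, topology$molecule_id[cer])
  }

  nf <- n_frames(frames)
  z0 <- numeric(nf)
  for (f in seq_len(nf)) {
    z <- frames$coords[, 3, f]
    refs <- c(z[p_rows], z[o_rows],
              vapply(cer_groups, function(rows) max(z[rows]), numeric(1)))
    mid <- mean(z[lipid_rows])
    upper <- refs[refs >= mid]
    lower <- refs[refs < mid]
    if (!length(upper) || !length(lower)) {
      abort(sprintf(
        "Degenerate geometry in frame %d: all lipid reference atoms in one leaflet.",
        f), class = "raftpath_degenerate_error")
    }
    z0[f] <- (mean(upper) + mean(lower)) / 2
  }
  out <- tibble(frame = seq_len(nf), time = frames$time, z0 = z0)
  class(out) <- c("membrane_frame", class(out))
  out
}

# Per-frame z offset implied by the z-reference convention.
z_offset <- function(frames, reference, z_reference) {
  if (z_reference == "absolute" || is.null(reference)) {
    return(numeric(n_frames(frames)))
  }
  if (nrow(reference) != n_frames(frames)) {
    abort("Membrane reference and frame series cover different frame counts.",
          class = "raftpath_alignment_error")
  }
  reference$z0
}

#' Per-moiety headgroup protrusion benchmarks
#'
#' For every frame and moiety, takes the maximum z (heavy atoms) over each
#' ganglioside molecule's moiety atoms, averages over molecules, and then
#' averages the per-frame values over time to give one scalar benchmark
#' per moiety.  z is measured relative to the bilayer centre
#' (`z_reference = "bilayer-center"`) or in raw box coordinates
#' (`"absolute"`).
#'
#' @param topology atom table.
#' @param frames a [frame_series()].
#' @param moieties a [annotate_moieties()] map.
#' @param reference a [bilayer_center()] tibble (required for the
#'   bilayer-centre convention).
#' @param z_reference `"bilayer-center"` or `"absolute"`.
#' @return Tibble of class `protrusion_benchmark`: columns `frame`,
#'   `time`, `moiety`, `protrusion` (Angstrom); the per-moiety scalar
#'   time-averages are in `attr(x, "summary")` and via [tidy()].
#' @export
protrusion_series <- function(topology, frames, moieties,
                              reference = NULL,
                              z_reference = c("bilayer-center", "absolute")) {
  z_reference <- match.arg(z_reference)
  if (z_reference == "bilayer-center" && is.null(reference)) {
    reference <- bilayer_center(topology, frames, moieties)
  }
  gm_ids <- unique(topology$molecule_id[topology$molecule_class == "ganglioside"])
  if (!length(gm_ids)) {
    abort("Topology contains no ganglioside molecules.",
          class = "raftpath_precondition_error")
  }
  offs <- z_offset(frames, reference, z_reference)

  heavy <- topology$element != "H"
  groups <- list()
  for (m in moiety_levels()) {
    for (id in gm_ids) {
      rows <- moiety_rows(topology, moieties, m, molecule_id = id)
      rows <- rows[heavy[rows]]
      if (!length(rows)) {
        abort(sprintf("Ganglioside molecule %d has no heavy atoms in moiety '%s'.",
                      id, m), class = "raftpath_annotation_error")
      }
      groups[[paste(m, id)]] <- rows
    }
  }
  nf <- n_frames(frames)
  nm <- length(moiety_levels())
  vals <- matrix(0, nrow = nf, ncol = nm,
                 dimnames = list(NULL, moiety_levels()))
  for (f in seq_len(nf)) {
    z <- frames$coords[, 3, f]
    for (mi in seq_len(nm)) {
      m <- moiety_levels()[mi]
      mx <- vapply(gm_ids, function(id) max(z[groups[[paste(m, id)]]]),
                   numeric(1))
      vals[f, mi] <- mean(mx) - offs[f]
    }
  }
  out <- tidyr::expand_grid(frame = seq_len(nf), moiety = moiety_levels())
  out$time <- frames$time[out$frame]
  out$protrusion <- as.vector(t(vals))
  out <- out[, c("frame", "time", "moiety", "protrusion")]
  summ <- out |>
    group_by(.data$moiety) |>
    summarise(benchmark = mean(.data$protrusion), .groups = "drop") |>
    arrange(match(.data$moiety, moiety_levels()))
  attr(out, "summary") <- summ
  attr(out, "z_reference") <- z_reference
  class(out) <- c("protrusion_benchmark", class(out))
  out
}

#' @export
tidy.protrusion_benchmark <- function(x, ...) attr(x, "summary")

#' @export
summary.protrusion_benchmark <- function(object, ...) attr(object, "summary")
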