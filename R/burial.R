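#' Centre-of-mass z series of a peptide residue (burial depth)
#'
#' Tracks the mass-weighted centre of mass of a residue's side-chain heavy
#' atoms along z, relative to the bilayer centre or in raw box
#' coordinates.  The scalar burial average is the arithmetic mean of the
#' per-frame values over the requested window.
#'
#' @param topology atom table.
#' @param frames a [frame_series()].
#' @param residue residue selector (see [residue_rows()]).
#' @param reference a [bilayer_center()] tibble, or `NULL` for absolute z.
#' @param z_reference `"bilayer-center"` or `"absolute"`.
#' @param side_chain use side-chain atoms only (default); set `FALSE` for
#'   all-atom centre of mass.
#' @param window optional time window `c(t0, t1)` in ns, logical mask or
#'   frame indices.
#' @param molecule_id restrict the residue lookup to one peptide.
#' @return Tibble of class `burial_series` with columns `frame`, `time`,
#'   `z`; the scalar average is `attr(x, "average")`.
#' @export
com_z_series <- function(topology, frames, residue, reference = NULL,
                         z_reference = c("bilayer-center", "absolute"),
                         side_chain = TRUE, window = NULL,
                         molecule_id = NULL) {
  z_reference <- match.arg(z_reference)
  rows <- residue_rows(topology, residue, molecule_id = molecule_id)
  use <- side_chain_rows(topology, rows, side_chain = side_chain)
  if (!length(use)) {
    abort(paste0("Residue has no side-chain heavy atoms; ",
                 "use side_chain = FALSE for an all-atom centre of mass."),
          class = "raftpath_selection_error")
  }
  offs <- z_offset(frames, reference, z_reference)
  w <- topology$mass[use]
  idx <- resolve_window(frames, window)
  z <- vapply(idx, function(f) {
    sum(frames$coords[use, 3, f] * w) / sum(w) - offs[f]
  }, numeric(1))
  out <- tibble(frame = idx, time = frames$time[idx], z = z)
  attr(out, "residue") <- residue
  attr(out, "average") <- mean(z)
  attr(out, "z_reference") <- z_reference
  class(out) <- c("burial_series", class(out))
  out
}

#' Scalar burial average of a burial series
#' @param burial a [com_z_series()] result.
#' @return The arithmetic mean of the per-frame z values (Angstrom).
#' @export
burial_average <- function(burial) attr(burial, "average")

#' Fraction of frames in which a residue reaches a moiety's protrusion
#'
#' Compares the residue burial z against a moiety's per-frame protrusion
#' benchmark; a frame counts as "reaching" the moiety when the burial z is
#' less than or equal to the benchmark (ties count).
#'
#' @param burial a [com_z_series()] result.
#' @param benchmark a [protrusion_series()] result on the same frames and
#'   z-reference convention.
#' @param moiety one of [moiety_levels()].
#' @return Tibble with columns `frame`, `time`, `z`, `benchmark`, `below`;
#'   the fraction of frames below is `attr(x, "fraction")`.
#' @export
benchmark_crossings <- function(burial, benchmark, moiety) {
  stopifnot(moiety %in% moiety_levels())
  keep <- benchmark$moiety == moiety
  ref <- tibble(frame = benchmark$frame[keep],
                benchmark = benchmark$protrusion[keep])
  out <- dplyr::inner_join(
    tibble(frame = burial$frame, time = burial$time, z = burial$z),
    ref, by = "frame")
  if (nrow(out) != nrow(burial)) {
    abort("Burial series and benchmark do not cover the same frames.",
          class = "raftpath_alignment_error")
  }
  out$below <- out$z <= out$benchmark
  attr(out, "fraction") <- mean(out$below)
  attr(out, "moiety") <- moiety
  class(out) <- c("benchmark_crossings", class(out))
  out
}

#' Fraction of frames reaching the moiety
#' @param crossings a [benchmark_crossings()] result.
#' @return Numeric in `[0, 1]`.
#' @export
crossing_fraction <- function(crossings) attr(crossings, "fraction")

#' 3D travel trail of a residue's centre of mass
#'
#' Per-frame centre of mass of the residue in original box coordinates
#' (matching how trails are rendered over the raft surface).
#'
#' @inheritParams com_z_series
#' @return Tibble of class `residue_trail` with columns `frame`, `time`,
#'   `x`, `y`, `z`; `attr(x, "path_length")` is the summed step length and
#'   `attr(x, "end_to_end")` the start-to-finish distance (Angstrom).
#' @export
travel_trail <- function(topology, frames, residue, side_chain = TRUE,
                         molecule_id = NULL) {
  rows <- residue_rows(topology, residue, molecule_id = molecule_id)
  use <- side_chain_rows(topology, rows, side_chain = side_chain)
  if (!length(use)) use <- rows[topology$element[rows] != "H"]
  w <- topology$mass[use]
  nf <- n_frames(frames)
  com <- t(vapply(seq_len(nf), function(f) {
    colSums(frames$coords[use, , f, drop = FALSE] * w) / sum(w)
  }, numeric(3)))
  out <- tibble(frame = seq_len(nf), time = frames$time,
                x = com[, 1], y = com[, 2], z = com[, 3])
  steps <- sqrt(rowSums((com[-1, , drop = FALSE] -
                           com[-nf, , drop = FALSE])^2))
  attr(out, "residue") <- residue
  attr(out, "path_length") <- if (nf > 1) sum(steps) else 0
  attr(out, "end_to_end") <- if (nf > 1) sqrt(sum((com[nf, ] - com[1, ])^2)) else 0
  class(out) <- c("residue_trail", class(out))
  out
}
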