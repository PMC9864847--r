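#' Deterministic Fibonacci sphere lattice
#'
#' Near-uniform unit-sphere point set used for Shrake-Rupley surface
#' sampling; fully deterministic, so SASA values are bit-reproducible.
#'
#' @param n number of points.
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over van-der-Waals spheres (Bondi radii) using a
#' deterministic Fibonacci point lattice.  Every other atom in the system
#' occludes the target group, so the returned area is the group's exposed
#' surface in context.
#'
#' @param topology atom table.
#' @param frames a [frame_series()] (or a single-frame series).
#' @param rows atom-table row positions of the target group.
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param points sphere points per atom.
#' @param frame frame index to evaluate (default 1).
#' @param per_atom return the per-atom breakdown instead of the total.
#' @return Total area in Angstrom^2, or a numeric vector per atom.
#' @export
sasa <- function(topology, frames, rows, probe = 1.4, points = 960,
                 frame = 1, per_atom = FALSE) {
  if (!length(rows)) {
    abort("SASA target group is empty.", class = "raftpath_precondition_error")
  }
  stopifnot(probe >= 0, points >= 12)
  radii <- vdw_radius(topology$element)
  xyz <- frame_coords(frames, frame)
  pts <- fibonacci_sphere(as.integer(points))
  a <- sasa_cpp(xyz, radii, as.integer(rows), probe, pts)
  if (per_atom) a else sum(a)
}

#' Per-residue SASA time series, optionally within one binding stage
#'
#' @param topology atom table.
#' @param frames a [frame_series()].
#' @param residues list or vector of residue selectors.
#' @param segmentation optional [segment_stages()] result, required when
#'   `stage` is given.
#' @param stage restrict frames to one stage label (`"early"`,
#'   `"intermediate"`, `"late"`).
#' @param probe,points see [sasa()].
#' @param stride evaluate every `stride`-th frame of the window.
#' @param molecule_id restrict residue lookup to one peptide.
#' @return Tibble with columns `frame`, `time`, `residue`, `sasa`
#'   (Angstrom^2); per-residue averages in `attr(x, "summary")`.
#' @export
residue_sasa_series <- function(topology, frames, residues,
                                segmentation = NULL, stage = NULL,
                                probe = 1.4, points = 960, stride = 1,
                                molecule_id = NULL) {
  idx <- seq_len(n_frames(frames))
  if (!is.null(stage)) {
    if (is.null(segmentation)) {
      abort("A stage window needs a stage segmentation.",
            class = "raftpath_precondition_error")
    }
    idx <- segmentation$labels$frame[segmentation$labels$stage == stage]
    if (!length(idx)) {
      abort(paste0("No frames carry stage label '", stage, "'."),
            class = "raftpath_precondition_error")
    }
  }
  idx <- idx[seq(1, length(idx), by = stride)]
  radii <- vdw_radius(topology$element)
  pts <- fibonacci_sphere(as.integer(points))
  res_rows <- lapply(residues, function(r) {
    residue_rows(topology, r, molecule_id = molecule_id)
  })
  res_lab <- vapply(residues, as.character, character(1))
  out <- purrr::map_dfr(idx, function(f) {
    xyz <- frame_coords(frames, f)
    tibble(
      frame = f, time = frames$time[f], residue = res_lab,
      sasa = vapply(res_rows, function(rows) {
        sum(sasa_cpp(xyz, radii, as.integer(rows), probe, pts))
      }, numeric(1)))
  })
  summ <- out |>
    group_by(.data$residue) |>
    summarise(mean_sasa = mean(.data$sasa), .groups = "drop")
  attr(out, "summary") <- summ
  class(out) <- c("sasa_series", class(out))
  out
}
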