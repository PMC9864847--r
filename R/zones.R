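# Internal wrapper around the cell-list pair kernel.  box entries that are
# NA/non-finite disable periodicity on that axis; triclinic input never
# reaches here (rejected at load time).
find_pairs <- function(xyz, box, rows_a, rows_b, cutoff, pbc = TRUE) {
  b <- if (pbc) ifelse(is.finite(box), box, -1) else rep(-1, 3)
  pairs_within_cutoff_cpp(xyz, as.numeric(b), as.integer(rows_a),
                          as.integer(rows_b), cutoff)
}

#' Partition the ganglioside raft into three equal-membership zones
#'
#' Ranks gangliosides by the projection of their lateral (xy) centre of
#' mass onto the axis running from the raft centroid towards the peptide's
#' mean lateral position, then cuts the ranking into tertiles:
#' `periphery-far` (away from the peptide), `center`, and
#' `periphery-near` (the peptide-accommodating edge).  When the count is
#' not divisible by three the remainder goes to the centre zone; ties are
#' broken by molecule id.
#'
#' @param topology atom table.
#' @param frames a [frame_series()].
#' @param peptide_anchor explicit lateral anchor `c(x, y)`, or `NULL` to
#'   use the peptide's mean lateral centre of mass over `window`.
#' @param window time window (ns) for the peptide anchor; default the
#'   final quarter of the trajectory, where the stabilised binding site
#'   lies.
#' @param peptide molecule id of the anchoring peptide (default: first
#'   peptide molecule).
#' @return Tibble of class `zone_partition` with columns `molecule_id`,
#'   `zone`, `projection`; the axis and origin are stored as attributes.
#' @export
partition_raft <- function(topology, frames, peptide_anchor = NULL,
                           window = NULL, peptide = NULL) {
  gm_ids <- sort(unique(topology$molecule_id[
    topology$molecule_class == "ganglioside"]))
  if (length(gm_ids) < 3) {
    abort("Raft partition needs at least three ganglioside molecules.",
          class = "raftpath_partition_error")
  }
  idx <- if (is.null(window)) {
    nf <- n_frames(frames)
    seq(max(1L, floor(3 * nf / 4) + 1L), nf)
  } else {
    resolve_window(frames, window)
  }

  # time-averaged lateral COM per ganglioside
  com_xy <- t(vapply(gm_ids, function(id) {
    rows <- atom_rows(topology, molecule_id = id)
    w <- topology$mass[rows]
    xy <- vapply(idx, function(f) {
      colSums(frames$coords[rows, 1:2, f, drop = FALSE] * w) / sum(w)
    }, numeric(2))
    rowMeans(matrix(xy, nrow = 2))
  }, numeric(2)))
  centroid <- colMeans(com_xy)

  if (is.null(peptide_anchor)) {
    pep_ids <- unique(topology$molecule_id[topology$molecule_class == "peptide"])
    if (!length(pep_ids)) {
      abort("No peptide present: supply `peptide_anchor = c(x, y)`.",
            class = "raftpath_partition_error")
    }
    pid <- peptide %||% pep_ids[1]
    rows <- atom_rows(topology, molecule_id = pid)
    w <- topology$mass[rows]
    xy <- vapply(idx, function(f) {
      colSums(frames$coords[rows, 1:2, f, drop = FALSE] * w) / sum(w)
    }, numeric(2))
    peptide_anchor <- rowMeans(matrix(xy, nrow = 2))
  }
  axis <- peptide_anchor - centroid
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-9) axis <- c(1, 0) else axis <- axis / nrm

  proj <- as.vector((com_xy - matrix(centroid, nrow(com_xy), 2,
                                     byrow = TRUE)) %*% axis)
  ord <- order(proj, gm_ids)
  n <- length(gm_ids)
  n_out <- floor(n / 3)
  sizes <- c(n_out, n - 2 * n_out, n_out)
  zone <- rep(c("periphery-far", "center", "periphery-near"), sizes)
  out <- tibble(molecule_id = gm_ids[ord], zone = zone,
                projection = proj[ord]) |>
    arrange(.data$molecule_id)
  attr(out, "axis") <- axis
  attr(out, "origin") <- centroid
  attr(out, "anchor") <- peptide_anchor
  class(out) <- c("zone_partition", class(out))
  out
}

zone_levels <- function() c("periphery-far", "center", "periphery-near")

#' Count water molecules in contact with a target atom group
#'
#' A water molecule counts when any of its (selected) atoms lies within
#' `cutoff` of any target atom under minimum-image distances; the 2.5
#' Angstrom default is a hydrogen-bond-like criterion, so hydrogens are
#' included by default.  Each water counts at most once per frame.
#'
#' @param topology atom table.
#' @param frames a [frame_series()].
#' @param target_rows atom-table row positions of the target group.
#' @param cutoff contact cutoff in Angstrom (closed boundary: exactly
#'   `cutoff` counts).
#' @param water_atoms `"all"` (default) or `"oxygen"`.
#' @param frame_idx frames to evaluate (default all).
#' @return Tibble with columns `frame`, `time`, `count`.
#' @export
water_contacts <- function(topology, frames, target_rows, cutoff = 2.5,
                           water_atoms = c("all", "oxygen"),
                           frame_idx = NULL) {
  water_atoms <- match.arg(water_atoms)
  if (cutoff <= 0) {
    abort("Cutoff must be positive.", class = "raftpath_precondition_error")
  }
  if (!length(target_rows)) {
    abort("Water-contact target set is empty.",
          class = "raftpath_precondition_error")
  }
  w_rows <- which(topology$molecule_class == "water")
  if (water_atoms == "oxygen") {
    w_rows <- w_rows[topology$element[w_rows] == "O"]
  }
  if (!length(w_rows)) {
    abort("Topology contains no water atoms.",
          class = "raftpath_precondition_error")
  }
  idx <- frame_idx %||% seq_len(n_frames(frames))
  counts <- vapply(idx, function(f) {
    p <- find_pairs(frame_coords(frames, f), frame_box(frames, f),
                    w_rows, target_rows, cutoff)
    dplyr::n_distinct(topology$molecule_id[p$ai])
  }, numeric(1))
  tibble(frame = idx, time = frames$time[idx], count = as.integer(counts))
}

#' Per-zone solvation report (water contacts and SASA)
#'
#' For every raft zone, counts the water molecules within the water cutoff
#' of the zone's ganglioside atoms and computes the zone's
#' solvent-accessible surface area, per frame, then summarises per-zone
#' averages and their ordering.
#'
#' @param topology atom table.
#' @param frames a [frame_series()].
#' @param partition a [partition_raft()] result covering all gangliosides.
#' @param moieties optional moiety map; when given with
#'   `sugar_only = TRUE`, only headgroup (non-ceramide) atoms define each
#'   zone's surface.
#' @param water_cutoff water-contact cutoff (Angstrom).
#' @param probe,points SASA parameters (see [sasa()]).
#' @param stride evaluate every `stride`-th frame.
#' @param sugar_only restrict zone atoms to sugar moieties.
#' @param compute_sasa set `FALSE` to skip the SASA column.
#' @return List with `series` (tibble: `frame`, `time`, `zone`, `waters`,
#'   `sasa`), `summary` (per-zone means) and `ordering` (zone with the
#'   minimum / maximum of each quantity).
#' @export
zone_solvation_report <- function(topology, frames, partition,
                                  moieties = NULL, water_cutoff = 2.5,
                                  probe = 1.4, points = 960, stride = 1,
                                  sugar_only = FALSE, compute_sasa = TRUE) {
  gm_ids <- unique(topology$molecule_id[topology$molecule_class == "ganglioside"])
  if (!all(gm_ids %in% partition$molecule_id)) {
    abort("Partition does not cover every ganglioside molecule.",
          class = "raftpath_partition_error")
  }
  zone_rows <- lapply(zone_levels(), function(zn) {
    ids <- partition$molecule_id[partition$zone == zn]
    rows <- atom_rows(topology, molecule_id = ids)
    if (sugar_only) {
      if (is.null(moieties)) {
        abort("`sugar_only = TRUE` needs a moiety map.",
              class = "raftpath_precondition_error")
      }
      sugar <- moiety_rows(topology, moieties,
                           setdiff(moiety_levels(), "ceramide"))
      rows <- intersect(rows, sugar)
    }
    rows
  })
  names(zone_rows) <- zone_levels()

  idx <- seq(1, n_frames(frames), by = stride)
  radii <- vdw_radius(topology$element)
  pts <- fibonacci_sphere(as.integer(points))
  series <- purrr::map_dfr(zone_levels(), function(zn) {
    wc <- water_contacts(topology, frames, zone_rows[[zn]],
                         cutoff = water_cutoff, frame_idx = idx)
    sa <- if (compute_sasa) {
      vapply(idx, function(f) {
        sum(sasa_cpp(frame_coords(frames, f), radii,
                     as.integer(zone_rows[[zn]]), probe, pts))
      }, numeric(1))
    } else {
      rep(NA_real_, length(idx))
    }
    tibble(frame = idx, time = frames$time[idx], zone = zn,
           waters = wc$count, sasa = sa)
  })
  summ <- series |>
    group_by(.data$zone) |>
    summarise(mean_waters = mean(.data$waters),
              mean_sasa = mean(.data$sasa), .groups = "drop") |>
    arrange(match(.data$zone, zone_levels()))
  ordering <- list(
    waters_min = summ$zone[which.min(summ$mean_waters)],
    waters_max = summ$zone[which.max(summ$mean_waters)],
    sasa_min = if (compute_sasa) summ$zone[which.min(summ$mean_sasa)] else NA,
    sasa_max = if (compute_sasa) summ$zone[which.max(summ$mean_sasa)] else NA
  )
  structure(list(series = series, summary = summ, ordering = ordering),
            class = "zone_solvation")
}

#' @export
print.zone_solvation <- function(x, ...) {
  cat("<zone_solvation>\n")
  print(x$summary)
  cat(sprintf("least water: %s; most water: %s\n",
              x$ordering$waters_min, x$ordering$waters_max))
  invisible(x)
}
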