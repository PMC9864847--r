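# centred moving average with edge windows normalised by actual coverage
smooth_centered <- function(x, window) {
  half <- window %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# first index of a run of `persistence` consecutive TRUEs starting at or
# after `from`; NA when none
first_persistent <- function(cond, persistence, from = 1) {
  n <- length(cond)
  if (from > n) return(NA_integer_)
  run <- 0L
  for (i in from:n) {
    run <- if (cond[i]) run + 1L else 0L
    if (run >= persistence) return(i - persistence + 1L)
  }
  NA_integer_
}

# refine a smoothed-series boundary to the first raw-series crossing inside
# +/- half the smoothing window that persists, so isolated noise frames do
# not capture the boundary
refine_boundary <- function(candidate, raw_cond, halfwin, lo_limit,
                            persistence = 1) {
  n <- length(raw_cond)
  lo <- max(lo_limit, candidate - halfwin)
  hi <- min(n, candidate + halfwin)
  for (i in lo:hi) {
    run <- i:min(n, i + persistence - 1L)
    if (all(raw_cond[run])) return(i)
  }
  candidate
}

#' Segment a trajectory into attachment / migration / stabilised stages
#'
#' Uses per-zone contact occupancy to label the binding timeline: the
#' early stage runs from the first persistent attachment to the raft
#' centre, the intermediate stage starts when centre-zone occupancy is
#' persistently lost (`t_detach`), and the late stage starts when
#' occupancy of the peptide-accommodating periphery is regained and holds
#' for at least 80 percent of the remaining frames (`t_stabilize`).
#' Occupancy series are smoothed with a centred moving average for state
#' detection; each boundary is then refined to the nearest raw-occupancy
#' threshold crossing within half a smoothing window, so boundaries land
#' on the actual transition frame rather than the smoothing shoulder.
#'
#' @param contacts a [contact_series()] computed with a zone
#'   [partition_raft()], so per-zone counts are available.
#' @param smoothing_window centred moving-average width in frames.
#' @param min_occupancy contacts required to call a zone occupied.
#' @param persistence frames a state must hold to count.
#' @param late_hold fraction of remaining frames the near-periphery must
#'   stay occupied after `t_stabilize`.
#' @return Object of class `stage_segmentation`: `t_attach`, `t_detach`,
#'   `t_stabilize` (ns), `labels` (tibble `frame`, `time`, `stage`), and
#'   `diagnostics` (smoothed occupancy series and thresholds).  When no
#'   attachment is ever detected all frames are labelled `"unbound"` and a
#'   warning is raised (not an error).
#' @export
segment_stages <- function(contacts, smoothing_window = 21,
                           min_occupancy = 5, persistence = 10,
                           late_hold = 0.8) {
  counts <- contacts$counts
  if (!any(counts$zone == "center")) {
    abort("Contact series has no per-zone counts; supply a partition to contact_series().",
          class = "raftpath_precondition_error")
  }
  nf <- contacts$n_frames
  if (nf < smoothing_window) {
    abort("Fewer frames than the smoothing window.",
          class = "raftpath_precondition_error")
  }
  time <- contacts$time
  occ <- function(zn) {
    v <- integer(nf)
    sub <- counts[counts$zone == zn, ]
    v[sub$frame] <- sub$n
    v
  }
  center_raw <- occ("center")
  near_raw <- occ("periphery-near")
  center_s <- smooth_centered(center_raw, smoothing_window)
  near_s <- smooth_centered(near_raw, smoothing_window)
  halfwin <- smoothing_window %/% 2

  stage <- rep("unbound", nf)
  t_attach <- t_detach <- t_stabilize <- NA_real_

  a <- first_persistent(center_s >= min_occupancy, persistence)
  if (is.na(a)) {
    warn("No persistent attachment detected; all frames labelled 'unbound'.")
    labels <- tibble(frame = seq_len(nf), time = time, stage = stage)
    return(new_stage_segmentation(NA_real_, NA_real_, NA_real_, labels,
                                  center_s, near_s, smoothing_window,
                                  min_occupancy, persistence))
  }
  a <- refine_boundary(a, center_raw >= min_occupancy, halfwin, 1L, persistence)
  t_attach <- time[a]

  d <- first_persistent(center_s < min_occupancy, persistence, from = a + 1L)
  if (is.na(d)) {
    d <- nf + 1L           # permanent central binding: no detachment
    t_detach <- time[nf]
  } else {
    d <- refine_boundary(d, center_raw < min_occupancy, halfwin, a + 1L, persistence)
    t_detach <- time[d]
  }

  s <- NA_integer_
  if (d <= nf) {
    cand <- which(near_s >= min_occupancy)
    cand <- cand[cand >= d]
    for (i in cand) {
      rest <- near_s[i:nf]
      if (mean(rest >= min_occupancy) >= late_hold) { s <- i; break }
    }
    if (!is.na(s)) {
      s <- refine_boundary(s, near_raw >= min_occupancy, halfwin, d, persistence)
      t_stabilize <- time[s]
    } else {
      t_stabilize <- time[nf]
    }
  } else {
    t_stabilize <- time[nf]
  }

  stage[seq_len(nf) >= a] <- "early"
  if (d <= nf) stage[seq_len(nf) >= d] <- "intermediate"
  if (!is.na(s)) stage[seq_len(nf) >= s] <- "late"
  labels <- tibble(frame = seq_len(nf), time = time, stage = stage)
  new_stage_segmentation(t_attach, t_detach, t_stabilize, labels,
                         center_s, near_s, smoothing_window,
                         min_occupancy, persistence)
}

new_stage_segmentation <- function(t_attach, t_detach, t_stabilize, labels,
                                   center_s, near_s, window, min_occ,
                                   persistence) {
  structure(list(
    t_attach = t_attach, t_detach = t_detach, t_stabilize = t_stabilize,
    labels = labels,
    diagnostics = list(
      smoothed = tibble(frame = labels$frame, time = labels$time,
                        center = center_s, periphery_near = near_s),
      smoothing_window = window, min_occupancy = min_occ,
      persistence = persistence)),
    class = "stage_segmentation")
}

#' @export
print.stage_segmentation <- function(x, ...) {
  cat("<stage_segmentation>\n")
  cat(sprintf("  attach %.2f ns | detach %.2f ns | stabilise %.2f ns\n",
              x$t_attach, x$t_detach, x$t_stabilize))
  print(table(x$labels$stage))
  invisible(x)
}

#' @export
tidy.stage_segmentation <- function(x, ...) x$labels

#' @export
glance.stage_segmentation <- function(x, ...) {
  tab <- table(factor(x$labels$stage,
                      levels = c("unbound", "early", "intermediate", "late")))
  tibble(t_attach = x$t_attach, t_detach = x$t_detach,
         t_stabilize = x$t_stabilize,
         n_frames = nrow(x$labels),
         n_unbound = as.integer(tab[["unbound"]]),
         n_early = as.integer(tab[["early"]]),
         n_intermediate = as.integer(tab[["intermediate"]]),
         n_late = as.integer(tab[["late"]]))
}
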