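#' Construct a frame series
#'
#' A `frame_series` holds the time-resolved coordinates of a trajectory:
#' an `n_atoms x 3 x n_frames` array of positions (Angstrom), a time stamp
#' per frame (ns) and an orthorhombic box (Angstrom) per frame.
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom); a plain
#'   `n_atoms x 3` matrix is promoted to a single frame.
#' @param time numeric vector of frame times in ns, strictly increasing.
#' @param box numeric length-3 vector (constant box) or `n_frames x 3`
#'   matrix of orthorhombic box lengths in Angstrom.
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(coords, time = NULL, box = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(nrow(coords), 3L, 1L))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  nf <- dim(coords)[3]
  if (is.null(time)) time <- seq_len(nf) - 1
  if (length(time) != nf) {
    abort("`time` must have one entry per frame.", class = "raftpath_structural_error")
  }
  if (nf > 1 && any(diff(time) <= 0)) {
    abort("Frame times must be strictly increasing.", class = "raftpath_structural_error")
  }
  if (is.null(box)) box <- c(NA_real_, NA_real_, NA_real_)
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  if (nrow(box) != nf || ncol(box) != 3) {
    abort("`box` must be length 3 or an n_frames x 3 matrix.",
          class = "raftpath_structural_error")
  }
  if (any(box[is.finite(box)] <= 0)) {
    abort("Box lengths must be positive.", class = "raftpath_structural_error")
  }
  structure(list(coords = coords, time = as.numeric(time), box = box),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d atoms, %d frames, t = %.3f .. %.3f ns\n",
              n_atoms(x), n_frames(x), x$time[1], x$time[n_frames(x)]))
  b <- x$box[1, ]
  if (all(is.finite(b))) {
    cat(sprintf("  box %.1f x %.1f x %.1f A\n", b[1], b[2], b[3]))
  }
  invisible(x)
}

#' Number of frames / atoms in a frame series
#' @param fs a [frame_series()].
#' @return An integer.
#' @export
n_frames <- function(fs) dim(fs$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(fs) dim(fs$coords)[1]

#' Coordinates of one frame
#' @param fs a [frame_series()].
#' @param i frame index (1-based).
#' @return An `n_atoms x 3` matrix.
#' @export
frame_coords <- function(fs, i) {
  stopifnot(i >= 1, i <= n_frames(fs))
  m <- fs$coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Box lengths of one frame (NA where non-periodic)
#' @inheritParams frame_coords
#' @return Length-3 numeric vector.
#' @export
frame_box <- function(fs, i) fs$box[i, ]

#' Subset a frame series by frame index
#' @param fs a [frame_series()].
#' @param idx integer frame indices to keep, in increasing order.
#' @return A new `frame_series`.
#' @export
subset_frames <- function(fs, idx) {
  frame_series(fs$coords[, , idx, drop = FALSE], fs$time[idx],
               fs$box[idx, , drop = FALSE])
}

# Resolve a time window (c(t0, t1) in ns) or logical/integer frame selection
# into integer frame indices.
resolve_window <- function(fs, window) {
  if (is.null(window)) return(seq_len(n_frames(fs)))
  if (is.logical(window)) return(which(window))
  if (length(window) == 2 && is.numeric(window)) {
    return(which(fs$time >= window[1] & fs$time <= window[2]))
  }
  as.integer(window)
}
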