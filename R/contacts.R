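#' Atom-atom contacts between two groups over a trajectory
#'
#' Lists every pair (one atom from each group) within the cutoff under
#' minimum-image distances, per frame.  When a raft zone partition is
#' supplied, each contact is tagged with the zone of the group-b
#' ganglioside it touches, and per-frame per-zone counts are provided for
#' stage segmentation.
#'
#' @param topology atom table.
#' @param frames a [frame_series()].
#' @param rows_a,rows_b disjoint, non-empty atom-table row positions.
#' @param cutoff contact cutoff in Angstrom (closed boundary).
#' @param partition optional [partition_raft()] result.
#' @return Object of class `contact_series`: a list with `pairs`
#'   (tibble: `frame`, `time`, `atom_a`, `atom_b`, `distance`, `zone`) and
#'   `counts` (tibble: `frame`, `time`, `zone`, `n` — zone `"all"` rows
#'   give the total).
#' @export
contact_series <- function(topology, frames, rows_a, rows_b, cutoff = 3.0,
                           partition = NULL) {
  if (!length(rows_a) || !length(rows_b)) {
    abort("Contact groups must be non-empty.",
          class = "raftpath_precondition_error")
  }
  if (length(intersect(rows_a, rows_b))) {
    abort("Contact groups overlap.", class = "raftpath_precondition_error")
  }
  if (cutoff <= 0) {
    abort("Cutoff must be positive.", class = "raftpath_precondition_error")
  }
  zone_of <- NULL
  if (!is.null(partition)) {
    zone_of <- setNames(partition$zone, partition$molecule_id)
  }
  nf <- n_frames(frames)
  pair_list <- vector("list", nf)
  for (f in seq_len(nf)) {
    p <- find_pairs(frame_coords(frames, f), frame_box(frames, f),
                    rows_a, rows_b, cutoff)
    if (!length(p$ai)) next
    zone <- if (is.null(zone_of)) NA_character_ else {
      unname(zone_of[as.character(topology$molecule_id[p$bi])])
    }
    pair_list[[f]] <- tibble(
      frame = f, time = frames$time[f],
      atom_a = topology$atom_id[p$ai], atom_b = topology$atom_id[p$bi],
      row_a = p$ai, row_b = p$bi,
      distance = p$dist, zone = zone)
  }
  pairs <- bind_rows(pair_list)
  if (!nrow(pairs)) {
    pairs <- tibble(frame = integer(), time = numeric(),
                    atom_a = integer(), atom_b = integer(),
                    row_a = integer(), row_b = integer(),
                    distance = numeric(), zone = character())
  }
  base <- tibble(frame = seq_len(nf), time = frames$time)
  total <- pairs |>
    dplyr::count(.data$frame, name = "n") |>
    dplyr::right_join(base, by = "frame") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n), zone = "all")
  counts <- total[, c("frame", "time", "zone", "n")]
  if (!is.null(partition)) {
    zc <- purrr::map_dfr(zone_levels(), function(zn) {
      pairs |>
        filter(.data$zone == zn) |>
        dplyr::count(.data$frame, name = "n") |>
        dplyr::right_join(base, by = "frame") |>
        mutate(n = ifelse(is.na(.data$n), 0L, .data$n), zone = zn) |>
        select("frame", "time", "zone", "n")
    })
    counts <- bind_rows(counts, zc)
  }
  structure(list(pairs = pairs, counts = arrange(counts, .data$frame),
                 cutoff = cutoff, n_frames = nf, time = frames$time),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("<contact_series> %d frames, %d contacts, cutoff %.2f A\n",
              x$n_frames, nrow(x$pairs), x$cutoff))
  invisible(x)
}

# hydrogens bonded to a heavy atom: same molecule, within 1.2 A
attached_hydrogens <- function(topology, xyz, heavy_row) {
  h <- which(topology$element == "H" &
               topology$molecule_id == topology$molecule_id[heavy_row])
  if (!length(h)) return(integer())
  d <- sqrt(rowSums((xyz[h, , drop = FALSE] -
                       matrix(xyz[heavy_row, ], length(h), 3,
                              byrow = TRUE))^2))
  h[d <= 1.2]
}

#' Default formal-charge rules for electrostatic classification
#'
#' Assigns +/-1 formal charges to atoms by residue/atom-name patterns:
#' lysine and arginine terminal nitrogens, aspartate/glutamate carboxylate
#' oxygens, sialic-acid carboxylate oxygens and monatomic ions.
#'
#' @return Tibble with columns `residue_pattern`, `atom_pattern`, `charge`.
#' @export
default_charge_rules <- function() {
  tibble(
    residue_pattern = c("^LYS", "^ARG", "^ASP", "^GLU", "^GM1|^SIA|^NEU",
                        "^SOD$|^NA$|^POT$|^K$", "^CLA$|^CL$"),
    atom_pattern = c("^NZ", "^NH|^NE$", "^OD", "^OE", "^SO", ".", "."),
    charge = c(1, 1, -1, -1, -1, 1, -1)
  )
}

formal_charges <- function(topology, rules = default_charge_rules()) {
  q <- numeric(nrow(topology))
  for (i in seq_len(nrow(rules))) {
    hit <- q == 0 &
      grepl(rules$residue_pattern[i], topology$residue_name) &
      grepl(rules$atom_pattern[i], toupper(topology$atom_name))
    q[hit] <- rules$charge[i]
  }
  q
}

#' Classify contacts as hydrogen bond, electrostatic and/or van der Waals
#'
#' A contact is tagged `hydrogen_bond` when both atoms are N/O, their
#' distance is at most 3.5 Angstrom, and a donor hydrogen satisfies a
#' D-H...A angle of at least 120 degrees (when no hydrogens are present
#' on either partner the angle test is skipped and a warning record is
#' kept); `electrostatic` when the atoms belong to oppositely charged
#' groups within 4.0 Angstrom; contacts earning neither tag are
#' `van_der_waals`.  A salt bridge may carry both the hydrogen-bond and
#' electrostatic tags.
#'
#' @param topology atom table.
#' @param frames a [frame_series()].
#' @param contacts a [contact_series()] result.
#' @param charge_rules see [default_charge_rules()].
#' @param hbond_dist,hbond_angle,elec_dist classification thresholds.
#' @return The contact pair tibble with logical columns `hydrogen_bond`,
#'   `electrostatic`, `van_der_waals`; degraded angle tests are listed in
#'   `attr(x, "warnings")`.
#' @export
classify_interactions <- function(topology, frames, contacts,
                                  charge_rules = default_charge_rules(),
                                  hbond_dist = 3.5, hbond_angle = 120,
                                  elec_dist = 4.0) {
  pairs <- contacts$pairs
  q <- formal_charges(topology, charge_rules)
  is_no <- topology$element %in% c("N", "O")
  hb <- logical(nrow(pairs))
  el <- logical(nrow(pairs))
  warn_rec <- list()
  for (f in unique(pairs$frame)) {
    xyz <- frame_coords(frames, f)
    sel <- which(pairs$frame == f)
    for (k in sel) {
      ra <- pairs$row_a[k]; rb <- pairs$row_b[k]
      d <- pairs$distance[k]
      if (d <= elec_dist && q[ra] * q[rb] < 0) el[k] <- TRUE
      if (d <= hbond_dist && is_no[ra] && is_no[rb]) {
        ha <- attached_hydrogens(topology, xyz, ra)
        hb_b <- attached_hydrogens(topology, xyz, rb)
        if (!length(ha) && !length(hb_b)) {
          hb[k] <- TRUE   # distance-only criterion, no hydrogens to test
          warn_rec[[length(warn_rec) + 1]] <- tibble(
            frame = f, atom_a = pairs$atom_a[k], atom_b = pairs$atom_b[k],
            note = "no hydrogens: distance-only hydrogen-bond call")
        } else {
          ang_ok <- function(donor, hs, acceptor) {
            any(vapply(hs, function(h) {
              v1 <- xyz[donor, ] - xyz[h, ]
              v2 <- xyz[acceptor, ] - xyz[h, ]
              cosv <- sum(v1 * v2) /
                (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
              acos(pmin(pmax(cosv, -1), 1)) * 180 / pi >= hbond_angle
            }, logical(1)))
          }
          hb[k] <- (length(ha) && ang_ok(ra, ha, rb)) ||
            (length(hb_b) && ang_ok(rb, hb_b, ra))
        }
      }
    }
  }
  out <- pairs
  out$hydrogen_bond <- hb
  out$electrostatic <- el
  out$van_der_waals <- !hb & !el
  attr(out, "warnings") <- bind_rows(warn_rec)
  out
}

aromatic_ring_names <- list(
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HSD = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HSE = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HSP = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

ring_rows <- function(topology, residue, molecule_id = NULL) {
  rows <- residue_rows(topology, residue, molecule_id = molecule_id)
  resn <- topology$residue_name[rows[1]]
  ring_names <- aromatic_ring_names[[resn]]
  if (is.null(ring_names)) {
    abort(paste0("Residue ", resn, " is not aromatic."),
          class = "raftpath_precondition_error")
  }
  rr <- rows[toupper(topology$atom_name[rows]) %in% ring_names]
  if (length(rr) < 5) {
    abort(paste0("Residue has fewer than 5 ring atoms (found ",
                 length(rr), ")."), class = "raftpath_precondition_error")
  }
  rr
}

#' Ring-stacking (pi-pi) series for two aromatic residues
#'
#' Per frame, the distance between the two ring centroids and the acute
#' angle between the ring planes (fitted by SVD); frames meeting both the
#' distance and angle thresholds are flagged as stacked.
#'
#' @param topology atom table.
#' @param frames a [frame_series()].
#' @param residue_a,residue_b aromatic residue selectors.
#' @param max_centroid_dist maximum centroid distance for stacking (A).
#' @param max_angle maximum interplanar angle (degrees).
#' @param molecule_id restrict residue lookup to one peptide.
#' @return Tibble of class `stacking_series` with columns `frame`, `time`,
#'   `distance`, `angle`, `stacked`; the stacked fraction is
#'   `attr(x, "fraction")`.
#' @export
ring_stacking <- function(topology, frames, residue_a, residue_b,
                          max_centroid_dist = 5.5, max_angle = 45,
                          molecule_id = NULL) {
  ra <- ring_rows(topology, residue_a, molecule_id)
  rb <- ring_rows(topology, residue_b, molecule_id)
  nf <- n_frames(frames)
  dist <- numeric(nf)
  ang <- numeric(nf)
  plane_normal <- function(m) {
    c0 <- sweep(m, 2, colMeans(m))
    svd(c0)$v[, 3]
  }
  for (f in seq_len(nf)) {
    xyz <- frame_coords(frames, f)
    ma <- xyz[ra, , drop = FALSE]
    mb <- xyz[rb, , drop = FALSE]
    ca <- colMeans(ma); cb <- colMeans(mb)
    dist[f] <- sqrt(sum((ca - cb)^2))
    na_ <- plane_normal(ma); nb_ <- plane_normal(mb)
    cosv <- abs(sum(na_ * nb_))
    ang[f] <- acos(pmin(pmax(cosv, 0), 1)) * 180 / pi
  }
  out <- tibble(frame = seq_len(nf), time = frames$time,
                distance = dist, angle = ang,
                stacked = dist <= max_centroid_dist & ang <= max_angle)
  attr(out, "fraction") <- mean(out$stacked)
  class(out) <- c("stacking_series", class(out))
  out
}

#' Stacked fraction of a stacking series
#' @param stacking a [ring_stacking()] result.
#' @return Numeric in `[0, 1]`.
#' @export
stacked_fraction <- function(stacking) attr(stacking, "fraction")
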