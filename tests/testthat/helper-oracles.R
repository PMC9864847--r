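# Brute-force all-pairs contact oracle (minimum image, closed boundary).
oracle_pairs <- function(xyz, box, rows_a, rows_b, cutoff) {
  out <- list()
  for (i in rows_a) {
    d <- sweep(xyz[rows_b, , drop = FALSE], 2, xyz[i, ])
    for (k in 1:3) {
      if (is.finite(box[k])) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    }
    dist <- sqrt(rowSums(d^2))
    hit <- which(dist <= cutoff)
    if (length(hit)) {
      out[[length(out) + 1]] <- data.frame(ai = i, bi = rows_b[hit],
                                           dist = dist[hit])
    }
  }
  if (!length(out)) {
    return(data.frame(ai = integer(), bi = integer(), dist = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$ai, res$bi), ]
}

# Distinct-water-count oracle on top of the pair oracle.
oracle_water_count <- function(topology, xyz, box, target_rows, cutoff) {
  w <- which(topology$molecule_class == "water")
  p <- oracle_pairs(xyz, box, w, target_rows, cutoff)
  length(unique(topology$molecule_id[p$ai]))
}

# Shrake-Rupley refinement oracle: random (seeded) sphere points, written
# independently of the package's Fibonacci-lattice kernel.
oracle_sasa_random <- function(xyz, radii, subset, probe, n_points = 1e5,
                               seed = 42) {
  withr::with_seed(seed, {
    total <- 0
    for (i in subset) {
      Ri <- radii[i] + probe
      g <- matrix(stats::rnorm(n_points * 3), ncol = 3)
      g <- g / sqrt(rowSums(g^2))
      pts <- sweep(g * Ri, 2, xyz[i, ], "+")
      free <- rep(TRUE, n_points)
      for (j in seq_len(nrow(xyz))) {
        if (j == i) next
        rj <- radii[j] + probe
        dj2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
        free <- free & dj2 >= rj^2
      }
      total <- total + 4 * pi * Ri^2 * mean(free)
    }
    total
  })
}

# Minimal atom-table constructor for toy geometries.
toy_topology <- function(atom_name, element, residue_name, molecule_class,
                         residue_id = NULL, molecule_id = NULL) {
  n <- length(atom_name)
  as_topology(data.frame(
    atom_id = seq_len(n), atom_name = atom_name, element = element,
    residue_id = residue_id %||% seq_len(n),
    residue_name = residue_name,
    molecule_id = molecule_id %||% seq_len(n),
    molecule_class = molecule_class))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Cached reference systems so expensive generations run once per session.
.raftpath_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.raftpath_cache[[key]])) .raftpath_cache[[key]] <- force(expr)
  .raftpath_cache[[key]]
}
default_sys <- function() cached("default", generate_system(synthetic_spec(seed = 101)))
small_sys <- function() {
  cached("small", generate_system(synthetic_spec(
    n_frames = 60, stride_ns = 1, stage_boundaries = c(25, 40),
    t_attach = 2, n_waters = 150, shell_waters_base = 30, seed = 55)))
}
comp_sys <- function() {
  cached("comp", generate_system(synthetic_competition_spec(seed = 77)))
}
comp_sys_wo <- function() {
  cached("comp_wo",
         generate_system(synthetic_competition_spec(FALSE, seed = 78)))
}
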