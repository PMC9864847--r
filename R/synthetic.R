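#' Specification for a synthetic raft-peptide system
#'
#' Describes a desk-scale toy system with fully known ground truth: a
#' lattice cluster of GM1-like gangliosides (ceramide anchor plus five
#' sugar pseudo-moieties stacked at prescribed z ceilings), sterols at a
#' 1:1 ratio, a phospholipid ring defining the two leaflets, a water slab
#' with per-zone shell-water densities, counter ions, and a peptide whose
#' centre of mass follows a scripted three-stage path: central attachment,
#' detachment and migration around the raft edge, stabilised peripheral
#' binding.  Positional noise is Gaussian: lipid and water atoms jitter
#' independently; peptide residues receive a rigid per-residue translation
#' (the tracked aromatic pair H9/H10 moves as one rigid sub-unit, and a
#' U-folded residue pair moves with its folding partner) plus a small
#' per-atom jitter.
#'
#' The defaults are the package's reference study conditions: 500 frames
#' at 0.12 ns (about 60 ns), stage boundaries at 30 and 45 ns, first
#' contact at 1.2 ns after a descent from 12 Angstrom above the raft,
#' moiety ceilings 18 < 23 < 26 < 28 < 30 < 31 Angstrom above the planted
#' bilayer centre (35 Angstrom in box coordinates), burial-average
#' targets Y6 41.36 < H9 46.30 < H10 47.10 Angstrom (absolute box z), a
#' centre zone holding half the shell water of the far periphery, and a
#' ring-stacked fraction of 0.6 in the late stage.
#'
#' @param ... overrides of any default field (unknown names are an error).
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(...) {
  spec <- list(
    n_ganglioside = 24,
    sterol_ratio = 1,
    n_phospholipid = 36,
    n_waters = 800,
    shell_waters_base = 120,
    zone_water_multipliers = c("periphery-far" = 1.0, "center" = 0.5,
                               "periphery-near" = 1.2),
    lattice_spacing = 8,
    zone_spacing_factors = c("periphery-far" = 1.0, "center" = 0.8,
                             "periphery-near" = 1.2),
    moiety_ceilings = c("ceramide" = 18, "glucose" = 23,
                        "galactose-inner" = 26, "GalNAc" = 28,
                        "galactose-terminal" = 30, "sialic-acid" = 31),
    bilayer_center_z = 35,
    leaflet_half_thickness = 18,
    noise_sd = 1.0,
    atom_noise_sd = 0.3,
    lipid_noise_sd = 0.5,
    water_noise_sd = 0.3,
    burial_targets = c(Y6 = 41.36, H9 = 46.30, H10 = 47.10),
    migration_lift = 6,
    stage_boundaries = c(30, 45),
    t_attach = 1.2,
    approach_height = 12,
    periphery_x = 26,
    n_frames = 500,
    stride_ns = 0.12,
    box = c(120, 120, 100),
    stack_fraction = 0.6,
    anchor_offset = 1.0,
    shell_water_dist = 1.8,
    include_peptide = TRUE,
    include_competitor = FALSE,
    competitor_first_contact = 4.0,
    masking_fraction = 0.70,
    dip = NULL,
    seed = 1
  )
  perturb(structure(spec, class = "synthetic_spec"), ...)
}

#' Derive a new spec with some fields overridden
#'
#' @param spec a [synthetic_spec()].
#' @param ... `key = value` overrides (or a single named list); keys must
#'   exist in the spec.
#' @return A new validated spec; the original is untouched.
#' @export
perturb <- function(spec, ...) {
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(spec))
  if (length(unknown)) {
    abort(paste0("Unknown spec field(s): ", paste(unknown, collapse = ", ")),
          class = "raftpath_spec_error")
  }
  for (k in names(overrides)) spec[[k]] <- overrides[[k]]
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  if (spec$n_ganglioside < 1) {
    abort("Need at least one ganglioside.", class = "raftpath_spec_error")
  }
  if (spec$sterol_ratio <= 0) {
    abort("sterol_ratio must be positive.", class = "raftpath_spec_error")
  }
  if (any(c(spec$noise_sd, spec$atom_noise_sd, spec$lipid_noise_sd,
            spec$water_noise_sd) < 0)) {
    abort("Noise SDs must be non-negative.", class = "raftpath_spec_error")
  }
  b <- spec$stage_boundaries
  if (all(is.finite(b)) && diff(b) <= 0) {
    abort("Stage boundaries must be increasing.",
          class = "raftpath_spec_error")
  }
  if (any(is.finite(b)) && spec$t_attach >= min(b[is.finite(b)])) {
    abort("Impossible script: attachment after the first stage boundary.",
          class = "raftpath_spec_error")
  }
  if (spec$n_frames < 2) {
    abort("Need at least 2 frames.", class = "raftpath_spec_error")
  }
  invisible(spec)
}

#' Reference spec for the two-peptide competition system
#'
#' Four gangliosides on a square patch inside a phospholipid/sterol ring,
#' with (`with_peptides = TRUE`) or without the designed-peptide /
#' competitor pair above the headgroups.  With the peptides present the
#' headgroups are planted spread apart (lattice spacing 9 Angstrom);
#' without them they pack at 7 Angstrom.  The designed peptide first
#' touches the gangliosides at 1.2 ns, the competitor at 4.0 ns, and the
#' competitor's aromatic residues H13/H14 are masked by its U-fold in 70
#' percent of frames.
#'
#' @param with_peptides include the two peptides.
#' @param ... further overrides, as in [perturb()].
#' @return A `synthetic_spec`.
#' @export
synthetic_competition_spec <- function(with_peptides = TRUE, ...) {
  spec <- synthetic_spec(
    n_ganglioside = 4,
    n_phospholipid = 24,
    n_waters = 300,
    shell_waters_base = 40,
    zone_water_multipliers = c("periphery-far" = 1, "center" = 1,
                               "periphery-near" = 1),
    lattice_spacing = if (with_peptides) 9 else 7,
    zone_spacing_factors = c("periphery-far" = 1, "center" = 1,
                             "periphery-near" = 1),
    n_frames = 250,
    stride_ns = 0.04,
    stage_boundaries = c(Inf, Inf),
    include_peptide = with_peptides,
    include_competitor = with_peptides,
    periphery_x = 0
  )
  perturb(spec, ...)
}

# ---- residue geometry templates ------------------------------------------

aa_side_templates <- list(
  LYS = tibble(atom_name = c("CB", "CG", "CD", "CE", "NZ"),
               element = c("C", "C", "C", "C", "N"),
               dx = c(0.5, 1.0, 1.4, 1.8, 2.2),
               dy = c(0.5, 0.8, 1.0, 1.2, 1.4),
               dz = c(-1, -2, -3, -4, -5)),
  ALA = tibble(atom_name = "CB", element = "C", dx = 0.5, dy = 0.5, dz = -1),
  SER = tibble(atom_name = c("CB", "OG"), element = c("C", "O"),
               dx = c(0.5, 1.0), dy = c(0.5, 0.8), dz = c(-1, -2)),
  VAL = tibble(atom_name = c("CB", "CG1", "CG2"),
               element = c("C", "C", "C"),
               dx = c(0.5, 1.2, 0.2), dy = c(0.5, 0.8, 1.3),
               dz = c(-1, -1.8, -1.8))
)
backbone_template <- tibble(
  atom_name = c("N", "CA", "C"), element = c("N", "C", "C"),
  dx = c(-0.6, 0, 0.6), dy = c(-0.4, 0, 0.4), dz = c(0, 0, 0))

his_ring <- list(names = c("CG", "ND1", "CD2", "CE1", "NE2"),
                 elements = c("C", "N", "C", "C", "N"), radius = 1.15)
tyr_ring <- list(names = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                 elements = c("C", "C", "C", "C", "C", "C"), radius = 1.35)

# ring atoms in the plane orthogonal to a normal tilted `ang_deg` from +x
# within the xy plane (a vertical ring)
ring_atoms_vertical <- function(center, ang_deg, ring) {
  th <- ang_deg * pi / 180
  u <- c(-sin(th), cos(th), 0)
  v <- c(0, 0, 1)
  al <- 2 * pi * (seq_along(ring$names) - 1) / length(ring$names)
  t(vapply(seq_along(al), function(i) {
    center + ring$radius * (cos(al[i]) * u + sin(al[i]) * v)
  }, numeric(3)))
}

# flat (membrane-parallel) ring
ring_atoms_flat <- function(center, ring) {
  al <- 2 * pi * (seq_along(ring$names) - 1) / length(ring$names)
  t(vapply(seq_along(al), function(i) {
    center + ring$radius * c(cos(al[i]), sin(al[i]), 0)
  }, numeric(3)))
}

# shift rows so the mass-weighted COM z equals target_z (xy untouched)
com_shift_z <- function(xyz, masses, target_z) {
  comz <- sum(xyz[, 3] * masses) / sum(masses)
  xyz[, 3] <- xyz[, 3] + (target_z - comz)
  xyz
}

gm1_atom_template <- function(ceilings) {
  tibble(
    atom_name = c("CER1", "CER2", "CER3", "CER4",
                  "GLC1", "GLC2", "GLC3",
                  "GLI1", "GLI2", "GLI3",
                  "GNC1", "GNC2", "GNC3",
                  "GLT1", "GLT2", "GLT3",
                  "SIA1", "SIA2", "SO1"),
    element = c("C", "C", "C", "C",
                "C", "O", "C", "C", "O", "C", "C", "N", "C",
                "C", "O", "C", "C", "C", "O"),
    moiety = rep(moiety_levels(), times = c(4, 3, 3, 3, 3, 3)),
    dx = c(0.0, 0.5, -0.4, 0.1,
           0.8, 0.9, 0.5, -0.8, -0.6, -1.0, 0.0, 0.3, -0.3,
           0.7, 0.9, 0.4, -0.6, -0.8, -0.4),
    dy = c(0.0, 0.3, 0.2, -0.4,
           0.0, 0.3, -0.5, 0.5, 0.8, 0.2, -0.9, -1.1, -0.8,
           0.7, 0.9, 0.5, -0.7, -0.9, -0.5),
    dz = c(ceilings[["ceramide"]] + c(0, -4, -8, -12),
           ceilings[["glucose"]] + c(0, -3, -5.5),
           ceilings[["galactose-inner"]] + c(0, -3, -5.5),
           ceilings[["GalNAc"]] + c(0, -3, -5.5),
           ceilings[["galactose-terminal"]] + c(0, -3, -5.5),
           ceilings[["sialic-acid"]] + c(0, -4, -5))
  )
}

# lateral lattice for n gangliosides, centred at the origin
gm_lattice <- function(n, spacing) {
  nrow_ <- max(1, round(sqrt(n / 1.5)))
  ncol_ <- ceiling(n / nrow_)
  pos <- matrix(0, n, 2)
  k <- 1
  for (cc in seq_len(ncol_)) {
    for (rr in seq_len(nrow_)) {
      if (k > n) break
      pos[k, ] <- c((cc - (ncol_ + 1) / 2) * spacing,
                    (rr - (nrow_ + 1) / 2) * spacing +
                      ifelse(cc %% 2 == 0, spacing / 4, -spacing / 4))
      k <- k + 1
    }
  }
  pos
}

# zone labels by x-tertiles, far -> center -> near, remainder to center
plant_zones <- function(pos, ids) {
  n <- nrow(pos)
  if (n < 3) return(rep(NA_character_, n))
  ord <- order(pos[, 1], ids)
  n_out <- floor(n / 3)
  z <- rep(c("periphery-far", "center", "periphery-near"),
           c(n_out, n - 2 * n_out, n_out))
  out <- character(n)
  out[ord] <- z
  out
}

#' Generate a synthetic system with known ground truth
#'
#' Builds the topology and trajectory described by a [synthetic_spec()].
#' Deterministic given `spec$seed`: two calls produce identical output.
#'
#' @param spec a [synthetic_spec()].
#' @param write_to optional directory; when given, `system.pdb`,
#'   `traj.dcd` and `ground_truth.json` are written there.
#' @return List with `topology` (atom table), `frames`
#'   ([frame_series()]) and `truth` (list of planted quantities).
#' @export
generate_system <- function(spec, write_to = NULL) {
  validate_spec(spec)
  withr::with_seed(spec$seed, generate_system_impl(spec, write_to))
}

generate_system_impl <- function(spec, write_to) {
  z0 <- spec$bilayer_center_z
  half <- spec$leaflet_half_thickness
  nf <- spec$n_frames
  time <- (seq_len(nf) - 1) * spec$stride_ns
  top_names <- c("SIA1", "GLT1", "GNC1")

  # --- static molecules -----------------------------------------------------
  n_gm <- spec$n_ganglioside
  pos <- gm_lattice(n_gm, spec$lattice_spacing)
  gm_ids <- seq_len(n_gm)
  zones <- plant_zones(pos, gm_ids)
  if (!all(is.na(zones))) {
    for (zn in unique(zones)) {
      sel <- which(zones == zn)
      ctr <- colMeans(pos[sel, , drop = FALSE])
      fac <- spec$zone_spacing_factors[[zn]]
      pos[sel, ] <- sweep(sweep(pos[sel, , drop = FALSE], 2, ctr) * fac,
                          2, ctr, "+")
    }
  }
  gm_tmpl <- gm1_atom_template(spec$moiety_ceilings)

  atoms <- list()
  base <- list()
  res_counter <- 0L
  mol_counter <- 0L
  add_molecule <- function(names, elements, xyz, resname, class, jitter) {
    mol_counter <<- mol_counter + 1L
    res_counter <<- res_counter + 1L
    atoms[[length(atoms) + 1]] <<- tibble(
      atom_name = names, element = elements,
      residue_id = res_counter, residue_name = resname,
      molecule_id = mol_counter, molecule_class = class,
      noise = jitter)
    base[[length(base) + 1]] <<- xyz
    mol_counter
  }

  for (i in gm_ids) {
    xyz <- cbind(pos[i, 1] + gm_tmpl$dx, pos[i, 2] + gm_tmpl$dy,
                 z0 + gm_tmpl$dz)
    add_molecule(gm_tmpl$atom_name, gm_tmpl$element, xyz, "GM1",
                 "ganglioside", spec$lipid_noise_sd)
  }
  gm_mol_ids <- seq_len(n_gm)

  n_st <- round(n_gm * spec$sterol_ratio)
  for (i in seq_len(n_st)) {
    p <- pos[((i - 1) %% n_gm) + 1, ] + spec$lattice_spacing * c(0.5, 0.5)
    xyz <- cbind(p[1] + c(0, 0.3, -0.3), p[2] + c(0, 0.3, -0.3),
                 z0 + c(half, 10, 2))
    add_molecule(c("O1", "C1", "C2"), c("O", "C", "C"), xyz, "CHL1",
                 "sterol", spec$lipid_noise_sd)
  }

  n_pl <- spec$n_phospholipid
  ring_r <- max(abs(pos)) + 14
  for (i in seq_len(n_pl)) {
    th <- 2 * pi * (i - 1) / n_pl
    sgn <- if (i %% 2 == 1) 1 else -1
    p <- ring_r * c(cos(th), sin(th))
    xyz <- cbind(p[1] + c(0, 0.3, -0.3, 0.2, -0.2),
                 p[2] + c(0, -0.3, 0.3, 0.2, -0.2),
                 z0 + sgn * c(half, half - 6, half - 10, half - 14,
                              half - 16))
    add_molecule(c("P", "C2", "C3", "C4", "N1"),
                 c("P", "C", "C", "C", "N"), xyz, "POPC", "phospholipid",
                 spec$lipid_noise_sd)
  }

  slab_lo <- z0 + max(spec$moiety_ceilings) + 14
  slab_hi <- spec$box[3] - 2
  add_water <- function(o) {
    xyz <- rbind(o, o + c(0.4, 0, 0.8), o + c(-0.4, 0, 0.8))
    add_molecule(c("OH2", "H1", "H2"), c("O", "H", "H"), xyz, "TIP3",
                 "water", spec$water_noise_sd)
  }
  for (i in seq_len(spec$n_waters)) {
    add_water(c(stats::runif(1, -spec$box[1] / 2 + 2, spec$box[1] / 2 - 2),
                stats::runif(1, -spec$box[2] / 2 + 2, spec$box[2] / 2 - 2),
                stats::runif(1, slab_lo, slab_hi)))
  }

  # per-zone shell waters, each tethered to a sugar-top atom of its zone
  zone_names <- zone_levels()
  if (all(is.na(zones))) {
    shell_mols <- rep(gm_mol_ids,
                      length.out = round(spec$shell_waters_base * n_gm / 8))
  } else {
    shell_counts <- round(spec$shell_waters_base *
                            spec$zone_water_multipliers[zone_names])
    shell_mols <- unlist(lapply(zone_names, function(zn) {
      rep(gm_mol_ids[zones == zn], length.out = shell_counts[[zn]])
    }))
  }
  golden <- pi * (3 - sqrt(5))
  gm_top_rows_local <- which(gm_tmpl$atom_name %in% top_names)
  for (i in seq_along(shell_mols)) {
    anchor_xyz <- base[[shell_mols[i]]][
      gm_top_rows_local[(i %% length(gm_top_rows_local)) + 1], ]
    th <- 30 * pi / 180
    ph <- golden * i
    dirv <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    add_water(anchor_xyz + spec$shell_water_dist * dirv)
  }

  for (i in 1:8) {
    add_molecule("SOD", "NA", matrix(c(stats::runif(2, -40, 40),
                                       stats::runif(1, slab_lo, slab_hi)),
                                     1), "SOD", "ion", spec$water_noise_sd)
    add_molecule("CLA", "CL", matrix(c(stats::runif(2, -40, 40),
                                       stats::runif(1, slab_lo, slab_hi)),
                                     1), "CLA", "ion", spec$water_noise_sd)
  }

  n_static_atoms <- sum(vapply(base, nrow, numeric(1)))

  # --- peptide definitions --------------------------------------------------
  center_mols <- if (all(is.na(zones))) gm_mol_ids else
    gm_mol_ids[zones == "center"]
  near_mols <- if (all(is.na(zones))) gm_mol_ids else
    gm_mol_ids[zones == "periphery-near"]
  peptides <- list()
  if (spec$include_peptide) {
    peptides$main <- list(
      seq = c("LYS", "ALA", "SER", "VAL", "ALA", "TYR", "VAL", "SER",
              "HSD", "HSD", "ALA", "LYS"),
      anchors = list(c(1, "CE"), c(1, "NZ"), c(3, "CB"), c(3, "OG"),
                     c(4, "CG1"), c(4, "CG2"), c(7, "CG1"), c(7, "CG2"),
                     c(8, "CB"), c(8, "OG"), c(12, "CE"), c(12, "NZ")),
      tracked = c(Y6 = 6, H9 = 9, H10 = 10),
      t_attach = spec$t_attach,
      center_targets = center_mols,
      near_targets = near_mols,
      lateral_early = c(0, 0),
      lateral_late = c(spec$periphery_x, 0))
  }
  if (spec$include_competitor) {
    peptides$competitor <- list(
      seq = c("LYS", "ALA", "SER", "VAL", "ALA", "TYR", "VAL", "SER",
              "HSD", "HSD", "ALA", "LYS", "HSD", "HSD"),
      anchors = list(c(3, "CB"), c(3, "OG"), c(4, "CG1"), c(4, "CG2")),
      tracked = c(),
      t_attach = spec$competitor_first_contact,
      center_targets = gm_mol_ids[length(gm_mol_ids)],
      near_targets = gm_mol_ids[length(gm_mol_ids)],
      lateral_early = c(-6, 14),
      lateral_late = c(-6, 14))
  }

  # register peptide atoms (placeholder base coordinates)
  pep_meta <- list()
  for (pn in names(peptides)) {
    p <- peptides[[pn]]
    mol_counter <- mol_counter + 1L
    templates <- list()
    for (ri in seq_along(p$seq)) {
      resname <- p$seq[ri]
      sc <- if (ri %in% p$tracked) {
        if (resname == "TYR") {
          tibble(atom_name = c(tyr_ring$names, "CB", "OH"),
                 element = c(tyr_ring$elements, "C", "O"),
                 dx = 0, dy = 0, dz = 0)
        } else {
          tibble(atom_name = c(his_ring$names, "CB"),
                 element = c(his_ring$elements, "C"),
                 dx = 0, dy = 0, dz = 0)
        }
      } else if (pn == "competitor" && ri %in% c(13, 14)) {
        tibble(atom_name = c(his_ring$names, "CB"),
               element = c(his_ring$elements, "C"),
               dx = 0, dy = 0, dz = 0)
      } else {
        aa_side_templates[[resname]]
      }
      tmpl <- bind_rows(backbone_template, sc)
      atoms[[length(atoms) + 1]] <- tibble(
        atom_name = tmpl$atom_name, element = tmpl$element,
        residue_id = ri, residue_name = resname,
        molecule_id = mol_counter, molecule_class = "peptide",
        noise = 0)
      base[[length(base) + 1]] <- matrix(0, nrow(tmpl), 3)
      templates[[ri]] <- tmpl
    }
    pep_meta[[pn]] <- list(def = p, mol_id = mol_counter,
                           templates = templates)
  }

  topology_df <- bind_rows(atoms)
  topology_df$atom_id <- seq_len(nrow(topology_df))
  noise_sd_atom <- topology_df$noise
  topology <- as_topology(topology_df[, c("atom_id", "atom_name", "element",
                                          "residue_id", "residue_name",
                                          "molecule_id", "molecule_class")])
  base_xyz <- do.call(rbind, base)
  n_all <- nrow(topology)

  for (pn in names(pep_meta)) {
    pep_meta[[pn]]$res_rows <- lapply(seq_along(pep_meta[[pn]]$def$seq),
      function(ri) {
        which(topology$molecule_id == pep_meta[[pn]]$mol_id &
                topology$residue_id == ri)
      })
  }

  # --- schedules ------------------------------------------------------------
  b <- spec$stage_boundaries
  mig_frames <- which(time >= b[1] & time < b[2])
  late_frames <- which(time >= b[2])
  snap_time <- function(tt) {
    i <- which(time >= tt)[1]
    if (is.na(i)) NA_real_ else time[i]
  }
  stacked <- logical(nf)
  if (length(late_frames) > 1) {
    stacked[sample(late_frames,
                   round(spec$stack_fraction * length(late_frames)))] <- TRUE
  }
  masked <- logical(nf)
  if (spec$include_competitor) {
    masked[sample(nf, round(spec$masking_fraction * nf))] <- TRUE
  }
  dipped <- logical(nf)
  if (!is.null(spec$dip)) {
    dipped[sample(nf, round(spec$dip$fraction * nf))] <- TRUE
  }

  approach_offset <- function(tt, t_attach) {
    if (tt >= t_attach) return(0)
    max(10, spec$approach_height * (1 - tt / max(t_attach, 1e-9)))
  }
  extra_for <- function(t_attach) {
    appr <- vapply(time, approach_offset, numeric(1), t_attach = t_attach)
    lift <- numeric(nf)
    lift[mig_frames] <- spec$migration_lift
    appr + lift
  }

  # --- coordinates ----------------------------------------------------------
  coords <- array(0, dim = c(n_all, 3L, nf))
  static_rows <- seq_len(n_static_atoms)
  for (f in seq_len(nf)) {
    jitter <- matrix(stats::rnorm(n_static_atoms * 3), ncol = 3) *
      noise_sd_atom[static_rows]
    coords[static_rows, , f] <- base_xyz[static_rows, ] + jitter
  }

  anchor_target_rows <- function(mols, n_needed) {
    rows <- unlist(lapply(mols, function(m) {
      which(topology$molecule_id == m & topology$atom_name %in% top_names)
    }))
    rows[rep(seq_along(rows), length.out = n_needed)]
  }

  zbb <- z0 + 37                       # backbone altitude when bound
  pep_target_z <- list()
  for (pn in names(pep_meta)) {
    pm <- pep_meta[[pn]]
    p <- pm$def
    nres <- length(p$seq)
    extra <- extra_for(p$t_attach)
    anchor_keys <- vapply(p$anchors, function(a) paste(a[1], a[2]),
                          character(1))
    a_rows_center <- anchor_target_rows(p$center_targets, length(p$anchors))
    a_rows_near <- anchor_target_rows(p$near_targets, length(p$anchors))
    trk <- p$tracked
    # bound depth chosen so the full-trajectory mean hits the target
    bound_depth <- if (length(trk)) {
      spec$burial_targets[names(trk)] - mean(extra)
    } else numeric()
    for (nm in names(trk)) pep_target_z[[nm]] <- numeric(nf)

    for (f in seq_len(nf)) {
      tt <- time[f]
      phase <- if (!is.finite(b[1]) || tt < b[1]) "early"
        else if (tt < b[2]) "migration" else "late"
      lat <- switch(phase,
        early = p$lateral_early,
        late = p$lateral_late,
        migration = c(p$lateral_early[1] +
                        (p$lateral_late[1] - p$lateral_early[1]) *
                          (tt - b[1]) / max(b[2] - b[1], 1e-9), -30))
      if (tt < p$t_attach) lat <- p$lateral_early + c(0, -35)
      e <- extra[f]

      trans <- matrix(stats::rnorm(nres * 3, sd = spec$noise_sd), ncol = 3)
      if (all(c("H9", "H10") %in% names(trk))) trans[10, ] <- trans[9, ]
      if (pn == "competitor" && masked[f]) {
        trans[13, ] <- trans[2, ]
        trans[14, ] <- trans[1, ]
      }

      for (ri in seq_len(nres)) {
        tmpl <- pm$templates[[ri]]
        rows <- pm$res_rows[[ri]]
        if (pn == "competitor") {
          if (ri <= 7) {
            cx <- lat[1] + (ri - 4) * 3.2
            cy <- lat[2]
          } else {
            cx <- lat[1] + ((15 - ri) - 4) * 3.2
            cy <- lat[2] + (if (masked[f]) 1.6 else 9)
          }
        } else {
          cx <- lat[1] + (ri - (nres + 1) / 2) * 2.2
          cy <- lat[2] + ifelse(ri %% 2 == 0, 1.2, -1.2)
        }
        cz <- zbb + e
        bb_xyz <- cbind(cx + backbone_template$dx,
                        cy + backbone_template$dy,
                        cz + backbone_template$dz)
        xyz <- cbind(cx + tmpl$dx, cy + tmpl$dy, cz + tmpl$dz)
        xyz[1:3, ] <- bb_xyz

        trk_name <- if (length(trk) && ri %in% trk) {
          names(trk)[match(ri, trk)]
        } else NA_character_

        if (!is.na(trk_name)) {
          resname <- p$seq[ri]
          tz <- bound_depth[[trk_name]] + e
          if (!is.null(spec$dip) && spec$dip$residue == trk_name) {
            ceil_abs <- z0 + spec$moiety_ceilings[[spec$dip$moiety]]
            tz <- ceil_abs + ifelse(dipped[f], -3, 3)
          }
          pep_target_z[[trk_name]][f] <- tz
          if (resname == "TYR") {
            ctr <- c(lat[1] - 5, lat[2], tz)
            sc_xyz <- rbind(ring_atoms_flat(ctr, tyr_ring),
                            ctr + c(0, 0, -1.5), ctr + c(0, 0, 1.2))
          } else if (trk_name == "H9") {
            ctr <- c(lat[1], lat[2], tz)
            sc_xyz <- rbind(ring_atoms_vertical(ctr, 0, his_ring),
                            ctr + c(0, 0, -1.5))
          } else {                     # H10: stacked on H9 or swung away
            if (stacked[f]) {
              ctr <- c(lat[1], lat[2] + 4, tz); ang <- 0
            } else {
              ctr <- c(lat[1], lat[2] + 9, tz); ang <- 80
            }
            sc_xyz <- rbind(ring_atoms_vertical(ctr, ang, his_ring),
                            ctr + c(0, 0, -1.5))
          }
          masses <- atom_mass(tmpl$element)
          sc_idx <- seq(4, nrow(tmpl))
          sc_xyz <- com_shift_z(sc_xyz, masses[sc_idx], tz)
          xyz <- rbind(bb_xyz, sc_xyz)
        } else if (pn == "competitor" && ri %in% c(13, 14)) {
          partner <- if (ri == 13) 2 else 1
          pctr <- c(lat[1] + (partner - 4) * 3.2 + 0.5,
                    lat[2] + (if (masked[f]) 1.6 else 9),
                    zbb + e - 1 + 1.15)
          xyz <- rbind(bb_xyz,
                       ring_atoms_vertical(pctr, 90, his_ring),
                       pctr + c(0, 0, 1.5))
        }

        hit <- which(anchor_keys %in% paste(ri, tmpl$atom_name))
        if (length(hit) && phase != "migration") {
          t_rows <- if (phase == "late") a_rows_near else a_rows_center
          for (h in hit) {
            ai <- match(strsplit(anchor_keys[h], " ")[[1]][2],
                        tmpl$atom_name)
            xyz[ai, ] <- base_xyz[t_rows[h], ] +
              c(0, 0, spec$anchor_offset + e)
          }
        }

        jitter <- matrix(stats::rnorm(length(rows) * 3,
                                      sd = spec$atom_noise_sd), ncol = 3)
        coords[rows, , f] <- xyz +
          matrix(trans[ri, ], length(rows), 3, byrow = TRUE) + jitter
      }
    }
  }

  frames <- frame_series(coords, time = time, box = spec$box)

  # --- ground truth ---------------------------------------------------------
  truth <- list(
    bilayer_center_z = z0,
    moiety_ceilings = spec$moiety_ceilings,
    zones = tibble(molecule_id = gm_mol_ids, zone = zones),
    classes = dplyr::distinct(as_tibble(topology)[, c("molecule_id",
                                                      "molecule_class")]),
    moieties = tibble(
      atom_id = topology$atom_id[topology$molecule_class == "ganglioside"],
      moiety = rep(gm_tmpl$moiety, n_gm)),
    water_multipliers = spec$zone_water_multipliers,
    water_count_ratio_center_vs_far =
      unname(spec$zone_water_multipliers[["center"]] /
               spec$zone_water_multipliers[["periphery-far"]])
  )
  if (length(pep_target_z)) {
    truth$burial_avg <- vapply(pep_target_z, mean, numeric(1))
  }
  truth$stage_boundaries <- c(t_attach = snap_time(spec$t_attach),
                              t_detach = snap_time(b[1]),
                              t_stabilize = snap_time(b[2]))
  truth$first_contact <- c()
  if (spec$include_peptide) {
    truth$first_contact["main"] <- snap_time(spec$t_attach)
    truth$peptide_main <- pep_meta$main$mol_id
  }
  if (spec$include_competitor) {
    truth$first_contact["competitor"] <-
      snap_time(spec$competitor_first_contact)
    truth$peptide_competitor <- pep_meta$competitor$mol_id
    truth$masking_fraction <- mean(masked)
  }
  if (length(late_frames) > 1) {
    truth$stack_fraction <- mean(stacked[late_frames])
    truth$stacked_frames <- which(stacked)
  }
  if (!is.null(spec$dip)) truth$dip_fraction <- mean(dipped)
  if (n_gm >= 2) {
    d <- as.matrix(stats::dist(pos))
    diag(d) <- Inf
    truth$headgroup_spread <- mean(apply(d, 1, min))
  }

  out <- list(topology = topology, frames = frames, truth = truth)
  if (!is.null(write_to)) {
    dir.create(write_to, recursive = TRUE, showWarnings = FALSE)
    write_system_pdb(topology, subset_frames(frames, 1),
                     file.path(write_to, "system.pdb"))
    write_dcd(frames, file.path(write_to, "traj.dcd"))
    tr <- truth
    tr$zones <- NULL; tr$classes <- NULL; tr$moieties <- NULL
    jsonlite::write_json(tr, file.path(write_to, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
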