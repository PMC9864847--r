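#' Build and validate a pipeline run configuration
#'
#' Either `topology`/`trajectory` file paths or a [synthetic_spec()] must
#' be supplied.  Cutoff defaults follow the analysis conventions: water
#' contacts at 2.5 Angstrom, peptide-raft contacts at 3.0 Angstrom, SASA
#' probe 1.4 Angstrom.
#'
#' @param topology,trajectory input file paths (optional when `spec`
#'   given).
#' @param spec a [synthetic_spec()] to generate the system instead of
#'   reading files.
#' @param out_dir output directory for report files.
#' @param z_reference `"bilayer-center"` or `"absolute"`.
#' @param water_cutoff,contact_cutoff,sasa_probe,sasa_points cutoffs.
#' @param smoothing_window,min_occupancy,persistence segmentation
#'   thresholds (see [segment_stages()]).
#' @param solvation_stride frame stride for the per-zone solvation report.
#' @param residues tracked peptide residues for burial/trails.
#' @param stride_ns frame time step used when reading trajectories.
#' @param seed RNG seed (forwarded to the generator when `spec` is used).
#' @param competition_spec optional second [synthetic_spec()] for the
#'   two-peptide competition stage.
#' @return A validated list of class `raft_config`.
#' @export
raft_config <- function(topology = NULL, trajectory = NULL, spec = NULL,
                        out_dir = tempfile("raftpath-run-"),
                        z_reference = c("absolute", "bilayer-center"),
                        water_cutoff = 2.5, contact_cutoff = 3.0,
                        sasa_probe = 1.4, sasa_points = 960,
                        smoothing_window = 21, min_occupancy = 5,
                        persistence = 10, solvation_stride = 5,
                        residues = c("Y6", "H9", "H10"),
                        stride_ns = 1, seed = 1,
                        competition_spec = NULL) {
  z_reference <- match.arg(z_reference)
  cfg <- list(topology = topology, trajectory = trajectory, spec = spec,
              out_dir = out_dir, z_reference = z_reference,
              water_cutoff = water_cutoff, contact_cutoff = contact_cutoff,
              sasa_probe = sasa_probe, sasa_points = sasa_points,
              smoothing_window = smoothing_window,
              min_occupancy = min_occupancy, persistence = persistence,
              solvation_stride = solvation_stride, residues = residues,
              stride_ns = stride_ns, seed = seed,
              competition_spec = competition_spec)
  if (any(c(water_cutoff, contact_cutoff, sasa_probe) <= 0)) {
    abort("All cutoffs must be positive.", class = "raftpath_config_error")
  }
  if (is.null(spec) && is.null(topology)) {
    abort("Supply either input files or a synthetic spec.",
          class = "raftpath_config_error")
  }
  structure(cfg, class = "raft_config")
}

log_line <- function(con, ...) {
  writeLines(paste0(...), con)
}

#' Run the full raft-binding analysis pipeline
#'
#' Executes, in order: system loading (or synthesis), moiety annotation,
#' bilayer reference and protrusion benchmarks, residue burial and trails,
#' raft zonation, per-zone solvation, contact detection, stage
#' segmentation, late-stage residue SASA and ring stacking, and (when a
#' competition spec is configured) the two-peptide competition metrics.
#' Writes CSV tables, a JSON summary (`summary.json`) and a plain-text
#' run log into `config$out_dir`.  The JSON output contains no
#' timestamps, so identical configurations and seeds yield bit-identical
#' reports.
#'
#' @param config a [raft_config()].
#' @return Invisibly, a list with all intermediate results and
#'   `summary` (the content of `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "raft_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(log_con))
  log_line(log_con, "raftpath ", as.character(utils::packageVersion("raftpath")),
           " | R ", getRversion())
  log_line(log_con, "started: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  cfg_echo <- unclass(config)
  cfg_echo$spec <- if (is.null(config$spec)) NULL else unclass(config$spec)
  cfg_echo$competition_spec <- if (is.null(config$competition_spec)) NULL else
    unclass(config$competition_spec)
  log_line(log_con, "config: ",
           jsonlite::toJSON(cfg_echo, auto_unbox = TRUE, null = "null",
                            digits = NA))

  stage <- "load"
  result <- list()
  summary <- list(seed = config$seed)
  tryCatch({
    if (!is.null(config$spec)) {
      spec <- perturb(config$spec, seed = config$seed)
      sys <- generate_system(spec)
      truth <- sys$truth
    } else {
      sys <- load_system(config$topology, config$trajectory,
                         stride_ns = config$stride_ns)
      truth <- NULL
    }
    topology <- sys$topology
    frames <- sys$frames
    log_line(log_con, sprintf("loaded %d atoms, %d frames", nrow(topology),
                              n_frames(frames)))

    stage <- "moieties"
    moieties <- annotate_moieties(topology)

    stage <- "benchmark"
    ref <- bilayer_center(topology, frames, moieties)
    bench <- protrusion_series(topology, frames, moieties, reference = ref,
                               z_reference = "bilayer-center")
    readr::write_csv(as_tibble(bench),
                     file.path(config$out_dir, "protrusion.csv"))
    summary$bilayer_center_z <- mean(ref$z0)
    summary$protrusion <- setNames(as.list(tidy(bench)$benchmark),
                                   tidy(bench)$moiety)

    stage <- "burial"
    burials <- lapply(config$residues, function(r) {
      com_z_series(topology, frames, r,
                   reference = if (config$z_reference == "bilayer-center")
                     ref else NULL,
                   z_reference = config$z_reference)
    })
    names(burials) <- config$residues
    burial_tab <- purrr::map_dfr(config$residues, function(r) {
      tibble(residue = r, frame = burials[[r]]$frame,
             time = burials[[r]]$time, z = burials[[r]]$z)
    })
    readr::write_csv(burial_tab, file.path(config$out_dir, "burial.csv"))
    summary$burial_avg <- lapply(burials, burial_average)
    trails <- lapply(config$residues, function(r) {
      travel_trail(topology, frames, r)
    })
    names(trails) <- config$residues

    stage <- "zones"
    partition <- partition_raft(topology, frames)
    readr::write_csv(as_tibble(partition),
                     file.path(config$out_dir, "zones.csv"))
    summary$zone_sizes <- as.list(table(partition$zone))

    stage <- "solvation"
    solv <- zone_solvation_report(topology, frames, partition,
                                  moieties = moieties,
                                  water_cutoff = config$water_cutoff,
                                  probe = config$sasa_probe,
                                  points = config$sasa_points,
                                  stride = config$solvation_stride)
    readr::write_csv(solv$series, file.path(config$out_dir, "solvation.csv"))
    summary$zone_solvation <- lapply(seq_len(nrow(solv$summary)),
      function(i) {
        list(zone = solv$summary$zone[i],
             mean_waters = solv$summary$mean_waters[i],
             mean_sasa = solv$summary$mean_sasa[i])
      })
    summary$solvation_ordering <- solv$ordering
    summary$water_ratio_center_vs_far <-
      solv$summary$mean_waters[solv$summary$zone == "center"] /
      solv$summary$mean_waters[solv$summary$zone == "periphery-far"]

    stage <- "contacts"
    pep_ids <- unique(topology$molecule_id[topology$molecule_class == "peptide"])
    pep_rows <- atom_rows(topology, molecule_id = pep_ids[1])
    gm_rows <- atom_rows(topology, molecule_class = "ganglioside")
    contacts <- contact_series(topology, frames, pep_rows, gm_rows,
                               cutoff = config$contact_cutoff,
                               partition = partition)
    readr::write_csv(contacts$counts,
                     file.path(config$out_dir, "contact_counts.csv"))

    stage <- "staging"
    seg <- segment_stages(contacts,
                          smoothing_window = config$smoothing_window,
                          min_occupancy = config$min_occupancy,
                          persistence = config$persistence)
    jsonlite::write_json(
      list(t_attach = seg$t_attach, t_detach = seg$t_detach,
           t_stabilize = seg$t_stabilize,
           thresholds = seg$diagnostics[c("smoothing_window",
                                          "min_occupancy", "persistence")],
           labels = seg$labels),
      file.path(config$out_dir, "stages.json"),
      auto_unbox = TRUE, digits = NA)
    summary$t_attach <- seg$t_attach
    summary$t_detach <- seg$t_detach
    summary$t_stabilize <- seg$t_stabilize

    stage <- "late-stage analysis"
    late <- residue_sasa_series(topology, frames, c("H9", "H10"),
                                segmentation = seg, stage = "late",
                                probe = config$sasa_probe,
                                points = config$sasa_points,
                                stride = config$solvation_stride)
    ls <- attr(late, "summary")
    summary$late_sasa <- setNames(as.list(ls$mean_sasa), ls$residue)
    stk <- ring_stacking(topology, frames, "H9", "H10")
    late_frames <- seg$labels$frame[seg$labels$stage == "late"]
    summary$late_stacked_fraction <- if (length(late_frames)) {
      mean(stk$stacked[late_frames])
    } else NA
    fc <- first_contact_time(topology, frames,
                             cutoff = config$contact_cutoff)
    summary$first_contact_ns <- setNames(as.list(fc$first_contact_ns),
                                         paste0("molecule_", fc$molecule_id))

    if (!is.null(config$competition_spec)) {
      stage <- "competition"
      comp <- run_competition(config, log_con)
      summary$competition <- comp$summary
      result$competition <- comp
    }

    stage <- "report"
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line(log_con, "status: ok")
    result <- c(list(topology = topology, frames = frames,
                     moieties = moieties, reference = ref,
                     benchmark = bench, burials = burials, trails = trails,
                     partition = partition, solvation = solv,
                     contacts = contacts, segmentation = seg,
                     late_sasa = late, stacking = stk,
                     first_contact = fc, truth = truth,
                     summary = summary), result)
  }, error = function(e) {
    log_line(log_con, "status: FAILED at stage '", stage, "': ",
             conditionMessage(e))
    abort(paste0("Pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)), class = "raftpath_pipeline_error",
          parent = e)
  })
  invisible(result)
}

# two-peptide competition metrics on the configured competition spec, plus
# the matched peptide-free system for the headgroup-spread comparison
run_competition <- function(config, log_con) {
  spec_w <- perturb(config$competition_spec, seed = config$seed)
  spec_wo <- synthetic_competition_spec(with_peptides = FALSE,
                                        seed = config$seed + 1)
  sys_w <- generate_system(spec_w)
  sys_wo <- generate_system(spec_wo)
  topology <- sys_w$topology
  frames <- sys_w$frames
  moieties_w <- annotate_moieties(topology)
  moieties_wo <- annotate_moieties(sys_wo$topology)

  fc <- first_contact_time(topology, frames, cutoff = config$contact_cutoff)
  mask_comp <- masking_report(topology, frames,
                              peptide = sys_w$truth$peptide_competitor,
                              residues = c("H13", "H14"),
                              cutoff = config$contact_cutoff)
  mask_main <- masking_report(topology, frames,
                              peptide = sys_w$truth$peptide_main,
                              residues = c("H9", "H10"),
                              cutoff = config$contact_cutoff)
  sp_w <- headgroup_spread(topology, frames, moieties_w)
  sp_wo <- headgroup_spread(sys_wo$topology, sys_wo$frames, moieties_wo)

  main_id <- sys_w$truth$peptide_main
  comp_id <- sys_w$truth$peptide_competitor
  summary <- list(
    first_contact_main_ns =
      fc$first_contact_ns[fc$molecule_id == main_id],
    first_contact_competitor_ns =
      fc$first_contact_ns[fc$molecule_id == comp_id],
    masking_competitor = setNames(as.list(mask_comp$summary$masking_fraction),
                                  mask_comp$summary$residue),
    masking_main = setNames(as.list(mask_main$summary$masking_fraction),
                            mask_main$summary$residue),
    headgroup_spread_with_peptides = attr(sp_w, "average"),
    headgroup_spread_without_peptides = attr(sp_wo, "average")
  )
  log_line(log_con, "competition: first contact main ",
           summary$first_contact_main_ns, " ns, competitor ",
           summary$first_contact_competitor_ns, " ns")
  list(summary = summary, first_contact = fc, masking_competitor = mask_comp,
       masking_main = mask_main, spread_with = sp_w, spread_without = sp_wo,
       truth_with = sys_w$truth, truth_without = sys_wo$truth)
}
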