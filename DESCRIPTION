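Package: raftpath
Title: Trajectory Analysis of Peptide Binding to Ganglioside-Rich Lipid Rafts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise how a peptide engages a ganglioside/cholesterol
    raft in molecular-dynamics trajectories: per-moiety headgroup protrusion
    benchmarks relative to the bilayer centre, residue burial depth and 3D travel
    trails, equal-membership raft zonation with differential solvation (water
    contacts and Shrake-Rupley solvent-accessible surface area), contact-based
    segmentation of the trajectory into attachment, migration and stabilised
    binding stages, ring-stacking analysis, and two-peptide competition metrics
    (first contact, intramolecular masking, headgroup spread).  Includes a
    synthetic-trajectory generator with fully known ground truth so every
    analysis can be validated at desk scale, and a pipeline driver that writes
    tabular and JSON reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    bio3d,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
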