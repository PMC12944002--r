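#!/usr/bin/env Rscript
# Step 1 — simulate the demo study.
#
# Generates the two-condition seated-pressure study the rest of the analysis
# consumes: 18 subjects, each with a calm and an anxious static induction
# session and a calm and an anxious drive over the eight-scenario urban route
# (congestion, lane change, emergency braking, pedestrian crossing,
# consecutive turns, roundabout entry/exit, parking), plus paired SAM
# self-reports. Sessions are written as one directory per session (long-format
# pad CSVs + JSON sidecar) under results/study/.

suppressPackageStartupMessages(library(pressanx))

seed <- 20260919
study_dir <- "results/study"

message("Simulating 18 subjects x 2 conditions x (static + driving), seed ", seed)
study <- run_simulate(study_dir, n_subjects = 18, seed = seed)

kappa <- study$sessions[[3]]$ground_truth$kappa
message("Planted anxiety couplings (ground truth):")
print(round(sort(kappa, decreasing = TRUE), 2))
message("Study written to ", study_dir, " (", length(study$sessions),
        " sessions)")
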