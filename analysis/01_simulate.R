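#!/usr/bin/env Rscript

# Simulate the study cohort: 14 subjects with borderline personality
# disorder, each video-recorded during one social-inclusion and one
# social-exclusion Cyberball session (12 subjects at 30 fps, 2 at 60 fps),
# plus their clinical-scale scores. Writes frame-level CSV logs, a manifest
# and the scores under results/cohort/.

suppressPackageStartupMessages(library(cyberface))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

spec <- default_cohort_spec(seed = seed)
cohort <- generate_cohort(spec)
write_cohort(cohort, "results/cohort")

durs <- vapply(cohort$recordings, recording_duration, numeric(1))
cat(sprintf("Simulated %d recordings (%d subjects x 2 conditions), seed %d\n",
            length(cohort$recordings), spec$n_subjects, seed))
cat(sprintf("Recording durations: %.0f-%.0f s (14 s lead-in included)\n",
            min(durs), max(durs)))
cat(sprintf("NTS means: inclusion %.2f, exclusion %.2f (shift %.2f)\n",
            mean(cohort$scores$nts_inclusion),
            mean(cohort$scores$nts_exclusion),
            mean(cohort$scores$nts_exclusion -
                 cohort$scores$nts_inclusion)))
cat("Cohort written to results/cohort/\n")
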