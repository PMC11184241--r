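#!/usr/bin/env Rscript

# Area-under-the-curve analysis: trapezium AUC per emotion for the full
# recording and per temporal segment, standardized onto a common 30-fps
# frame axis; masked-emotion sums (emotion AUC + happiness AUC) and
# per-subject composition shares. Requires results/cohort/.

suppressPackageStartupMessages(library(cyberface))

recs <- read_cohort_manifest("results/cohort/manifest.csv")
trimmed <- lapply(recs, trim_lead, lead_s = 14)

aucs <- cohort_aucs(trimmed)
masked <- masked_auc(aucs)
shares <- auc_proportions(aucs)

dir.create("results/auc", showWarnings = FALSE, recursive = TRUE)
write.csv(aucs, "results/auc/auc.csv", row.names = FALSE)
write.csv(masked, "results/auc/auc_masked.csv", row.names = FALSE)
write.csv(shares, "results/auc/auc_proportions.csv", row.names = FALSE)

tot <- aucs[aucs$scope == "total", ]
means <- aggregate(auc ~ emotion + condition, tot, mean)
cat("Group mean total AUC per emotion:\n")
print(reshape(means, idvar = "emotion", timevar = "condition",
              direction = "wide"), row.names = FALSE)

mtot <- masked[masked$scope == "total", ]
mm <- aggregate(masked ~ emotion + condition, mtot, mean)
cat("\nGroup mean masked AUC (emotion + happiness):\n")
print(reshape(mm, idvar = "emotion", timevar = "condition",
              direction = "wide"), row.names = FALSE)
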