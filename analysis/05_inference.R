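#!/usr/bin/env Rscript

# Inferential layer: paired t on the need-threat scores, Wilcoxon
# signed-rank comparisons of the AUCs between conditions, two-way
# repeated-measures ANOVA per emotion (with normalizing transforms,
# Benjamini-Hochberg adjustment across the family, and an extreme-outlier
# sensitivity re-run), and Spearman correlations among scales and between
# scales and AUCs. Requires results/cohort/.

suppressPackageStartupMessages(library(cyberface))

recs <- read_cohort_manifest("results/cohort/manifest.csv")
trimmed <- lapply(recs, trim_lead, lead_s = 14)
scores <- read.csv("results/cohort/scores.csv")
scores <- scores[order(scores$subject_id), ]
aucs <- cohort_aucs(trimmed)

dir.create("results/inference", showWarnings = FALSE, recursive = TRUE)

tt <- paired_t(scores$nts_exclusion, scores$nts_inclusion)
cat(sprintf("NTS exclusion vs inclusion: t(%d) = %.2f, p = %.3g\n",
            tt$df, tt$value, tt$p))

tot <- aucs[aucs$scope == "total", ]
wil <- do.call(rbind, lapply(emotion_levels(), function(e) {
  d <- tot[tot$emotion == e, ]
  inc <- d$auc[d$condition == "inclusion"][order(d$subject_id[d$condition ==
                                                                "inclusion"])]
  exc <- d$auc[d$condition == "exclusion"][order(d$subject_id[d$condition ==
                                                                "exclusion"])]
  cbind(emotion = e, wilcoxon_paired(inc, exc))
}))
write.csv(wil, "results/inference/wilcoxon_auc.csv", row.names = FALSE)
cat("\nWilcoxon signed-rank, total AUC inclusion vs exclusion:\n")
print(wil[, c("emotion", "value", "p")], row.names = FALSE)

fam <- rm_anova_by_emotion(aucs)
fam_out <- rm_anova_by_emotion(aucs, include_outliers = FALSE)
write.csv(fam, "results/inference/rm_anova.csv", row.names = FALSE)
write.csv(fam_out, "results/inference/rm_anova_no_outliers.csv",
          row.names = FALSE)
cat("\nRM-ANOVA (condition x segment) per emotion, BH-adjusted:\n")
print(fam[fam$effect == "Condition:Segment",
          c("emotion", "F", "p", "p_adjusted")], row.names = FALSE)
same <- all((fam$p < 0.05) == (fam_out$p < 0.05))
cat(if (same) "Outlier removal does not change any conclusion\n" else
  "Outlier removal changes at least one conclusion (see CSVs)\n")

sc <- scores[, c("scid_ii", "bis15", "best", "ders_e")]
sc$nts <- scores$nts_inclusion
sp <- spearman_matrix(sc)
write.csv(round(sp$rho, 3), "results/inference/scale_spearman_rho.csv")
write.csv(round(sp$p_adjusted, 4),
          "results/inference/scale_spearman_p_adjusted.csv")
cat("\nSpearman correlations among clinical scales:\n")
print(round(sp$rho, 2))
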