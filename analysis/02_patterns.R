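#!/usr/bin/env Rscript

# Second-by-second pattern analysis: per-second dominant emotions, group
# percentage patterns per condition, the 10-interval summary grids, their
# exclusion-minus-inclusion differences, per-interval extremes and the
# comparative-error screen for every emotion x interval cell.
# Requires results/cohort/ from 01_simulate.R.

suppressPackageStartupMessages(library(cyberface))

recs <- read_cohort_manifest("results/cohort/manifest.csv")
trimmed <- lapply(recs, trim_lead, lead_s = 14)
conds <- vapply(trimmed, `[[`, "", "condition")
tl <- analysis_timeline()

patterns <- lapply(c("inclusion", "exclusion"), function(cond) {
  doms <- lapply(trimmed[conds == cond], function(r) {
    dominant_per_second(per_second_means(r))
  })
  group_percentages(doms, tl)
})
names(patterns) <- c("inclusion", "exclusion")
grids <- lapply(names(patterns), function(cond) {
  interval_means(patterns[[cond]], tl, condition = cond)
})
names(grids) <- names(patterns)
dgrid <- condition_difference(grids$exclusion, grids$inclusion)

dir.create("results/patterns", showWarnings = FALSE, recursive = TRUE)
for (cond in names(grids)) {
  write.csv(data.frame(emotion = rownames(grids[[cond]]),
                       unclass(grids[[cond]])),
            sprintf("results/patterns/interval_grid_%s.csv", cond),
            row.names = FALSE)
}
write.csv(data.frame(emotion = rownames(dgrid), unclass(dgrid)),
          "results/patterns/difference_grid.csv", row.names = FALSE)

for (cond in names(grids)) {
  ext <- extremes_per_interval(grids[[cond]])
  cat(sprintf("[%s] most common emotion per interval: %s\n", cond,
              paste(ext$most, collapse = ", ")))
}
grand <- colMeans(unclass(patterns$inclusion), na.rm = TRUE)
cat(sprintf("Grand-mean dominant percentages (inclusion): %s\n",
            paste(sprintf("%s %.1f", names(grand), grand), collapse = ", ")))

# the largest swing between conditions, screened by comparative error at
# the study sample size
n_inc <- sum(conds == "inclusion")
n_exc <- sum(conds == "exclusion")
cells <- expand.grid(emotion = emotion_levels(), interval = 1:10)
cells$p_inc <- mapply(function(e, i) unclass(grids$inclusion)[e, i],
                      as.character(cells$emotion), cells$interval)
cells$p_exc <- mapply(function(e, i) unclass(grids$exclusion)[e, i],
                      as.character(cells$emotion), cells$interval)
cells <- cells[!is.na(cells$p_inc) & !is.na(cells$p_exc), ]
ce <- comparative_error(cells$p_inc, cells$p_exc, n_inc, n_exc)
out <- cbind(cells[, c("emotion", "interval")], ce)
write.csv(out, "results/patterns/comparative_error.csv", row.names = FALSE)
top <- out[which.max(out$diff), ]
cat(sprintf(paste0("Largest condition swing: %s interval %d, %.2f -> %.2f ",
                   "(diff %.2f, comparative error %.2f, %ssignificant)\n"),
            top$emotion, top$interval, top$p1, top$p2, top$diff, top$ce,
            if (top$significant) "" else "not "))
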