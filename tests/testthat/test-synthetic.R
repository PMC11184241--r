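test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(small_spec(seed = 5))
  b <- generate_cohort(small_spec(seed = 5))
  expect_identical(a$recordings, b$recordings)
  expect_identical(a$scores, b$scores)
  c <- generate_cohort(small_spec(seed = 6))
  expect_false(identical(a$recordings[[1]]$intensities,
                         c$recordings[[1]]$intensities))
})

test_that("generated recordings satisfy the recording invariants", {
  co <- generate_cohort(small_spec(seed = 9))
  expect_length(co$recordings, 8)
  for (rec in co$recordings) {
    expect_true(all(rec$intensities >= 0 & rec$intensities <= 1))
    expect_true(all(rec$neutral >= 0 & rec$neutral <= 1))
    expect_true(all(diff(rec$time) > 0))
  }
  # every subject has exactly one recording per condition
  key <- table(vapply(co$recordings, `[[`, "", "subject_id"),
               vapply(co$recordings, `[[`, "", "condition"))
  expect_true(all(key == 1))
})

test_that("zero noise and no effects give constant logistic(baseline)", {
  sp <- small_spec(seed = 2, noise_sd = 0, subject_sd = 0)
  co <- generate_cohort(sp)
  s <- per_second_means(trim_lead(co$recordings[[1]]))
  for (e in emotions) {
    expect_true(all(abs(unclass(s)[, e] - plogis(sp$baseline[[e]])) < 1e-12))
  }
})

test_that("injected effects shift the latent mean where specified", {
  ef <- list(effect_spec("anger", "exclusion", 3, "constant", 3))
  sp <- small_spec(seed = 3, duration_s = c(135, 140), noise_sd = 0,
                   subject_sd = 0, effects = ef)
  co <- generate_cohort(sp)
  conds <- vapply(co$recordings, `[[`, "", "condition")
  s <- per_second_means(trim_lead(co$recordings[[which(conds ==
                                                         "exclusion")[1]]]))
  anger <- unclass(s)[, "anger"]
  expect_equal(anger[50], plogis(sp$baseline[["anger"]]))
  expect_equal(anger[110], plogis(sp$baseline[["anger"]] + 3))
  # inclusion untouched
  si <- per_second_means(trim_lead(co$recordings[[which(conds ==
                                                          "inclusion")[1]]]))
  expect_equal(unclass(si)[110, "anger"], plogis(sp$baseline[["anger"]]),
               ignore_attr = TRUE)
})

test_that("ramp effects rise linearly over their covered span", {
  ef <- list(effect_spec("happiness", "inclusion", 2:3, "ramp", 2))
  sp <- small_spec(seed = 4, duration_s = c(159, 159), noise_sd = 0,
                   subject_sd = 0, effects = ef)
  co <- generate_cohort(sp)
  conds <- vapply(co$recordings, `[[`, "", "condition")
  s <- per_second_means(trim_lead(co$recordings[[which(conds ==
                                                         "inclusion")[1]]]))
  hap <- qlogis(unclass(s)[, "happiness"]) - sp$baseline[["happiness"]]
  expect_equal(hap[30], 0)
  span <- 60:145
  expect_equal(hap[span], 2 * (span - 60 + 1) / length(span),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("clinical scores hit their marginal targets and stay in range", {
  sp <- default_cohort_spec(seed = 13)
  sc <- generate_clinical_scores(sp, n = 400)
  expect_equal(mean(sc$scid_ii), 12.36, tolerance = 0.1)
  expect_equal(sd(sc$scid_ii), 2, tolerance = 0.15)
  # censoring to the scale range pulls the BIS-15 moments in slightly
  expect_lt(abs(mean(sc$bis15) - 49.79), 3)
  expect_gt(sd(sc$bis15), 9)
  expect_true(all(sc$nts_inclusion >= 14 & sc$nts_inclusion <= 140))
  expect_true(all(sc$nts_exclusion >= 14 & sc$nts_exclusion <= 140))
  expect_true(all(sc$best_c >= 3 & sc$best_c <= 15))
  # exclusion NTS exceeds inclusion on average
  expect_gt(mean(sc$nts_exclusion - sc$nts_inclusion), 20)
  # cross-condition NTS association is strong and positive
  expect_gt(cor(sc$nts_inclusion, sc$nts_exclusion, method = "spearman"),
            0.4)
})

test_that("an infeasible correlation matrix is rejected", {
  bad <- default_scale_correlations()
  bad[1, 2] <- bad[2, 1] <- 0.99
  bad[1, 3] <- bad[3, 1] <- 0.99
  bad[2, 3] <- bad[3, 2] <- -0.99
  sp <- small_spec(seed = 1, scale_correlations = bad)
  expect_error(generate_clinical_scores(sp, n = 10), "positive semidefinite")
})

test_that("difference grids recover injected effect directions", {
  # late-exclusion happiness rise: exclusion-minus-inclusion means over
  # replicates must be positive in segment 3 and near zero in segment 1
  sp <- cohort_spec(
    n_subjects = 6, fps_assignment = rep(30L, 6),
    duration_s = c(159, 159), noise_sd = 0.8,
    effects = list(effect_spec("happiness", "exclusion", 3, "constant", 1.5))
  )
  tl <- analysis_timeline()
  diffs <- vapply(1:50, function(r) {
    co <- generate_cohort(sp, seed = 1000 + r)
    conds <- vapply(co$recordings, `[[`, "", "condition")
    pats <- lapply(c("inclusion", "exclusion"), function(cc) {
      doms <- lapply(co$recordings[conds == cc], function(rec) {
        dominant_per_second(per_second_means(trim_lead(rec)))
      })
      group_percentages(doms, tl)
    })
    d <- condition_difference(interval_means(pats[[2]], tl),
                              interval_means(pats[[1]], tl))
    c(seg3 = mean(unclass(d)["happiness", 8:10]),
      seg1 = mean(unclass(d)["happiness", 1:4]))
  }, numeric(2))
  expect_gt(mean(diffs["seg3", ]), 10)
  expect_lt(abs(mean(diffs["seg1", ])), 10)
  expect_gt(mean(diffs["seg3", ]), abs(mean(diffs["seg1", ])) + 5)
})

test_that("written cohorts round-trip through the manifest reader", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(small_spec(seed = 14))
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "scores.csv")))
  recs <- read_cohort_manifest(file.path(dir, "manifest.csv"),
                               duration_window = NULL)
  orig <- co$recordings[[3]]
  match_idx <- which(vapply(recs, `[[`, "", "subject_id") ==
                       orig$subject_id &
                     vapply(recs, `[[`, "", "condition") == orig$condition)
  expect_equal(recs[[match_idx]]$intensities, orig$intensities,
               tolerance = 1e-12)
})
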