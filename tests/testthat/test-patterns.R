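test_that("per-second means average the frames of each second", {
  rec <- make_recording(list(happiness = 0.4), fps = 30, duration = 5)
  s <- per_second_means(rec)
  expect_equal(nrow(s), 5)
  expect_true(all(abs(unclass(s)[, "happiness"] - 0.4) < 1e-12))

  # block means over a 2-second stream
  rec2 <- make_recording(list(happiness = rep(c(0, 1), each = 30)),
                         fps = 30, duration = 2)
  expect_equal(unname(unclass(per_second_means(rec2))[, "happiness"]),
               c(0, 1))

  # 60 fps second with half the frames at 0.2 and half at 0.6
  rec3 <- make_recording(list(sadness = rep(c(0.2, 0.6), each = 30)),
                         fps = 60, duration = 1)
  expect_equal(unname(unclass(per_second_means(rec3))[, "sadness"]), 0.4)

  # trailing partial second dropped
  rec4 <- make_recording(list(), fps = 30, duration = 3)
  rec4$time <- rec4$time[1:75]
  rec4$intensities <- rec4$intensities[1:75, ]
  expect_equal(nrow(per_second_means(rec4)), 2)
})

test_that("dominant emotion is the per-second argmax with canonical ties", {
  m <- matrix(0.1, 2, 7, dimnames = list(NULL, emotions))
  m[1, "sadness"] <- 0.3
  m[2, c("happiness", "anger")] <- 0.2
  d <- dominant_per_second(m)
  expect_equal(as.character(d), c("sadness", "happiness"))

  # brute-force pairwise-comparison oracle on random vectors
  withr::with_seed(99, {
    M <- matrix(runif(1000 * 7), ncol = 7, dimnames = list(NULL, emotions))
    d <- dominant_per_second(M)
    oracle <- apply(M, 1, function(r) {
      best <- 1
      for (j in 2:7) if (r[j] > r[best]) best <- j
      emotions[best]
    })
    expect_equal(as.character(d), oracle)
  })

  # all-zero seconds resolve to the first canonical label and are counted
  z <- matrix(0, 3, 7, dimnames = list(NULL, emotions))
  dz <- dominant_per_second(z)
  expect_true(all(dz == "happiness"))
  expect_equal(attr(dz, "n_allzero"), 3)
})

test_that("group percentages use on-record denominators", {
  doms <- c(rep(list(factor(rep("sadness", 10), levels = emotions)), 7),
            rep(list(factor(rep("anger", 10), levels = emotions)), 7))
  gp <- group_percentages(doms, analysis_timeline(10))
  expect_equal(unname(unclass(gp)[5, "sadness"]), 50)
  expect_equal(unname(rowSums(unclass(gp))), rep(100, 10))

  # one subject: every second is 100 for exactly one emotion
  gp1 <- group_percentages(list(factor(rep("fear", 4), levels = emotions)))
  expect_true(all(unclass(gp1)[, "fear"] == 100))
  expect_equal(unname(rowSums(unclass(gp1))), rep(100, 4))

  # a subject whose recording ends early leaves the denominator
  doms2 <- list(factor(rep("sadness", 10), levels = emotions),
                factor(rep("anger", 5), levels = emotions))
  gp2 <- group_percentages(doms2)
  expect_equal(unname(unclass(gp2)[1, "sadness"]), 50)
  expect_equal(unname(unclass(gp2)[10, "sadness"]), 100)
  expect_equal(attr(gp2, "n_subjects"), c(rep(2L, 5), rep(1L, 5)))
})

test_that("group percentages approach uniformity for random labels", {
  withr::with_seed(5, {
    doms <- lapply(1:10000, function(i) {
      factor(sample(emotions, 3, replace = TRUE), levels = emotions)
    })
    gp <- group_percentages(doms)
    expect_true(all(abs(unclass(gp) - 100 / 7) < 1))
  })
})

test_that("interval means reproduce constant patterns and sum to 100", {
  m <- matrix(0, 145, 7, dimnames = list(NULL, emotions))
  m[, "sadness"] <- 100
  pat <- structure(m, class = "group_pattern")
  grid <- interval_means(pat)
  expect_equal(unname(unclass(grid)["sadness", ]), rep(100, 10))
  expect_equal(unname(colSums(unclass(grid))), rep(100, 10))

  # computed grids on random complete data have exact 100 column sums
  gp <- withr::with_seed(8, random_pattern(145))
  expect_equal(unname(colSums(unclass(interval_means(gp)))), rep(100, 10),
               tolerance = 1e-9)

  # idempotence: a pattern already constant at the published interval values
  ref <- reference_interval_grids()$inclusion
  tl <- analysis_timeline()
  m2 <- matrix(NA_real_, 145, 7, dimnames = list(NULL, emotions))
  for (i in 1:10) {
    secs <- tl$intervals$start[i]:tl$intervals$end[i]
    m2[secs, ] <- matrix(unclass(ref)[, i], length(secs), 7, byrow = TRUE)
  }
  grid2 <- interval_means(structure(m2, class = "group_pattern"))
  expect_equal(unclass(grid2), unclass(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("interval means tolerate short recordings", {
  gp <- withr::with_seed(2, random_pattern(120))  # pattern ends at 120 s
  grid <- interval_means(gp)
  expect_true(all(is.na(unclass(grid)[, 10])))     # 136-145 uncovered
  expect_false(anyNA(unclass(grid)[, 1:8]))
})

test_that("condition differences subtract inclusion from exclusion", {
  ref <- reference_interval_grids()
  d <- condition_difference(ref$exclusion, ref$inclusion)
  expect_equal(unclass(d)["anger", "interval9"], 6.70 - 30.77)
  expect_equal(unclass(d)["contempt", "interval10"], 2.25 - 18.39)
  zero <- condition_difference(ref$inclusion, ref$inclusion)
  expect_true(all(unclass(zero) == 0))
  expect_error(condition_difference(unclass(ref$exclusion)[, 1:5],
                                    ref$inclusion), "mismatch")
  # computed difference grids have zero column sums
  a <- withr::with_seed(3, random_pattern(145))
  b <- withr::with_seed(4, random_pattern(145))
  dd <- condition_difference(interval_means(a), interval_means(b))
  expect_equal(unname(colSums(unclass(dd))), rep(0, 10), tolerance = 1e-9)
})

test_that("per-interval extremes match the published cohort", {
  ref <- reference_interval_grids()
  ext_inc <- extremes_per_interval(ref$inclusion)
  expect_equal(ext_inc$most[1], "sadness")
  ext_exc <- extremes_per_interval(ref$exclusion)
  expect_equal(ext_exc$most[5], "contempt")
  one <- matrix(0, 7, 1, dimnames = list(emotions, "interval1"))
  one["anger", 1] <- 100
  ext <- extremes_per_interval(structure(one, class = "interval_grid"))
  expect_equal(ext$most, "anger")
  expect_equal(ext$least, "happiness")  # first zero in canonical order
})

test_that("comparative error is symmetric and shrinks with n", {
  ce <- comparative_error(50, 50, 14, 14)
  expect_false(ce$significant)
  expect_equal(ce$diff, 0)
  a <- comparative_error(20, 60, 10, 30)
  b <- comparative_error(60, 20, 30, 10)
  expect_equal(a$ce, b$ce)
  ns <- c(5, 10, 20, 40, 80)
  ces <- comparative_error(rep(20, 5), rep(60, 5), ns, ns)$ce
  expect_true(all(diff(ces) < 0))
  expect_error(comparative_error(120, 10, 14, 14))
})
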