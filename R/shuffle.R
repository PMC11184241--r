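#' Second-by-second shuffled (white-noise) pattern
#'
#' Builds the white-noise null for a group dominant-emotion pattern: for
#' every second independently, the seven percentage values are rearranged by
#' a fresh uniform-random permutation of the emotion labels. Each second's
#' multiset of values (and hence its 100% sum) is conserved, while temporal
#' and identity structure is destroyed.
#'
#' @param pattern A complete `group_pattern` (no missing seconds).
#' @param seed Integer seed for the permutations.
#' @return List of class `shuffled_pattern` with elements `source`,
#'   `shuffled` (both `group_pattern`), `permutations` (seconds x 7 matrix of
#'   label indices) and `seed`.
#' @export
shuffle_pattern <- function(pattern, seed) {
  m <- unclass(pattern)
  if (anyNA(m)) {
    stop("pattern has missing seconds; restrict the timeline to covered ",
         "seconds before shuffling")
  }
  n <- nrow(m)
  withr::with_seed(seed, {
    perms <- t(vapply(seq_len(n), function(i) sample.int(7L), integer(7)))
  })
  shuf <- m
  for (i in seq_len(n)) shuf[i, ] <- m[i, perms[i, ]]
  structure(
    list(source = pattern,
         shuffled = structure(shuf, class = "group_pattern",
                              n_subjects = attr(pattern, "n_subjects")),
         permutations = perms, seed = seed),
    class = "shuffled_pattern"
  )
}

#' Compare a pattern with its shuffled null
#'
#' Per emotion, a two-sample t test across seconds between the source
#' percentage series and the shuffled series. The default is Student's
#' pooled-variance independent-samples test; Welch and paired variants are
#' available. Degenerate input (both series constant) is reported as t = 0,
#' p = 1 with a flag.
#'
#' @param source,shuffled `group_pattern` objects of equal length (typically
#'   the `source` and `shuffled` elements of [shuffle_pattern()]).
#' @param variant `"student"` (pooled variance, default), `"welch"` or
#'   `"paired"`.
#' @return Data frame per emotion: t, p, n_seconds, degenerate.
#' @export
compare_to_null <- function(source, shuffled,
                            variant = c("student", "welch", "paired")) {
  variant <- match.arg(variant)
  a <- unclass(source)
  b <- unclass(shuffled)
  if (nrow(a) != nrow(b)) stop("pattern lengths differ")
  res <- lapply(EMOTIONS, function(e) {
    x <- a[, e]
    y <- b[, e]
    if (sd(x) == 0 && sd(y) == 0) {
      return(data.frame(emotion = e, t = 0, p = 1, n_seconds = length(x),
                        degenerate = TRUE))
    }
    tt <- switch(variant,
      student = t.test(x, y, var.equal = TRUE),
      welch   = t.test(x, y),
      paired  = t.test(x, y, paired = TRUE)
    )
    data.frame(emotion = e, t = unname(tt$statistic), p = tt$p.value,
               n_seconds = length(x), degenerate = FALSE)
  })
  do.call(rbind, res)
}

#' Shuffle-null test with one or several realizations
#'
#' Runs [shuffle_pattern()] + [compare_to_null()] `k` times (child seeds are
#' derived from `seed`) and summarizes across realizations. `k = 1` mirrors
#' the single-realization protocol; larger `k` stabilizes the statistics.
#'
#' @param pattern A complete `group_pattern`.
#' @param seed Integer master seed.
#' @param k Number of shuffle realizations (default 1).
#' @param variant Passed to [compare_to_null()].
#' @return Data frame per emotion: mean t over realizations, median p,
#'   n_seconds, k, seed.
#' @export
shuffle_null_test <- function(pattern, seed, k = 1,
                              variant = c("student", "welch", "paired")) {
  variant <- match.arg(variant)
  reps <- lapply(seq_len(k), function(j) {
    sh <- shuffle_pattern(pattern, seed = child_seed(seed, j))
    compare_to_null(sh$source, sh$shuffled, variant = variant)
  })
  tmat <- sapply(reps, function(r) r$t)
  pmat <- sapply(reps, function(r) r$p)
  if (k == 1) {
    tmat <- matrix(tmat, ncol = 1)
    pmat <- matrix(pmat, ncol = 1)
  }
  data.frame(emotion = EMOTIONS, t = rowMeans(tmat),
             p = apply(pmat, 1, median),
             n_seconds = reps[[1]]$n_seconds, k = k, seed = seed)
}

# Deterministic fan-out of a master seed into stage/replicate child seeds,
# kept within the 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647)
}
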