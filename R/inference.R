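#' Paired Student's t test
#'
#' @param x,y Per-subject paired values (equal length >= 2).
#' @return Data frame: statistic = "t", value, df, p.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 2) stop("need at least 2 pairs")
  if (sd(x - y) == 0) stop("degenerate input: all paired differences equal")
  tt <- t.test(x, y, paired = TRUE)
  data.frame(statistic = "t", value = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value)
}

#' Wilcoxon signed-rank test with normal-approximation Z
#'
#' Paired signed-rank test reported as a Z statistic (normal approximation
#' with tie correction, no continuity correction), the convention of the
#' major statistics suites. Zero differences are dropped before ranking; tied
#' absolute differences receive mid-ranks. If all differences are zero the
#' result is flagged degenerate with Z = 0, p = 1.
#'
#' @param x,y Paired values.
#' @return Data frame: statistic = "Z", value (signed Z, positive when x
#'   tends to exceed y), n (non-zero pairs), p, degenerate.
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(data.frame(statistic = "Z", value = 0, n = 0, p = 1,
                      degenerate = TRUE))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    return(data.frame(statistic = "Z", value = 0, n = n, p = 1,
                      degenerate = TRUE))
  }
  z <- (w_plus - mu) / sqrt(sigma2)
  data.frame(statistic = "Z", value = z, n = n,
             p = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Default normalizing-transform assignment
#'
#' The per-emotion transforms applied to AUCs before repeated-measures
#' ANOVA: hyperbolic arcsine for anger, happiness, sadness and surprise;
#' ordered-quantile rank normalization for fear; Yeo-Johnson for disgust;
#' contempt untransformed.
#'
#' @return Named character vector emotion -> transform name.
#' @export
default_transform_spec <- function() {
  c(happiness = "arcsinh", sadness = "arcsinh", anger = "arcsinh",
    surprise = "arcsinh", fear = "orderquant", disgust = "yeojohnson",
    contempt = "none")
}

#' Apply a normalizing transform
#'
#' `arcsinh` is `asinh(x)`; `orderquant` maps ranks to normal quantiles,
#' `qnorm((rank - 0.5) / n)` with mid-ranks for ties; `yeojohnson` estimates
#' the Yeo-Johnson power parameter by maximum likelihood (via
#' `car::powerTransform`) on the vector itself and applies it. Transforms
#' are fitted on the analysed vector, mirroring a normalize-then-test
#' workflow.
#'
#' @param x Numeric vector.
#' @param method One of "none", "arcsinh", "orderquant", "yeojohnson".
#' @return Transformed vector.
#' @export
apply_transform <- function(x, method = c("none", "arcsinh", "orderquant",
                                          "yeojohnson")) {
  method <- match.arg(method)
  switch(method,
    none = x,
    arcsinh = asinh(x),
    orderquant = qnorm((rank(x, ties.method = "average") - 0.5) / length(x)),
    yeojohnson = {
      lambda <- car::powerTransform(x ~ 1, family = "yjPower")$lambda
      as.numeric(car::yjPower(x, lambda))
    }
  )
}

#' Extreme outliers by the 3 x IQR rule
#'
#' Flags values above Q3 + 3 IQR or below Q1 - 3 IQR, with quartiles by
#' linear interpolation (type 7). The multiplier 3 targets extreme outliers;
#' the conventional 1.5 is available through `multiplier`.
#'
#' @param x Numeric vector (>= 4 values).
#' @param multiplier IQR multiplier (default 3).
#' @return Data frame of flagged points: index, value, bound ("upper" or
#'   "lower"), plus attributes `q1`, `q3`, `iqr`.
#' @export
extreme_outliers <- function(x, multiplier = 3) {
  if (length(x) < 4) stop("need at least 4 values")
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  hi <- which(x > q[2] + multiplier * iqr)
  lo <- which(x < q[1] - multiplier * iqr)
  out <- data.frame(
    index = c(lo, hi), value = x[c(lo, hi)],
    bound = rep(c("lower", "upper"), c(length(lo), length(hi)))
  )
  attr(out, "q1") <- q[1]
  attr(out, "q3") <- q[2]
  attr(out, "iqr") <- iqr
  out
}

#' Multiple-testing correction
#'
#' Thin wrapper over [stats::p.adjust()]: Benjamini-Hochberg step-up (FDR)
#' or Bonferroni.
#'
#' @param pvals Vector of p-values in \[0, 1\].
#' @param method "benjamini-hochberg" (default) or "bonferroni".
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(pvals, method = c("benjamini-hochberg",
                                             "bonferroni")) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0,1]")
  }
  method <- match.arg(method)
  p.adjust(pvals, method = c(`benjamini-hochberg` = "BH",
                             bonferroni = "bonferroni")[method])
}

# Greenhouse-Geisser epsilon for a within-subject effect. Y is the
# subject x cell matrix of that effect's condition means; C an orthonormal
# contrast basis (cells x df).
gg_epsilon <- function(Y, C) {
  S <- cov(Y)
  M <- t(C) %*% S %*% C
  k <- ncol(C)
  (sum(diag(M)))^2 / (k * sum(M * M))
}

#' Two-way repeated-measures ANOVA (condition x segment)
#'
#' Univariate within-subject ANOVA for a complete balanced subject x
#' condition x segment table, the design used to test whether an emotion's
#' segment AUCs differ between inclusion and exclusion. Reports F, degrees
#' of freedom, uncorrected p, partial eta-squared, and the
#' Greenhouse-Geisser-corrected p for each of the three within effects.
#' Normality of each cell is screened by Shapiro-Wilk (reported, not
#' enforced).
#'
#' @param data Data frame with columns `subject`, `condition`, `segment`,
#'   `value`; every subject must have one value per condition x segment cell.
#' @param transform A transform name (see [apply_transform()]) applied to
#'   `value` before fitting, default "none".
#' @return Data frame per effect (Condition, Segment, Condition:Segment):
#'   DFn, DFd, F, p, pes (partial eta-squared), gg_eps, p_gg. Attribute
#'   `shapiro` holds the per-cell Shapiro-Wilk p-values.
#' @export
rm_anova_2way <- function(data, transform = "none") {
  req <- c("subject", "condition", "segment", "value")
  if (!all(req %in% names(data))) {
    stop("data must have columns subject, condition, segment, value")
  }
  data$subject <- factor(data$subject)
  data$condition <- factor(data$condition)
  data$segment <- factor(data$segment)
  tab <- table(data$subject, data$condition, data$segment)
  if (any(tab != 1)) stop("unbalanced or incomplete table: one value per ",
                          "subject x condition x segment cell required")
  data$value <- apply_transform(data$value, transform)

  shap <- aggregate(value ~ condition + segment, data, function(v) {
    if (length(unique(v)) < 3) NA_real_ else shapiro.test(v)$p.value
  })

  fit <- aov(value ~ condition * segment +
               Error(subject / (condition * segment)), data = data)
  sm <- summary(fit)
  pick <- function(stratum, term) {
    tabs <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(tabs)))
    err <- grep("Residuals", rownames(tabs))
    c(DFn = tabs$Df[i], DFd = tabs$Df[err], F = tabs$`F value`[i],
      p = tabs$`Pr(>F)`[i],
      pes = tabs$`Sum Sq`[i] / (tabs$`Sum Sq`[i] + tabs$`Sum Sq`[err]))
  }
  eff <- rbind(
    Condition = pick("Error: subject:condition", "condition"),
    Segment = pick("Error: subject:segment", "segment"),
    `Condition:Segment` = pick("Error: subject:condition:segment",
                               "condition:segment")
  )

  # GG epsilon from subject-level cell means per effect
  cell <- tapply(data$value, list(data$subject, data$condition, data$segment),
                 identity)
  nseg <- dim(cell)[3]
  ncond <- dim(cell)[2]
  Yseg <- apply(cell, c(1, 3), mean)            # subject x segment
  Yint <- matrix(aperm(cell, c(1, 3, 2)), nrow = dim(cell)[1])
  contr_seg <- contr.helmert(nseg)
  contr_seg <- qr.Q(qr(contr_seg))
  contr_cond <- qr.Q(qr(contr.helmert(ncond)))
  C_int <- kronecker(contr_cond, contr_seg)     # cells ordered seg-in-cond
  eps <- c(Condition = 1,
           Segment = gg_epsilon(Yseg, contr_seg),
           `Condition:Segment` = gg_epsilon(Yint, C_int))
  out <- as.data.frame(eff)
  out$effect <- rownames(eff)
  out$gg_eps <- eps[out$effect]
  out$p_gg <- pf(out$F, out$DFn * out$gg_eps, out$DFd * out$gg_eps,
                 lower.tail = FALSE)
  rownames(out) <- NULL
  out <- out[, c("effect", "DFn", "DFd", "F", "p", "pes", "gg_eps", "p_gg")]
  attr(out, "shapiro") <- shap
  out
}

#' Repeated-measures ANOVA family over the seven emotions
#'
#' Runs [rm_anova_2way()] per emotion on a long AUC table, applying each
#' emotion's normalizing transform, and Benjamini-Hochberg-adjusts the
#' p-values across the whole family of effects. Optionally re-runs with
#' extreme outliers (3 x IQR within each emotion) removed via subject
#' exclusion; both variants are returned so their conclusions can be
#' compared.
#'
#' @param records Long AUC table with columns subject_id, condition, scope
#'   ("segment1".."segment3" rows are used), emotion, auc.
#' @param transforms Named vector emotion -> transform (default
#'   [default_transform_spec()]).
#' @param include_outliers Keep extreme outliers (default TRUE, the primary
#'   analysis). When FALSE, subjects contributing an extreme outlier for an
#'   emotion are dropped from that emotion's ANOVA.
#' @return Data frame: emotion, effect, DFn, DFd, F, p, pes, gg_eps, p_gg,
#'   p_adjusted (BH across all rows), n_subjects.
#' @export
rm_anova_by_emotion <- function(records,
                                transforms = default_transform_spec(),
                                include_outliers = TRUE) {
  seg <- records[grepl("^segment", records$scope), ]
  out <- lapply(EMOTIONS, function(e) {
    d <- seg[seg$emotion == e, ]
    d <- data.frame(subject = d$subject_id, condition = d$condition,
                    segment = d$scope, value = d$auc)
    if (!include_outliers) {
      fl <- extreme_outliers(d$value)
      drop_subj <- unique(d$subject[fl$index])
      # keep at least 2 subjects so the within-subject strata stay estimable
      if (length(unique(d$subject)) - length(drop_subj) >= 2) {
        d <- d[!d$subject %in% drop_subj, ]
      }
    }
    res <- rm_anova_2way(d, transform = unname(transforms[e]))
    res$emotion <- e
    res$n_subjects <- length(unique(d$subject))
    res
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- adjust_pvalues(out$p, "benjamini-hochberg")
  out[, c("emotion", "effect", "DFn", "DFd", "F", "p", "pes", "gg_eps",
          "p_gg", "p_adjusted", "n_subjects")]
}

#' Spearman correlation matrix with corrected p-values
#'
#' Pairwise Spearman correlations between the columns of `left` and `right`
#' (aligned by row/subject), with two-sided p-values and a multiplicity
#' correction over all reported pairs. Constant columns yield NA with a
#' warning.
#'
#' @param left Data frame / matrix of scores (subjects x variables).
#' @param right Optional second table; default `left` (then only the upper
#'   triangle enters the correction family).
#' @param correction "bonferroni" (default) or "benjamini-hochberg".
#' @return List with matrices `rho`, `p`, `p_adjusted`.
#' @export
spearman_matrix <- function(left, right = NULL,
                            correction = c("bonferroni",
                                           "benjamini-hochberg")) {
  correction <- match.arg(correction)
  symmetric <- is.null(right)
  if (symmetric) right <- left
  left <- as.data.frame(left)
  right <- as.data.frame(right)
  if (nrow(left) != nrow(right)) stop("tables must align by subject")
  if (nrow(left) < 4) stop("need n >= 4 subjects")
  rho <- p <- matrix(NA_real_, ncol(left), ncol(right),
                     dimnames = list(names(left), names(right)))
  for (i in seq_len(ncol(left))) {
    for (j in seq_len(ncol(right))) {
      x <- left[[i]]
      y <- right[[j]]
      if (sd(x) == 0 || sd(y) == 0) {
        warning("constant column: rho undefined for ",
                names(left)[i], " vs ", names(right)[j])
        next
      }
      ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                      exact = FALSE))
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  family <- if (symmetric) upper.tri(p) else !is.na(p) | is.na(p)
  p_adj <- p
  idx <- which(if (symmetric) upper.tri(p) else matrix(TRUE, nrow(p), ncol(p)))
  p_adj[idx] <- adjust_pvalues(pmin(p[idx], 1), correction)
  if (symmetric) {
    p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
    diag(p_adj) <- NA_real_
  }
  list(rho = rho, p = p, p_adjusted = p_adj)
}
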