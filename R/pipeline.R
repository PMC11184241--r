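#' Pipeline run configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"manifest"`
#'   (ingest recordings listed in a manifest CSV).
#' @param spec A [cohort_spec()] (simulate mode).
#' @param manifest Manifest path (manifest mode).
#' @param scores Optional clinical-scores data frame or CSV path (manifest
#'   mode).
#' @param out_dir Output directory.
#' @param seed Master seed; fanned out to named child seeds per stochastic
#'   stage so stages can be re-run in isolation.
#' @param lead_s Lead-in seconds discarded from each recording.
#' @param calibrate Apply [apply_continuous_calibration()] before analysis
#'   (default FALSE: FaceReader exports are already calibrated).
#' @param shuffle_k Shuffle realizations per condition (default 1).
#' @param transforms Named emotion -> transform vector for the ANOVAs.
#' @param timeline An [analysis_timeline()].
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "manifest"),
                       spec = default_cohort_spec(),
                       manifest = NULL, scores = NULL,
                       out_dir = "results", seed = 1L, lead_s = 14,
                       calibrate = FALSE, shuffle_k = 1,
                       transforms = default_transform_spec(),
                       timeline = analysis_timeline()) {
  mode <- match.arg(mode)
  if (mode == "manifest" && is.null(manifest)) {
    stop("manifest mode requires a manifest path")
  }
  structure(list(mode = mode, spec = spec, manifest = manifest,
                 scores = scores, out_dir = out_dir, seed = as.integer(seed),
                 lead_s = lead_s, calibrate = calibrate,
                 shuffle_k = shuffle_k, transforms = transforms,
                 timeline = timeline),
            class = "run_config")
}

# Hash of the serialized config, stamped into every emitted table.
config_hash <- function(config) {
  # out_dir does not affect the analysis; timeline is not JSON-serializable
  strip <- config[setdiff(names(config), c("timeline", "out_dir"))]
  json <- jsonlite::toJSON(strip, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

grid_to_df <- function(grid) {
  data.frame(emotion = rownames(grid), as.data.frame(unclass(grid)),
             row.names = NULL)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage over one cohort: ingest or simulate, optional
#' continuous calibration, lead-in trim, per-second aggregation and dominant
#' emotions, group percentage patterns per condition, 10-interval grids and
#' their exclusion-minus-inclusion differences, per-cell comparative errors,
#' the shuffled white-noise comparison, trapezium AUCs with masking and
#' composition shares, and the inferential layer (paired t on NTS, Wilcoxon
#' per emotion, the RM-ANOVA family with and without extreme outliers,
#' Spearman matrices). All tables are written as CSV (stamped with a config
#' hash); test results land in `inference.json` together with seeds and
#' settings. The output tree is a pure function of inputs, config and
#' master seed.
#'
#' @param config A [run_config()].
#' @return List of class `run_report` with the in-memory results and
#'   `paths` of everything written.
#' @export
run_pipeline <- function(config) {
  tl <- config$timeline
  hash <- config_hash(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_stamped_csv(df, p, hash)
    paths[[name]] <<- p
    p
  }

  # --- ingest -------------------------------------------------------------
  scores <- NULL
  if (config$mode == "simulate") {
    cohort <- generate_cohort(config$spec, seed = child_seed(config$seed, 1))
    recordings <- cohort$recordings
    scores <- cohort$scores
  } else {
    recordings <- read_cohort_manifest(config$manifest)
    if (is.character(config$scores)) {
      scores <- read.csv(config$scores, stringsAsFactors = FALSE)
    } else {
      scores <- config$scores
    }
  }
  if (config$calibrate) {
    recordings <- lapply(recordings, apply_continuous_calibration)
  }
  trimmed <- lapply(recordings, trim_lead, lead_s = config$lead_s)

  # --- patterns -----------------------------------------------------------
  conds <- vapply(trimmed, `[[`, "", "condition")
  series <- lapply(trimmed, per_second_means)
  patterns <- lapply(c("inclusion", "exclusion"), function(cond) {
    doms <- lapply(series[conds == cond], dominant_per_second)
    group_percentages(doms, tl)
  })
  names(patterns) <- c("inclusion", "exclusion")
  long <- do.call(rbind, lapply(names(patterns), function(cond) {
    m <- unclass(patterns[[cond]])
    data.frame(condition = cond, second = rep(seq_len(nrow(m)), 7),
               emotion = rep(EMOTIONS, each = nrow(m)),
               percentage = as.vector(m),
               n_subjects = rep(attr(patterns[[cond]], "n_subjects"), 7))
  }))
  emit(long, "pattern_per_second.csv")

  grids <- lapply(names(patterns), function(cond) {
    interval_means(patterns[[cond]], tl, condition = cond)
  })
  names(grids) <- names(patterns)
  emit(cbind(condition = rep(names(grids), each = 7),
             do.call(rbind, lapply(grids, grid_to_df))),
       "interval_grid.csv")
  dgrid <- condition_difference(grids$exclusion, grids$inclusion)
  emit(grid_to_df(dgrid), "difference_grid.csv")

  n_by_cond <- table(conds)
  ce <- do.call(rbind, lapply(1:10, function(i) {
    p_inc <- unclass(grids$inclusion)[, i]
    p_exc <- unclass(grids$exclusion)[, i]
    ok <- !is.na(p_inc) & !is.na(p_exc)
    if (!any(ok)) return(NULL)
    cbind(emotion = EMOTIONS[ok], interval = i,
          comparative_error(p_inc[ok], p_exc[ok],
                            n_by_cond[["inclusion"]],
                            n_by_cond[["exclusion"]]))
  }))
  emit(ce, "comparative_error.csv")

  # --- shuffle null -------------------------------------------------------
  shuffle_res <- do.call(rbind, lapply(names(patterns), function(cond) {
    m <- unclass(patterns[[cond]])
    covered <- which(!is.na(rowSums(m)))
    pat <- structure(m[covered, , drop = FALSE], class = "group_pattern")
    res <- shuffle_null_test(pat, seed = child_seed(config$seed, 2),
                             k = config$shuffle_k)
    cbind(condition = cond, res)
  }))
  emit(shuffle_res, "shuffle_null.csv")

  # --- AUC / masking ------------------------------------------------------
  aucs <- cohort_aucs(trimmed, tl)
  emit(aucs, "auc.csv")
  masked <- masked_auc(aucs)
  emit(masked, "auc_masked.csv")
  emit(auc_proportions(aucs), "auc_proportions.csv")

  # --- inference ----------------------------------------------------------
  tot <- aucs[aucs$scope == "total", ]
  wide <- function(df, valcol) {
    inc <- df[df$condition == "inclusion", ]
    exc <- df[df$condition == "exclusion", ]
    merge(inc[, c("subject_id", "emotion", valcol)],
          exc[, c("subject_id", "emotion", valcol)],
          by = c("subject_id", "emotion"), suffixes = c("_inc", "_exc"))
  }
  w <- wide(tot, "auc")
  wilcox <- do.call(rbind, lapply(EMOTIONS, function(e) {
    d <- w[w$emotion == e, ]
    cbind(emotion = e, wilcoxon_paired(d$auc_inc, d$auc_exc))
  }))
  wm <- wide(masked[masked$scope == "total", ], "masked")
  wilcox_masked <- do.call(rbind, lapply(setdiff(EMOTIONS, "happiness"),
    function(e) {
      d <- wm[wm$emotion == e, ]
      cbind(emotion = e, wilcoxon_paired(d$masked_inc, d$masked_exc))
    }))
  anova_with <- rm_anova_by_emotion(aucs, config$transforms,
                                    include_outliers = TRUE)
  anova_without <- rm_anova_by_emotion(aucs, config$transforms,
                                       include_outliers = FALSE)
  emit(anova_with, "rm_anova.csv")
  emit(anova_without, "rm_anova_no_outliers.csv")

  inference <- list(seed = config$seed, config_hash = hash,
                    wilcoxon_auc = wilcox,
                    wilcoxon_masked = wilcox_masked)
  if (!is.null(scores)) {
    scores <- scores[order(scores$subject_id), ]
    inference$nts_paired_t <- paired_t(scores$nts_exclusion,
                                       scores$nts_inclusion)
    sc <- scores[, c("scid_ii", "bis15", "best", "ders_e")]
    sc$nts <- scores$nts_inclusion
    if (nrow(sc) >= 4) {
      inference$scale_spearman <- spearman_matrix(sc)
    } else {
      inference$scale_spearman_skipped <- "fewer than 4 subjects"
    }
    auc_wide <- do.call(cbind, lapply(c("inclusion", "exclusion"),
      function(cond) {
        sub <- tot[tot$condition == cond, ]
        m <- matrix(sub$auc[order(sub$subject_id, match(sub$emotion,
                                                        EMOTIONS))],
                    ncol = 7, byrow = TRUE,
                    dimnames = list(NULL, paste0(EMOTIONS, "_",
                                                 substr(cond, 1, 3))))
        m
      }))
    if (nrow(sc) >= 4) {
      inference$scale_auc_spearman <-
        spearman_matrix(sc, as.data.frame(auc_wide))
    }
  }
  inf_path <- file.path(config$out_dir, "inference.json")
  jsonlite::write_json(inference, inf_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, dataframe = "rows")
  paths[["inference.json"]] <- inf_path

  structure(list(patterns = patterns, grids = grids,
                 difference_grid = dgrid, comparative_error = ce,
                 shuffle = shuffle_res, aucs = aucs, masked = masked,
                 anova = anova_with, anova_no_outliers = anova_without,
                 inference = inference, scores = scores,
                 config_hash = hash, paths = paths),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> config", x$config_hash, "\n")
  cat("  outputs:", paste(names(x$paths), collapse = ", "), "\n")
  invisible(x)
}
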