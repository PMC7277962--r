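#' Analyze a cohort feature + clinical table
#'
#' The full cohort statistics for one biomarker index: median split,
#' remission/response contingency and Pearson chi-square, repeated-
#' measures ANCOVA of the week-by-group interaction (Greenhouse-Geisser
#' corrected when Mauchly rejects sphericity), and per-week one-way
#' ANCOVA. Covariates throughout: age, sex, baseline HAM-D, medication
#' type. Complete cases only; no multiple-testing correction is applied
#' across indices (none is part of the analysis design).
#'
#' @param features data.frame with subject_id and index columns
#'   (faa_f5f6, faa_f7f8, ldaep, mmn; `core` is taken from clinical).
#' @param clinical clinical table (see [read_clinical_table()]).
#' @param indices index columns to analyze.
#' @param alpha significance level used for flags in the report.
#' @return nested list of results per index plus partial correlations of
#'   the melancholia (CORE) score with each ERP index.
#' @export
analyze_cohort <- function(features, clinical,
                           indices = c("faa_f5f6", "faa_f7f8",
                                       "ldaep", "mmn", "mel"),
                           alpha = 0.05) {
  df <- merge(clinical, features, by = "subject_id")
  df$mel <- df$core
  hamd_cols <- c("hamd_w0", "hamd_w2", "hamd_w4", "hamd_w8")
  complete <- stats::complete.cases(df[hamd_cols])
  n_dropped <- sum(!complete)
  df <- df[complete, ]
  covs <- df[, c("age", "sex", "hamd_w0", "medication")]
  names(covs) <- c("age", "sex", "baseline_hamd", "medication")
  out_flags <- classify_outcomes(df$hamd_w0, df$hamd_w8)

  per_index <- lapply(indices, function(ix) {
    vals <- df[[ix]]
    sp <- median_split(vals, ix)
    res <- list(index = ix, split = sp)
    # degenerate outcomes (everyone remitted/responded) leave the
    # chi-square undefined; report NA rather than aborting the cohort
    chi_or_na <- function(flag) tryCatch(
      pearson_chi2(contingency(sp$group, flag)),
      error = function(e) list(statistic = NA_real_, df = 1L,
                               p = NA_real_, note = conditionMessage(e)))
    res$chi2_remission <- chi_or_na(out_flags$remission)
    res$chi2_response <- chi_or_na(out_flags$response)
    res$rm_ancova <- rm_ancova(as.matrix(df[hamd_cols]), sp$group, covs)
    res$ancova_by_week <- lapply(stats::setNames(hamd_cols, hamd_cols),
                                 function(cc)
                                   ancova_at_week(df[[cc]], sp$group, covs))
    res
  })
  names(per_index) <- indices

  mel_corr <- lapply(stats::setNames(setdiff(indices, "mel"),
                                     setdiff(indices, "mel")),
                     function(ix) partial_corr(df$mel, df[[ix]], covs))

  list(n = nrow(df), n_dropped_incomplete = n_dropped, alpha = alpha,
       overall = list(
         remission_rate = mean(out_flags$remission),
         response_rate = mean(out_flags$response)),
       indices = per_index, mel_partial_corr = mel_corr)
}

#' Run the end-to-end synthetic pipeline
#'
#' Simulates a clinical cohort, synthesizes the three EEG paradigms per
#' subject with the cohort's per-subject ground truth, extracts the
#' biomarker vector through the full preprocessing chain, and runs the
#' cohort statistics. Deterministic given the configuration (including
#' its seed). Optionally writes the feature table, clinical table, ground
#' truth and results bundle to an output directory.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory or NULL (no files written).
#' @param paradigms which EEG paradigms to synthesize and extract; by
#'   default all three. Indices whose paradigm is skipped fall back to
#'   the generator's true values (feature-level simulation).
#' @param alpha significance level for report flags.
#' @return list: clinical, truth, features, results (from
#'   [analyze_cohort()]).
#' @export
run_pipeline <- function(cfg, out_dir = NULL,
                         paradigms = c("resting", "ldaep", "mmn"),
                         alpha = 0.05) {
  cohort <- gen_clinical_cohort(cfg)
  n <- cfg$n_subjects
  feats <- cohort$truth[, c("subject_id", "faa_f5f6_true",
                            "faa_f7f8_true", "ldaep_true", "mmn_true")]
  names(feats) <- c("subject_id", "faa_f5f6", "faa_f7f8", "ldaep", "mmn")
  for (i in seq_len(n)) {
    tr <- cohort$truth[i, ]
    if ("resting" %in% paradigms) {
      rec <- gen_resting_eeg(cfg, i, asym = c(f5f6 = tr$faa_f5f6_true,
                                              f7f8 = tr$faa_f7f8_true))
      faa <- compute_faa(rec)
      feats$faa_f5f6[i] <- faa$f5f6$value
      feats$faa_f7f8[i] <- faa$f7f8$value
    }
    if ("ldaep" %in% paradigms) {
      rec <- gen_ldaep_recording(cfg, i, slope = tr$ldaep_true)
      ep <- segment_events(bandpass(rec, 0.1, 30), post_ms = 900)
      feats$ldaep[i] <- ldaep(ep)$slope
    }
    if ("mmn" %in% paradigms) {
      rec <- gen_mmn_recording(cfg, i, amp = tr$mmn_true)
      ep <- segment_events(bandpass(rec, 0.1, 30), post_ms = 600)
      feats$mmn[i] <- mmn(ep)$composite
    }
  }
  results <- analyze_cohort(feats, cohort$clinical, alpha = alpha)
  bundle <- list(clinical = cohort$clinical, truth = cohort$truth,
                 features = feats, results = results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_clinical_table(cohort$clinical,
                         file.path(out_dir, "clinical.csv"))
    utils::write.csv(feats, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    jsonlite::write_json(cohort$truth,
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(strip_for_json(results),
                         file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(format_report(results, cfg),
               file.path(out_dir, "report.txt"))
  }
  bundle
}

strip_for_json <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_for_json)
  } else if (is.factor(x)) {
    x <- as.character(x)
  }
  x
}

#' Plain-text report of the cohort analysis
#' @param results output of [analyze_cohort()].
#' @param cfg the simulation config used (for provenance), or NULL.
#' @return character vector of report lines.
#' @export
format_report <- function(results, cfg = NULL) {
  a <- results$alpha
  flag <- function(p) if (!is.na(p) && p < a) "*" else " "
  lines <- c(
    "ERP biomarker treatment-outcome analysis",
    sprintf("n = %d complete cases (%d dropped incomplete); alpha = %g",
            results$n, results$n_dropped_incomplete, a),
    sprintf("remission %.2f%%, response %.2f%%",
            100 * results$overall$remission_rate,
            100 * results$overall$response_rate),
    "")
  for (ix in names(results$indices)) {
    r <- results$indices[[ix]]
    w8 <- r$ancova_by_week$hamd_w8
    lines <- c(lines,
      sprintf("[%s] median %.3f", ix, r$split$median),
      sprintf("  chi2 remission X2(1) = %.2f, p = %.3f%s",
              r$chi2_remission$statistic, r$chi2_remission$p,
              flag(r$chi2_remission$p)),
      sprintf("  chi2 response  X2(1) = %.2f, p = %.3f%s",
              r$chi2_response$statistic, r$chi2_response$p,
              flag(r$chi2_response$p)),
      sprintf(paste0("  rANCOVA week x group F(%.3f, %.3f) = %.2f, ",
                     "p = %.3f%s (eps = %.4f, Mauchly p = %.3f%s)"),
              r$rm_ancova$df1, r$rm_ancova$df2, r$rm_ancova$F,
              r$rm_ancova$p, flag(r$rm_ancova$p), r$rm_ancova$epsilon,
              r$rm_ancova$mauchly_p,
              if (r$rm_ancova$gg_applied) ", GG applied" else ""),
      sprintf(paste0("  week-8 ANCOVA F = %.2f, p = %.3f%s; ",
                     "means low %.2f +/- %.2f, high %.2f +/- %.2f"),
              w8$F, w8$p, flag(w8$p),
              w8$means["low"], w8$sds["low"],
              w8$means["high"], w8$sds["high"]))
  }
  lines <- c(lines, "", "partial correlation with melancholia (CORE):")
  for (ix in names(results$mel_partial_corr)) {
    pc <- results$mel_partial_corr[[ix]]
    lines <- c(lines, sprintf("  %s: r = %.2f (df = %d), p = %.3f%s",
                              ix, pc$r, pc$df, pc$p, flag(pc$p)))
  }
  lines <- c(lines, "",
             "note: no multiple-testing correction across indices.")
  if (!is.null(cfg))
    lines <- c(lines, sprintf("provenance: seed %d, n_subjects %d",
                              cfg$seed, cfg$n_subjects))
  lines
}
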