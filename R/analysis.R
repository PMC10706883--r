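#' Full statistical analysis of a longitudinal CKD cohort
#'
#' Runs the clinical derivations (eGFR, slopes, progressor/stable labels from
#' the realized slopes) and the complete statistics layer: baseline
#' normality-gated group comparisons of every MRI measure, per-measure ROC of
#' baseline values against progression, Spearman correlation of baseline
#' measures with the eGFR slope, the pooled all-visit correlation matrix of
#' MRI and biochemical measures, and the CV-referenced percentage-change
#' monitoring report.
#'
#' @param clinical longitudinal clinical tibble (see [simulate_cohort()] /
#'   [read_clinical_csv()]).
#' @param mri tidy MRI summary tibble: subject_id, visit_year, measure,
#'   value.
#' @param alpha significance level used throughout.
#' @param n_boot ROC bootstrap resamples.
#' @param seed seed for the ROC bootstrap streams.
#' @param cv_table,polarity monitoring references, see [reference_cv()] and
#'   [decline_polarity()].
#' @return Object of class `ckd_analysis`: slopes, baseline_comparison,
#'   roc (tibble over measures), slope_correlation, correlation
#'   (`correlation_result`), change_report.
#' @export
analyze_cohort <- function(clinical, mri, alpha = 0.05, n_boot = 2000,
                           seed = NULL, cv_table = reference_cv(),
                           polarity = decline_polarity()) {
  if (inherits(clinical, "ckd_cohort")) {
    mri <- clinical$mri
    clinical <- clinical$clinical
  }
  clin <- add_egfr(clinical)
  slopes <- egfr_slopes(clin)
  labels <- slopes %>% select("subject_id", "label")
  baseline <- mri %>% filter(.data$visit_year == 0) %>%
    inner_join(labels, by = "subject_id")
  baseline_comparison <- baseline %>%
    rename(group = "label") %>%
    compare_measures(alpha = alpha)
  roc <- baseline %>%
    group_by(.data$measure) %>%
    dplyr::group_modify(function(d, key) {
      r <- roc_auc(d$value, d$label, positive = "progressor",
                   n_boot = n_boot,
                   seed = if (is.null(seed)) NULL
                          else derive_seed(seed, match(key$measure[1],
                                                       sort(unique(mri$measure)))))
      glance(r)
    }) %>% ungroup()
  wide_base <- baseline %>%
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "measure",
                       values_from = "value") %>%
    left_join(slopes %>% select("subject_id", "slope"), by = "subject_id")
  slope_corr <- slope_correlation(wide_base %>% select(-"subject_id"),
                                  alpha = alpha)
  pooled <- pooled_visit_table(clin, mri)
  corr <- correlation_matrix(pooled %>%
                               select(-"subject_id", -"visit_year"),
                             method = "auto", alpha = alpha)
  change <- pct_change_report(mri, labels, cv_table = cv_table,
                              polarity = polarity, alpha = alpha)
  structure(list(slopes = slopes, baseline_comparison = baseline_comparison,
                 roc = roc, slope_correlation = slope_corr,
                 correlation = corr, change_report = change,
                 alpha = alpha),
            class = "ckd_analysis")
}

# One row per subject x MRI visit: wide MRI measures plus the eGFR and
# log(PCR) of the clinical visit nearest in time.
pooled_visit_table <- function(clin, mri) {
  clin <- clin %>% group_by(.data$subject_id) %>%
    mutate(t_yr = as.numeric(.data$visit_date - min(.data$visit_date)) /
             365.25) %>% ungroup()
  wide <- mri %>%
    tidyr::pivot_wider(id_cols = c("subject_id", "visit_year"),
                       names_from = "measure", values_from = "value")
  nearest <- wide %>% select("subject_id", "visit_year") %>%
    purrr::pmap(function(subject_id, visit_year) {
      rows <- clin %>% filter(.data$subject_id == !!subject_id)
      rows[which.min(abs(rows$t_yr - visit_year)), ] %>%
        mutate(visit_year = visit_year)
    }) %>% list_rbind() %>%
    mutate(log_pcr = log_pcr(.data$pcr_mg_mmol)) %>%
    select("subject_id", "visit_year", "egfr", "log_pcr")
  wide %>% inner_join(nearest, by = c("subject_id", "visit_year"))
}

#' @export
print.ckd_analysis <- function(x, ...) {
  cat("<ckd_analysis>\n")
  cat(sprintf("  %d subjects, %d progressors (realized)\n",
              nrow(x$slopes), sum(x$slopes$label == "progressor")))
  sig <- x$baseline_comparison %>% filter(.data$significant)
  cat("  baseline differences:",
      if (nrow(sig)) paste(sig$measure, collapse = ", ") else "none", "\n")
  cat(sprintf("  change-report cells: %d decline, %d improve, %d no-change\n",
              sum(x$change_report$category == "decline"),
              sum(x$change_report$category == "improve"),
              sum(x$change_report$category == "no-change")))
  invisible(x)
}
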