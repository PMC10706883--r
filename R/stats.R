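#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk on each group; when both pass (p > alpha) a Welch two-sample
#' t-test is used, otherwise a two-sided Mann-Whitney U test (normal
#' approximation with mid-ranks, no continuity correction, so identical
#' groups give p = 1).
#'
#' @param x,y numeric samples (each n >= 3).
#' @param alpha normality-gate and reporting level, default 0.05.
#' @param measure optional measure label carried into the output.
#' @return One-row tibble: measure, n_x, n_y, center/dispersion per group
#'   (mean/SD when normal, median/IQR otherwise), test ("t-test" /
#'   "mann-whitney"), shapiro_p_x/y, p_value, significant.
#' @export
compare_groups <- function(x, y, alpha = 0.05, measure = NA_character_) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3)
    abort("group comparison needs at least 3 observations per group")
  shap <- function(v) tryCatch(shapiro.test(v)$p.value, error = function(e) 0)
  px <- shap(x); py <- shap(y)
  normal <- px > alpha && py > alpha
  p <- if (normal) t.test(x, y, var.equal = FALSE)$p.value
       else suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                         correct = FALSE))$p.value
  ctr <- function(v) if (normal) mean(v) else median(v)
  dsp <- function(v) if (normal) sd(v) else IQR(v)
  tibble(measure = measure, n_x = length(x), n_y = length(y),
         center_x = ctr(x), dispersion_x = dsp(x),
         center_y = ctr(y), dispersion_y = dsp(y),
         test = if (normal) "t-test" else "mann-whitney",
         shapiro_p_x = px, shapiro_p_y = py,
         p_value = p, significant = p < alpha)
}

#' Groupwise comparison of every measure in a tidy table
#'
#' @param data tidy tibble with one row per observation.
#' @param value,group,measure column names (strings) of the value, the
#'   two-level grouping factor, and the measure label.
#' @param alpha significance level.
#' @return tibble, one row per measure, as [compare_groups()].
#' @export
compare_measures <- function(data, value = "value", group = "group",
                             measure = "measure", alpha = 0.05) {
  g <- sort(unique(data[[group]]))
  if (length(g) != 2) abort("compare_measures needs exactly 2 groups")
  data %>%
    group_by(measure = .data[[measure]]) %>%
    dplyr::group_modify(function(d, key) {
      compare_groups(d[[value]][d[[group]] == g[1]],
                     d[[value]][d[[group]] == g[2]], alpha = alpha) %>%
        select(-"measure")
    }) %>%
    ungroup()
}

#' ROC area under the curve with bootstrap confidence interval
#'
#' AUC by the rank (Mann-Whitney) formulation with mid-ranks for ties — the
#' fraction of correctly ordered positive/negative pairs, ties counting 1/2.
#' The 95% CI is a stratified bootstrap percentile interval and the p-value
#' against AUC = 0.5 is the tie-corrected normal approximation of the
#' Mann-Whitney U statistic.
#'
#' @param scores numeric predictor.
#' @param labels logical or two-level vector; `positive` names the positive
#'   class when not logical.
#' @param positive positive class label.
#' @param direction ">" scores higher in positives, "<" lower, "auto"
#'   (default) picks the orientation with AUC >= 0.5 and records it.
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level.
#' @param seed optional local RNG seed for the bootstrap.
#' @return Object of class `roc_result`: auc, ci_lo, ci_hi, p_value,
#'   direction, n_pos, n_neg, n_boot, conf.
#' @export
roc_auc <- function(scores, labels, positive = TRUE, direction = "auto",
                    n_boot = 2000, conf = 0.95, seed = NULL) {
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("ROC needs both classes present")
  auc_raw <- auc_rank(scores, pos)
  dir_used <- direction
  if (direction == "auto") dir_used <- if (auc_raw >= 0.5) ">" else "<"
  s <- if (dir_used == "<") -scores else scores
  auc <- auc_rank(s, pos)
  # tie-corrected normal approximation for U = auc * n1 * n0 vs null 1/2
  n <- n1 + n0
  ties <- table(scores)
  tiecorr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n0 / 12 * ((n + 1) - tiecorr))
  z <- (auc_raw * n1 * n0 - n1 * n0 / 2) / sigma
  p <- 2 * pnorm(-abs(z))
  boot <- with_local_seed(seed, {
    ip <- which(pos); ineg <- which(!pos)
    vapply(seq_len(n_boot), function(b) {
      bi <- c(sample(ip, n1, replace = TRUE), sample(ineg, n0, replace = TRUE))
      auc_rank(s[bi], pos[bi])
    }, numeric(1))
  })
  qs <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  structure(list(auc = auc, ci_lo = qs[1], ci_hi = qs[2], p_value = p,
                 direction = dir_used, n_pos = n1, n_neg = n0,
                 n_boot = n_boot, conf = conf, scores = s, pos = pos),
            class = "roc_result")
}

# Mid-rank AUC: ties between classes count half.
auc_rank <- function(scores, pos) {
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC AUC %.3f (%.0f%% CI %.3f-%.3f), p = %.4g (n = %d/%d, direction %s)\n",
              x$auc, 100 * x$conf, x$ci_lo, x$ci_hi, x$p_value,
              x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' Pairwise correlation matrix with normality-gated method choice
#'
#' Correlates every pair of numeric columns over pairwise-complete rows.
#' With `method = "auto"` a pair uses Pearson when both columns pass
#' Shapiro-Wilk at `alpha`, Spearman otherwise; `"pearson"`/`"spearman"`
#' force the method.
#'
#' @param data tibble/data frame; non-numeric columns are dropped.
#' @param method "auto", "pearson" or "spearman".
#' @param alpha significance / normality-gate level.
#' @return Object of class `correlation_result` with matrices `estimate`,
#'   `p_value`, `n`, `method` and the `alpha` used.  [tidy()] gives the long
#'   form.
#' @export
correlation_matrix <- function(data, method = c("auto", "pearson", "spearman"),
                               alpha = 0.05) {
  method <- match.arg(method)
  num <- data[vapply(data, is.numeric, logical(1))]
  vars <- names(num)
  k <- length(vars)
  if (k < 2) abort("correlation matrix needs at least 2 numeric columns")
  est <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  meth <- matrix(NA_character_, k, k, dimnames = list(vars, vars))
  normal_col <- vapply(num, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 3 || sd(v) == 0) return(FALSE)
    tryCatch(shapiro.test(v)$p.value > alpha, error = function(e) FALSE)
  }, logical(1))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    xi <- num[[i]]; xj <- num[[j]]
    ok <- is.finite(xi) & is.finite(xj)
    nmat[i, j] <- sum(ok)
    if (sum(ok) < 3 || sd(xi[ok]) == 0 || sd(xj[ok]) == 0) next
    m <- switch(method, auto = if (normal_col[i] && normal_col[j])
                  "pearson" else "spearman", method)
    ct <- suppressWarnings(cor.test(xi[ok], xj[ok], method = m,
                                    exact = FALSE))
    est[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value; meth[i, j] <- m
  }
  structure(list(estimate = est, p_value = p, n = nmat, method = meth,
                 alpha = alpha), class = "correlation_result")
}

#' Spearman correlation of each measure with the eGFR slope
#'
#' Spearman is forced (the slope is a rank-level progression indicator);
#' constant measures are returned flagged with `NA` correlation.
#'
#' @param data tibble of numeric columns including `slope_col`.
#' @param slope_col name of the eGFR-slope column.
#' @param alpha significance level.
#' @return tibble: measure, rho, p_value, n, significant.
#' @export
slope_correlation <- function(data, slope_col = "slope", alpha = 0.05) {
  stopifnot(slope_col %in% names(data))
  slope <- data[[slope_col]]
  vars <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], slope_col)
  purrr::map(vars, function(v) {
    x <- data[[v]]
    ok <- is.finite(x) & is.finite(slope)
    if (sum(ok) < 3 || sd(x[ok]) == 0)
      return(tibble(measure = v, rho = NA_real_, p_value = NA_real_,
                    n = sum(ok), significant = NA))
    ct <- suppressWarnings(cor.test(x[ok], slope[ok], method = "spearman",
                                    exact = FALSE))
    tibble(measure = v, rho = unname(ct$estimate), p_value = ct$p.value,
           n = sum(ok), significant = ct$p.value < alpha)
  }) %>% list_rbind()
}

#' Reference between-session coefficients of variation
#'
#' Published short-term intra-subject between-session CVs used as the
#' detectable-change band for longitudinal monitoring, keyed by measure
#' family (a measure like `t1_cortex` maps onto family `t1`).
#'
#' @return tibble: family, cv_pct.
#' @export
reference_cv <- function() {
  tibble(family = c("tkv", "t1", "adc", "t2star", "perfusion"),
         cv_pct = c(2.5, 3, 4, 6, 12))
}

#' Decline polarity of each MRI measure family
#'
#' Direction of change associated with declining kidney function: TKV, ADC
#' and T2* fall while T1 rises; perfusion falls (loss of cortical
#' microvasculature).
#'
#' @return named numeric vector (+1 = rises with decline, -1 = falls).
#' @export
decline_polarity <- function() {
  c(tkv = -1, t1 = 1, adc = -1, t2star = -1, perfusion = -1)
}

measure_family <- function(measure) sub("_(cortex|medulla)$", "", measure)

#' Percentage-change monitoring report with CV-referenced classification
#'
#' For every subject who completed all requested visits, the percentage
#' change of each measure from baseline is computed at each follow-up year.
#' Per group x measure x year the mean change is tested against zero
#' (one-sample t) and a cell is called a change only when the test is
#' significant at `alpha` AND the mean change magnitude exceeds the
#' measure's reference between-session CV; the direction then maps onto
#' "decline" or "improve" via the decline-polarity table, everything else
#' is "no-change".  Between-group and year-1-vs-year-2 comparisons of the
#' percentage changes are included.
#'
#' @param summaries tidy tibble: subject_id, visit_year (0 = baseline),
#'   measure, value.
#' @param labels tibble: subject_id, label ("progressor"/"stable").
#' @param cv_table reference CV table, see [reference_cv()].
#' @param polarity named polarity vector, see [decline_polarity()].
#' @param alpha significance level.
#' @param years follow-up years reported (default 1 and 2; baseline is 0).
#' @return tibble of class `change_report`: label, measure, visit_year, n,
#'   mean_pct, sd_pct, p_vs_zero, exceeds_cv, p_between_groups, p_y1_vs_y2,
#'   category.
#' @export
pct_change_report <- function(summaries, labels, cv_table = reference_cv(),
                              polarity = decline_polarity(), alpha = 0.05,
                              years = c(1, 2)) {
  need <- c(0, years)
  complete <- summaries %>%
    filter(.data$visit_year %in% need) %>%
    group_by(.data$subject_id, .data$measure) %>%
    filter(length(unique(.data$visit_year)) == length(need)) %>%
    ungroup()
  base <- complete %>% filter(.data$visit_year == 0) %>%
    select("subject_id", "measure", baseline = "value")
  pct <- complete %>% filter(.data$visit_year != 0) %>%
    inner_join(base, by = c("subject_id", "measure")) %>%
    mutate(pct_change = 100 * (.data$value - .data$baseline) / .data$baseline) %>%
    inner_join(labels, by = "subject_id")
  safe_p <- function(v) if (length(v) >= 3 && sd(v) > 0)
    t.test(v)$p.value else NA_real_
  safe_p2 <- function(a, b) if (length(a) >= 3 && length(b) >= 3 &&
                                (sd(a) > 0 || sd(b) > 0))
    t.test(a, b)$p.value else NA_real_
  rep <- pct %>%
    group_by(.data$label, .data$measure, .data$visit_year) %>%
    summarise(n = dplyr::n(), mean_pct = mean(.data$pct_change),
              sd_pct = sd(.data$pct_change),
              p_vs_zero = safe_p(.data$pct_change), .groups = "drop")
  between <- pct %>%
    group_by(.data$measure, .data$visit_year) %>%
    summarise(p_between_groups = safe_p2(
      .data$pct_change[.data$label == "progressor"],
      .data$pct_change[.data$label == "stable"]), .groups = "drop")
  yr_pair <- if (length(years) == 2) pct %>%
    tidyr::pivot_wider(id_cols = c("subject_id", "measure", "label"),
                       names_from = "visit_year", values_from = "pct_change",
                       names_prefix = "y") %>%
    group_by(.data$label, .data$measure) %>%
    summarise(p_y1_vs_y2 = {
      d <- .data[[paste0("y", years[2])]] - .data[[paste0("y", years[1])]]
      if (length(d) >= 3 && sd(d) > 0) t.test(d)$p.value else NA_real_
    }, .groups = "drop")
  else NULL
  out <- rep %>%
    left_join(between, by = c("measure", "visit_year")) %>%
    mutate(family = measure_family(.data$measure)) %>%
    left_join(cv_table, by = "family") %>%
    mutate(exceeds_cv = abs(.data$mean_pct) > .data$cv_pct,
           significant = !is.na(.data$p_vs_zero) & .data$p_vs_zero < alpha &
             .data$exceeds_cv,
           category = dplyr::case_when(
             !significant ~ "no-change",
             sign(.data$mean_pct) == polarity[.data$family] ~ "decline",
             TRUE ~ "improve"))
  if (!is.null(yr_pair))
    out <- left_join(out, yr_pair, by = c("label", "measure"))
  structure(out %>% select(-"family"),
            class = c("change_report", class(out)))
}
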