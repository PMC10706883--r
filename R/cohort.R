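#' Default cohort MRI measure table
#'
#' Study conditions of the synthetic cohort: per-measure group means at
#' baseline, between-subject SD, annual drift (%/yr, compounded) per group,
#' and the between-session CV of the per-visit measurement noise (equal to
#' the reference CVs of [reference_cv()]).  Progressors start with higher
#' cortex/medulla T1 and lower cortex perfusion; TKV, ADC and T2* are equal
#' at baseline.  Longitudinally, progressors lose TKV and ADC and gain
#' cortical T1 and lose perfusion; the stable group only loses TKV.
#'
#' @return tibble, one row per measure.
#' @export
default_measure_table <- function() {
  tibble(
    measure = c("tkv", "t1_cortex", "t1_medulla", "perfusion_cortex",
                "adc_cortex", "adc_medulla", "t2star_cortex",
                "t2star_medulla"),
    mean_progressor = c(130, 1600, 2000, 150, 2.0e-3, 1.8e-3, 55, 42),
    mean_stable = c(130, 1450, 1850, 250, 2.0e-3, 1.8e-3, 55, 42),
    between_sd = c(20, 60, 60, 40, 1.5e-4, 1.5e-4, 4, 3),
    drift_progressor_pct_yr = c(-5, 4, 0, -8, -5, -5, 0, 0),
    drift_stable_pct_yr = c(-3, 0, 0, 0, 0, 0, 0, 0),
    session_cv_pct = c(2.5, 3, 3, 12, 4, 4, 6, 6)
  )
}

#' Specify a synthetic CKD cohort
#'
#' Longitudinal clinical trajectories (creatinine back-computed so that
#' CKD-EPI eGFR follows `intercept + slope * t` plus measurement noise,
#' quarterly over two years) together with per-visit MRI tissue summaries
#' drifting by group.  Group labels are assigned twice: the intended
#' (generative) group and the realized label from the eGFR-slope rule;
#' analyses use the realized label.
#'
#' @param n_progressor,n_stable subjects per intended group (each >= 2).
#' @param egfr_intercept,egfr_slope lists with `progressor`/`stable`
#'   c(mean, sd) entries (mL/min/1.73 m^2 and per year).
#' @param creatinine_cv multiplicative creatinine measurement CV.
#' @param visit_days clinical visit schedule in days from baseline
#'   (strictly increasing).
#' @param mri_years MRI visit times in years.
#' @param pcr lognormal log-parameters per group (`meanlog`, `sdlog`).
#' @param measures MRI measure table, see [default_measure_table()].
#' @param seed RNG seed fixing the whole cohort.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_progressor = 9, n_stable = 13,
                        egfr_intercept = list(progressor = c(38, 8),
                                              stable = c(42, 10)),
                        egfr_slope = list(progressor = c(-8, 1.2),
                                          stable = c(-1.5, 1.2)),
                        creatinine_cv = 0.04,
                        visit_days = seq(0, 728, by = 91),
                        mri_years = c(0, 1, 2),
                        pcr = list(progressor = c(meanlog = log(120),
                                                  sdlog = 0.7),
                                   stable = c(meanlog = log(35), sdlog = 0.8)),
                        measures = default_measure_table(),
                        seed = 2024) {
  stopifnot(n_progressor >= 2, n_stable >= 2,
            all(diff(visit_days) > 0), creatinine_cv >= 0)
  structure(list(n_progressor = n_progressor, n_stable = n_stable,
                 egfr_intercept = egfr_intercept, egfr_slope = egfr_slope,
                 creatinine_cv = creatinine_cv, visit_days = visit_days,
                 mri_years = mri_years, pcr = pcr, measures = measures,
                 seed = seed),
            class = "cohort_spec")
}

#' Simulate the synthetic CKD cohort
#'
#' @param spec a [cohort_spec()].
#' @param baseline_date date of the first visit.
#' @return Object of class `ckd_cohort`:
#'   * `clinical` — tibble(subject_id, visit_date, age, sex, ethnicity_black,
#'     creatinine_umol_L, pcr_mg_mmol), one row per clinical visit;
#'   * `mri` — tibble(subject_id, visit_year, measure, value);
#'   * `subjects` — tibble(subject_id, group_intended, slope_true,
#'     slope_realized, label_realized);
#'   * the spec.
#' @export
simulate_cohort <- function(spec, baseline_date = as.Date("2020-01-06")) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_progressor + spec$n_stable
    subjects <- tibble(
      subject_id = sprintf("S%02d", seq_len(n)),
      group_intended = rep(c("progressor", "stable"),
                           c(spec$n_progressor, spec$n_stable)),
      age0 = pmin(pmax(rnorm(n, 58, 12), 25), 85),
      sex = ifelse(runif(n) < 0.7, "male", "female"),
      ethnicity_black = runif(n) < 0.1,
      intercept = NA_real_, slope_true = NA_real_)
    for (g in c("progressor", "stable")) {
      sel <- subjects$group_intended == g
      subjects$intercept[sel] <- rnorm(sum(sel), spec$egfr_intercept[[g]][1],
                                       spec$egfr_intercept[[g]][2])
      subjects$slope_true[sel] <- rnorm(sum(sel), spec$egfr_slope[[g]][1],
                                        spec$egfr_slope[[g]][2])
    }
    subjects$intercept <- pmax(subjects$intercept, 16)
    pcr_base <- numeric(n)
    for (g in c("progressor", "stable")) {
      sel <- subjects$group_intended == g
      pcr_base[sel] <- rlnorm(sum(sel), spec$pcr[[g]]["meanlog"],
                              spec$pcr[[g]]["sdlog"])
    }
    clinical <- tidyr::expand_grid(i = seq_len(n), day = spec$visit_days) %>%
      mutate(t_yr = .data$day / 365.25) %>%
      mutate(subject_id = subjects$subject_id[.data$i],
             sex = subjects$sex[.data$i],
             ethnicity_black = subjects$ethnicity_black[.data$i],
             age = subjects$age0[.data$i] + .data$t_yr,
             egfr_true = pmax(subjects$intercept[.data$i] +
                                subjects$slope_true[.data$i] * .data$t_yr, 5),
             visit_date = baseline_date + .data$day)
    clinical$creatinine_umol_L <- invert_egfr(
      clinical$egfr_true, clinical$age, clinical$sex,
      clinical$ethnicity_black) *
      pmax(1 + rnorm(nrow(clinical), 0, spec$creatinine_cv), 0.5)
    clinical$pcr_mg_mmol <- pcr_base[clinical$i] *
      exp(rnorm(nrow(clinical), 0, 0.15))
    clinical <- clinical %>%
      select("subject_id", "visit_date", "age", "sex", "ethnicity_black",
             "creatinine_umol_L", "pcr_mg_mmol")
    mri <- tidyr::expand_grid(i = seq_len(n),
                              measure = spec$measures$measure,
                              visit_year = spec$mri_years) %>%
      left_join(spec$measures, by = "measure")
    base_draw <- mri %>% distinct(.data$i, .data$measure) %>%
      left_join(spec$measures, by = "measure") %>%
      mutate(base = rnorm(dplyr::n(),
                          ifelse(subjects$group_intended[.data$i] == "progressor",
                                 .data$mean_progressor, .data$mean_stable),
                          .data$between_sd)) %>%
      select("i", "measure", "base")
    mri <- mri %>%
      left_join(base_draw, by = c("i", "measure")) %>%
      mutate(drift = ifelse(subjects$group_intended[.data$i] == "progressor",
                            .data$drift_progressor_pct_yr,
                            .data$drift_stable_pct_yr),
             value = .data$base * (1 + .data$drift / 100)^.data$visit_year *
               (1 + rnorm(dplyr::n(), 0, .data$session_cv_pct / 100)),
             subject_id = subjects$subject_id[.data$i]) %>%
      select("subject_id", "visit_year", "measure", "value")
    realized <- add_egfr(clinical) %>% egfr_slopes()
    subjects <- subjects %>%
      select("subject_id", "group_intended", "age0", "sex",
             "ethnicity_black", "slope_true") %>%
      left_join(realized %>% select("subject_id", slope_realized = "slope",
                                    label_realized = "label"),
                by = "subject_id")
    structure(list(clinical = clinical, mri = mri, subjects = subjects,
                   spec = spec),
              class = "ckd_cohort")
  })
}

#' @export
print.ckd_cohort <- function(x, ...) {
  cat(sprintf("<ckd_cohort: %d subjects (%d intended progressors), %d clinical visits, %d MRI rows>\n",
              nrow(x$subjects), sum(x$subjects$group_intended == "progressor"),
              nrow(x$clinical), nrow(x$mri)))
  invisible(x)
}

#' Write / read a cohort's clinical table as CSV
#'
#' Column layout: subject_id, visit_date (ISO-8601), age, sex,
#' ethnicity_black, creatinine_umol_L, pcr_mg_mmol.
#'
#' @param clinical clinical tibble.
#' @param path CSV path.
#' @export
write_clinical_csv <- function(clinical, path) {
  write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_csv
#' @export
read_clinical_csv <- function(path) {
  as_tibble(read.csv(path)) %>%
    mutate(visit_date = as.Date(.data$visit_date),
           ethnicity_black = as.logical(.data$ethnicity_black))
}
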