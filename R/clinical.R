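UMOL_PER_MGDL <- 88.4   # serum creatinine unit conversion

#' CKD-EPI 2009 estimated glomerular filtration rate
#'
#' The 2009 creatinine equation:
#' `eGFR = 141 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.209 * 0.993^Age *
#' 1.018 [female] * 1.159 [black]` with `k = 0.7` (female) / `0.9` (male) and
#' `a = -0.329` (female) / `-0.411` (male).  Creatinine is accepted in
#' µmol/L (divided by 88.4) or mg/dL.
#'
#' @param creatinine serum creatinine, > 0 (vectorised).
#' @param age age in years, >= 18.
#' @param sex "female"/"male" (or "F"/"M").
#' @param black logical, Black ethnicity coefficient.
#' @param units creatinine units, "umol/L" (default) or "mg/dL".
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr_ckdepi <- function(creatinine, age, sex, black = FALSE,
                        units = c("umol/L", "mg/dL")) {
  units <- match.arg(units)
  if (any(!is.finite(creatinine)) || any(creatinine <= 0))
    abort("creatinine must be positive")
  if (any(age < 18)) abort("CKD-EPI 2009 applies to adults (age >= 18)")
  female <- normalize_sex(sex)
  scr <- if (units == "umol/L") creatinine / UMOL_PER_MGDL else creatinine
  kappa <- ifelse(female, 0.7, 0.9)
  a <- ifelse(female, -0.329, -0.411)
  141 * pmin(scr / kappa, 1)^a * pmax(scr / kappa, 1)^(-1.209) *
    0.993^age * ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
}

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  f <- s %in% c("f", "female")
  m <- s %in% c("m", "male")
  if (any(!f & !m)) abort("sex must be 'female'/'male' (or 'F'/'M')")
  f
}

#' Invert CKD-EPI 2009 for serum creatinine
#'
#' Serum creatinine that yields a given eGFR for the stated age/sex/ethnicity
#' (used by the synthetic cohort generator to back-compute creatinine series
#' from target eGFR trajectories).
#'
#' @param egfr target eGFR, mL/min/1.73 m^2.
#' @inheritParams egfr_ckdepi
#' @param units output creatinine units.
#' @return creatinine (vectorised).
#' @export
invert_egfr <- function(egfr, age, sex, black = FALSE,
                        units = c("umol/L", "mg/dL")) {
  units <- match.arg(units)
  stopifnot(all(egfr > 0))
  female <- normalize_sex(sex)
  kappa <- ifelse(female, 0.7, 0.9)
  a <- ifelse(female, -0.329, -0.411)
  knot <- 141 * 0.993^age * ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
  ratio <- egfr / knot           # = (Scr/kappa)^a or ^-1.209 piecewise
  scr <- ifelse(ratio <= 1,
                kappa * ratio^(-1 / 1.209),   # Scr >= kappa branch
                kappa * ratio^(1 / a))        # Scr <  kappa branch
  if (units == "umol/L") scr * UMOL_PER_MGDL else scr
}

#' Least-squares eGFR slope
#'
#' Ordinary least squares of eGFR on time in years from the first
#' measurement, using all available points; a negative slope is an annual
#' decline.
#'
#' @param dates visit dates (`Date`, ISO-8601 strings, or numeric years).
#' @param egfr eGFR values, same length.
#' @return One-row tibble: slope (mL/min/1.73 m^2/yr), intercept, n_points,
#'   and `low_confidence` (TRUE when only 2 points).  Fewer than 2 points is
#'   an error.
#' @export
egfr_slope <- function(dates, egfr) {
  t_yr <- to_years(dates)
  ok <- is.finite(t_yr) & is.finite(egfr)
  t_yr <- t_yr[ok]; y <- egfr[ok]
  if (length(y) < 2) abort("eGFR slope needs at least 2 points")
  if (any(duplicated(t_yr)) && length(unique(t_yr)) < 2)
    abort("eGFR slope needs at least 2 distinct timepoints")
  tc <- t_yr - mean(t_yr)
  slope <- sum(tc * y) / sum(tc^2)
  tibble(slope = slope, intercept = mean(y) - slope * mean(t_yr),
         n_points = length(y), low_confidence = length(y) < 3)
}

to_years <- function(dates) {
  if (inherits(dates, "Date"))
    return(as.numeric(dates - min(dates)) / 365.25)
  if (is.character(dates))
    return(as.numeric(as.Date(dates) - min(as.Date(dates))) / 365.25)
  as.numeric(dates) - min(as.numeric(dates))
}

#' Classify CKD progression from the eGFR slope
#'
#' A decline of at least 5 mL/min/1.73 m^2 per year (slope <= -5, boundary
#' inclusive) labels the subject a progressor; anything shallower is stable.
#'
#' @param slope eGFR slope(s), mL/min/1.73 m^2/yr.
#' @param threshold decline threshold (positive magnitude), default 5.
#' @return character vector, "progressor"/"stable".
#' @export
classify_progression <- function(slope, threshold = 5) {
  ifelse(slope <= -threshold, "progressor", "stable")
}

#' Base-10 log of the urine protein-creatinine ratio
#'
#' PCR distributions are strongly right-skewed, so analyses use log(PCR).
#' The base only rescales the variable; rank statistics are unaffected.
#'
#' @param pcr PCR, mg/mmol, > 0.
#' @return log10(PCR).
#' @export
log_pcr <- function(pcr) {
  if (any(!is.finite(pcr)) || any(pcr <= 0)) abort("PCR must be positive")
  log10(pcr)
}

#' Derive eGFR on a longitudinal clinical table
#'
#' Tibble-in, tibble-out: adds an `egfr` column from creatinine, per-visit
#' age, sex and ethnicity.
#'
#' @param clinical tibble with columns `creatinine_umol_L`, `age`, `sex`,
#'   `ethnicity_black`.
#' @return the input with an `egfr` column appended.
#' @export
add_egfr <- function(clinical) {
  clinical %>%
    mutate(egfr = egfr_ckdepi(.data$creatinine_umol_L, .data$age, .data$sex,
                              .data$ethnicity_black, units = "umol/L"))
}

#' Per-subject eGFR slopes and progression labels
#'
#' @param clinical tibble with `subject_id`, `visit_date` and `egfr` columns
#'   (see [add_egfr()]).
#' @param threshold progression threshold passed to [classify_progression()].
#' @return tibble: subject_id, slope, intercept, n_points, low_confidence,
#'   label.
#' @export
egfr_slopes <- function(clinical, threshold = 5) {
  clinical %>%
    group_by(.data$subject_id) %>%
    dplyr::group_modify(~ egfr_slope(.x$visit_date, .x$egfr)) %>%
    ungroup() %>%
    mutate(label = classify_progression(.data$slope, threshold))
}
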