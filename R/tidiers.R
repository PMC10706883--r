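#' Tidy a voxelwise map fit
#'
#' One row per fitted voxel with its grid indices, the fitted parameters and
#' the status code.
#'
#' @param x a `map_fit` object (`ir_fit`, `t2star_fit`, `adc_fit`,
#'   `perfusion_fit`).
#' @param ... unused.
#' @return tibble with columns i, j, k plus the fit's parameter maps.
#' @export
tidy.map_fit <- function(x, ...) {
  arrays <- x[vapply(x, function(v) is.array(v) && length(dim(v)) == 3,
                     logical(1))]
  idx <- which(!is.na(arrays$status))
  dims <- dim(arrays$status)
  coords <- arrayInd(idx, dims)
  out <- tibble(i = coords[, 1], j = coords[, 2], k = coords[, 3])
  for (nm in names(arrays)) out[[nm]] <- arrays[[nm]][idx]
  out
}

#' @export
glance.map_fit <- function(x, ...) {
  st <- x$status[!is.na(x$status)]
  tibble(n_voxels = length(st), n_ok = sum(st == 0),
         n_flagged = sum(st != 0),
         mean_sse = if (!is.null(x$sse)) mean(x$sse[x$status == 0], na.rm = TRUE)
                    else NA_real_)
}

#' @export
tidy.roc_result <- function(x, ...) {
  thr <- sort(unique(x$scores), decreasing = TRUE)
  purrr::map(c(Inf, thr, -Inf), function(t)
    tibble(threshold = t,
           sensitivity = mean(x$scores[x$pos] >= t),
           specificity = mean(x$scores[!x$pos] < t))) %>% list_rbind()
}

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
         p_value = x$p_value, direction = x$direction,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
tidy.correlation_result <- function(x, ...) {
  vars <- rownames(x$estimate)
  tidyr::expand_grid(var1 = vars, var2 = vars) %>%
    mutate(estimate = as.vector(t(x$estimate)),
           p_value = as.vector(t(x$p_value)),
           n = as.vector(t(x$n)),
           method = as.vector(t(x$method)),
           significant = .data$p_value < x$alpha) %>%
    filter(.data$var1 != .data$var2)
}

#' @export
glance.ckd_analysis <- function(x, ...) {
  tibble(n_subjects = nrow(x$slopes),
         n_progressor = sum(x$slopes$label == "progressor"),
         n_stable = sum(x$slopes$label == "stable"),
         n_baseline_significant = sum(x$baseline_comparison$significant),
         n_decline_cells = sum(x$change_report$category == "decline"),
         alpha = x$alpha)
}

#' Plot a slice of a 3D parameter map
#'
#' @param map 3D array.
#' @param slice slice index along the 3rd axis (default: middle).
#' @param title,unit labels.
#' @return a ggplot.
#' @export
plot_map_slice <- function(map, slice = NULL, title = NULL, unit = NULL) {
  if (is.null(slice)) slice <- ceiling(dim(map)[3] / 2)
  df <- tidyr::expand_grid(i = seq_len(dim(map)[1]),
                           j = seq_len(dim(map)[2])) %>%
    mutate(value = map[cbind(.data$i, .data$j, slice)])
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = unit) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.map_fit <- function(object, slice = NULL, ...) {
  nm <- intersect(c("t1_ms", "adc_mm2_s", "t2star_ms", "perfusion"),
                  names(object))[1]
  unit <- c(t1_ms = "ms", adc_mm2_s = "mm²/s", t2star_ms = "ms",
            perfusion = "mL/100g/min")[nm]
  plot_map_slice(object[[nm]], slice, title = nm, unit = unname(unit))
}

#' @export
autoplot.roc_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC %.2f (%.0f%% CI %.2f-%.2f)",
                                  object$auc, 100 * object$conf,
                                  object$ci_lo, object$ci_hi)) +
    ggplot2::theme_minimal()
}

#' Heat-map of the percentage-change monitoring report
#'
#' Cells significantly changed in the direction associated with declining
#' kidney function are red, improvements blue, everything else grey.
#'
#' @param object a [pct_change_report()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.change_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(factor(.data$visit_year), .data$measure,
                               fill = .data$category)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.5) +
    ggplot2::facet_wrap(~ .data$label) +
    ggplot2::scale_fill_manual(values = c(decline = "#c23b22",
                                          improve = "#3b6fc2",
                                          `no-change` = "grey75")) +
    ggplot2::labs(x = "year", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' eGFR trajectories of a synthetic cohort
#'
#' @param object a [simulate_cohort()] result.
#' @param ... unused.
#' @return a ggplot of per-subject eGFR over time coloured by realized label.
#' @export
autoplot.ckd_cohort <- function(object, ...) {
  d <- add_egfr(object$clinical) %>%
    left_join(object$subjects %>% select("subject_id", "label_realized"),
              by = "subject_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$visit_date, .data$egfr,
                                  group = .data$subject_id,
                                  colour = .data$label_realized)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "eGFR (mL/min/1.73m²)", colour = NULL) +
    ggplot2::theme_minimal()
}
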