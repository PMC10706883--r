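#' Tissue mask container
#'
#' Kidney, cortex and medulla boolean volumes with the geometric invariants
#' enforced at construction: cortex and medulla are disjoint and both are
#' contained in the kidney mask.
#'
#' @param kidney,cortex,medulla logical 3D arrays.
#' @param voxel_mm voxel size in mm.
#' @param threshold_ms the T1 threshold that produced the split (if any).
#' @return list of class `tissue_masks`.
#' @export
tissue_masks <- function(kidney, cortex, medulla, voxel_mm,
                         threshold_ms = NA_real_) {
  stopifnot(identical(dim(kidney), dim(cortex)),
            identical(dim(kidney), dim(medulla)))
  if (any(cortex & medulla))
    abort("cortex and medulla masks overlap")
  if (any((cortex | medulla) & !kidney))
    abort("cortex/medulla masks extend outside the kidney mask")
  structure(list(kidney = kidney, cortex = cortex, medulla = medulla,
                 voxel_mm = as.numeric(voxel_mm),
                 voxel_volume_mm3 = prod(voxel_mm),
                 threshold_ms = threshold_ms),
            class = "tissue_masks")
}

#' @export
print.tissue_masks <- function(x, ...) {
  cat(sprintf("<tissue_masks: kidney %d, cortex %d, medulla %d voxels, T1 threshold %s ms>\n",
              sum(x$kidney), sum(x$cortex), sum(x$medulla),
              format(x$threshold_ms, digits = 5)))
  invisible(x)
}

#' T1 histogram threshold between cortex and medulla
#'
#' Fits a two-component Gaussian mixture (EM, deterministic model-based
#' initialisation) to the in-kidney T1 values and returns the value between
#' the two component means where the weighted component densities intersect.
#' This operationalises the bimodal-histogram threshold used to split renal
#' cortex (lower T1 at 3T) from medulla.
#'
#' @param t1_map 3D T1 array (ms).
#' @param kidney_mask logical 3D array.
#' @param options list; `min_voxels` (default 50), `min_separation_sd`
#'   (components whose means are closer than this multiple of the pooled SD
#'   are treated as unresolved, default 1), `max_dip_ratio` (the fitted
#'   mixture density must fall below this fraction of its value at the modes
#'   somewhere between them, default 0.95; otherwise the histogram is deemed
#'   unimodal).
#' @return Numeric threshold (ms) with attributes `means`, `sds`, `weights`.
#'   An unresolved (effectively unimodal) histogram raises a classed error
#'   (`renalmri_error_unresolved_mixture`) with a diagnostic.
#' @export
t1_threshold <- function(t1_map, kidney_mask, options = list()) {
  opt <- modifyList(list(min_voxels = 50, min_separation_sd = 1,
                         max_dip_ratio = 0.95), options)
  x <- t1_map[kidney_mask & is.finite(t1_map)]
  if (length(x) < opt$min_voxels)
    abort("too few in-kidney T1 values for a histogram threshold")
  # Mclust resolves mclustBIC in the caller's frame, so bind it locally.
  mclustBIC <- mclust::mclustBIC
  fit <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit))
    abort("Gaussian mixture fit failed on the T1 histogram",
          class = "renalmri_error_unresolved_mixture")
  mu <- fit$parameters$mean
  sdv <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sdv) == 1) sdv <- rep(sdv, 2)
  w <- fit$parameters$pro
  o <- order(mu)
  mu <- mu[o]; sdv <- sdv[o]; w <- w[o]
  pooled <- sqrt(mean(sdv^2))
  if (min(w) < 0.01 || diff(mu) < opt$min_separation_sd * pooled)
    abort(paste0("T1 histogram components unresolved (means ",
                 sprintf("%.0f/%.0f ms, pooled SD %.0f ms", mu[1], mu[2], pooled),
                 "); cortex/medulla cannot be separated"),
          class = "renalmri_error_unresolved_mixture")
  # bimodality check: the fitted mixture density must dip between the means
  # (a 2-component fit of a unimodal histogram has no interior valley)
  gx <- seq(mu[1], mu[2], length.out = 512)
  dens <- w[1] * stats::dnorm(gx, mu[1], sdv[1]) +
    w[2] * stats::dnorm(gx, mu[2], sdv[2])
  if (min(dens) > opt$max_dip_ratio * min(dens[1], dens[512]))
    abort("T1 histogram appears unimodal: no density valley between the fitted modes",
          class = "renalmri_error_unresolved_mixture")
  h <- function(t) log(w[1]) + stats::dnorm(t, mu[1], sdv[1], log = TRUE) -
    log(w[2]) - stats::dnorm(t, mu[2], sdv[2], log = TRUE)
  if (h(mu[1]) <= 0 || h(mu[2]) >= 0)
    abort("component densities do not intersect between the means",
          class = "renalmri_error_unresolved_mixture")
  thr <- uniroot(h, lower = mu[1], upper = mu[2], tol = 1e-6)$root
  structure(thr, means = mu, sds = sdv, weights = w)
}

#' Split the kidney into cortex and medulla at a T1 threshold
#'
#' Cortex collects the in-kidney voxels with T1 below the threshold, medulla
#' those at or above it (renal cortex T1 < medulla T1 at 3T).
#'
#' @param t1_map 3D T1 array (ms).
#' @param kidney_mask logical 3D array.
#' @param threshold_ms threshold in ms, e.g. from [t1_threshold()].
#' @param voxel_mm voxel size in mm.
#' @return a [tissue_masks()] object.
#' @export
apply_threshold <- function(t1_map, kidney_mask, threshold_ms, voxel_mm) {
  valid <- kidney_mask & is.finite(t1_map)
  cortex <- valid & t1_map < threshold_ms
  medulla <- valid & t1_map >= threshold_ms
  tissue_masks(kidney_mask, cortex, medulla, voxel_mm,
               threshold_ms = as.numeric(threshold_ms))
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b logical arrays of equal shape.
#' @return `2|A n B| / (|A| + |B|)`; 1 for identical non-empty masks.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Gaussian mode and FWHM of an in-mask histogram
#'
#' Histogram of the in-mask map values (Freedman-Diaconis bin width with a
#' floor of 10 bins) to whose bin counts a Gaussian curve is least-squares
#' fitted; the mode is the fitted mean and the FWHM is `2 sqrt(2 ln 2)` times
#' the fitted sigma.
#'
#' @param map 3D numeric array.
#' @param mask logical 3D array.
#' @param measure optional measure label carried into the output.
#' @param options list; `min_voxels` (histograms below this are flagged,
#'   default 30), `min_bins` (default 10).
#' @return One-row tibble: measure, mode, fwhm, sigma, n_voxels, r2, status
#'   (0 ok, 1 flagged: too few voxels or degenerate histogram).
#' @export
summarize_measure <- function(map, mask, measure = NA_character_,
                              options = list()) {
  opt <- modifyList(list(min_voxels = 30, min_bins = 10), options)
  x <- map[mask & is.finite(map)]
  flagged <- tibble(measure = measure, mode = NA_real_, fwhm = NA_real_,
                    sigma = NA_real_, n_voxels = length(x), r2 = NA_real_,
                    status = 1L)
  if (length(x) < opt$min_voxels || sd(x) == 0) return(flagged)
  bw <- 2 * IQR(x) / length(x)^(1 / 3)
  if (bw <= 0) return(flagged)
  nbins <- max(opt$min_bins, ceiling(diff(range(x)) / bw))
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1),
                      plot = FALSE)
  df <- data.frame(mid = h$mids, count = h$counts)
  start <- list(a = max(h$counts), mu = mean(x), sig = sd(x))
  fit <- tryCatch(
    minpack.lm::nlsLM(count ~ a * exp(-(mid - mu)^2 / (2 * sig^2)),
                      data = df, start = start,
                      lower = c(0, min(x), 1e-12),
                      upper = c(Inf, max(x), diff(range(x))),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(flagged)
  cf <- coef(fit)
  sst <- sum((df$count - mean(df$count))^2)
  r2 <- if (sst > 0) 1 - sum(resid(fit)^2) / sst else NA_real_
  tibble(measure = measure, mode = unname(cf["mu"]),
         fwhm = 2 * sqrt(2 * log(2)) * unname(cf["sig"]),
         sigma = unname(cf["sig"]), n_voxels = length(x), r2 = r2,
         status = 0L)
}

#' Per-tissue Gaussian summaries of a set of parameter maps
#'
#' Applies [summarize_measure()] to each map within the cortex and medulla
#' masks (pooling both kidneys' voxels into one histogram, matching the
#' bilateral-mean convention; set `per_kidney = TRUE` to also split by side
#' when the masks carry `left`/`right` volumes).
#'
#' @param maps named list of 3D arrays (e.g. `t1`, `adc`, `t2star`,
#'   `perfusion`).
#' @param masks a [tissue_masks()] object.
#' @param per_kidney also emit per-kidney rows.
#' @return tidy tibble: tissue, measure, mode, fwhm, sigma, n_voxels, r2,
#'   status (+ `side` when `per_kidney`).
#' @export
summarize_tissues <- function(maps, masks, per_kidney = FALSE) {
  tissues <- list(cortex = masks$cortex, medulla = masks$medulla)
  pooled <- purrr::imap(tissues, function(m, tis)
    purrr::imap(maps, function(mp, nm)
      summarize_measure(mp, m, measure = nm)) %>%
      list_rbind() %>% mutate(tissue = tis, .before = 1)) %>%
    list_rbind()
  if (!per_kidney) return(pooled)
  if (is.null(masks$left) || is.null(masks$right))
    abort("per-kidney summaries need left/right kidney masks")
  sides <- purrr::imap(list(left = masks$left, right = masks$right),
    function(side_mask, side)
      purrr::imap(tissues, function(m, tis)
        purrr::imap(maps, function(mp, nm)
          summarize_measure(mp, m & side_mask, measure = nm)) %>%
          list_rbind() %>% mutate(tissue = tis, .before = 1)) %>%
        list_rbind() %>% mutate(side = side)) %>%
    list_rbind()
  bind_rows(mutate(pooled, side = "both"), sides)
}

#' Total kidney volume and BSA correction
#'
#' Mask-based volume: voxel count times voxel volume over both kidneys, in
#' mL.  When height and weight are supplied the DuBois body surface area
#' `0.007184 W^0.425 H^0.725` (W kg, H cm) normalises the volume to mL/m^2.
#'
#' @param masks a [tissue_masks()] (its `kidney` volume is used) or a logical
#'   array.
#' @param voxel_mm voxel size in mm (taken from `masks` when omitted).
#' @param height_cm,weight_kg optional anthropometrics for BSA correction.
#' @return One-row tibble: tkv_ml, n_voxels, bsa_m2, tkv_bsa_ml_m2.
#' @export
total_kidney_volume <- function(masks, voxel_mm = NULL, height_cm = NULL,
                                weight_kg = NULL) {
  if (inherits(masks, "tissue_masks")) {
    kidney <- masks$kidney
    if (is.null(voxel_mm)) voxel_mm <- masks$voxel_mm
  } else kidney <- masks
  stopifnot(!is.null(voxel_mm))
  tkv_ml <- sum(kidney) * prod(voxel_mm) / 1000
  bsa <- if (!is.null(height_cm) && !is.null(weight_kg))
    0.007184 * weight_kg^0.425 * height_cm^0.725 else NA_real_
  tibble(tkv_ml = tkv_ml, n_voxels = sum(kidney), bsa_m2 = bsa,
         tkv_bsa_ml_m2 = tkv_ml / bsa)
}
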