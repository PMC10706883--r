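#' Combine diffusion directions by geometric mean
#'
#' Collapses the three orthogonal diffusion directions into one
#' direction-averaged series per b-value using the voxelwise geometric mean,
#' which equals the arithmetic mean in the log domain and is therefore exactly
#' consistent with the downstream log-linear ADC fit: the fitted ADC of the
#' combined series is the mean of the per-direction ADCs.
#'
#' Voxels with a non-positive signal in any direction get `NA` at that
#' b-value and are handled by the positivity fallback of [fit_adc()].
#'
#' @param series a DWI [acquisition_series()] with `b_s_mm2` and `direction`
#'   columns.
#' @return an [acquisition_series()] with one volume per b-value.
#' @export
combine_directions <- function(series) {
  stopifnot(inherits(series, "acquisition_series"), series$modality == "dwi")
  p <- series$params
  bvals <- sort(unique(p$b_s_mm2))
  ndir <- length(unique(p$direction))
  dims <- dim(series$data)[1:3]
  out <- array(NA_real_, c(dims, length(bvals)))
  for (k in seq_along(bvals)) {
    sel <- which(p$b_s_mm2 == bvals[k])
    if (length(sel) != ndir)
      abort(sprintf("b = %g has %d direction volumes, expected %d",
                    bvals[k], length(sel), ndir))
    sub <- series$data[, , , sel, drop = FALSE]
    bad <- apply(sub <= 0, 1:3, any)
    gm <- exp(apply(log(pmax(sub, .Machine$double.xmin)), 1:3, mean))
    gm[bad] <- NA_real_
    out[, , , k] <- gm
  }
  acquisition_series(out, tibble(b_s_mm2 = bvals), series$voxel_mm, "dwi")
}

#' Voxel-wise apparent diffusion coefficient fit
#'
#' Mono-exponential fit over all b-values: ordinary least squares of `log(S)`
#' on b; the slope is `-ADC`.  If the series still carries multiple
#' directions they are first collapsed with [combine_directions()].
#' Non-positive signals are dropped pointwise (>= 3 points must remain,
#' including one low b), and voxels whose fitted ADC is negative are flagged
#' rather than reported.
#'
#' @param series a DWI [acquisition_series()].
#' @param mask logical 3D array; `NULL` fits everything.
#' @param options list; `min_points` (default 3), `low_b_max` (a usable fit
#'   needs one b-value below this, default 50 s/mm^2).
#' @return list of class `c("adc_fit", "map_fit")` with arrays `adc_mm2_s`,
#'   `s0`, `r2`, `status`.
#' @export
fit_adc <- function(series, mask = NULL, options = list()) {
  stopifnot(inherits(series, "acquisition_series"))
  opt <- modifyList(list(min_points = 3, low_b_max = 50), options)
  if ("direction" %in% names(series$params) &&
      length(unique(series$params$direction)) > 1)
    series <- combine_directions(series)
  b <- series$params$b_s_mm2
  if (length(unique(b)) < 3 || !any(b < opt$low_b_max))
    abort("ADC fit needs >= 3 b-values including one low b (< 50 s/mm^2)")
  dims <- dim(series$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  idx <- which(mask)
  sig <- matrix(series$data[, , , , drop = FALSE][rep(mask, length(b))],
                nrow = length(idx))
  fit <- loglinear_fit(sig, b, opt$min_points)
  adc <- -fit$slope
  status <- fit$status
  neg <- status == FIT_OK & !is.na(adc) & adc < 0
  status[neg] <- FIT_NONPHYS
  adc[neg] <- NA_real_
  to_arr <- function(v, fill = NA_real_) { a <- array(fill, dims); a[idx] <- v; a }
  structure(list(adc_mm2_s = to_arr(adc), s0 = to_arr(exp(fit$intercept)),
                 r2 = to_arr(fit$r2), status = to_arr(status, NA_integer_),
                 b_s_mm2 = b, voxel_mm = series$voxel_mm),
            class = c("adc_fit", "map_fit"))
}
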