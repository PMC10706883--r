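# Fit-status codes shared by the voxelwise fitters:
#   0 = ok, 1 = degenerate/empty signal, 2 = unidentifiable (no inversion
#   contrast), 3 = non-physical decay (non-negative slope), 4 = too few
#   usable points.
FIT_OK <- 0L; FIT_EMPTY <- 1L; FIT_UNIDENT <- 2L; FIT_NONPHYS <- 3L
FIT_TOOFEW <- 4L

#' Voxel-wise inversion-recovery T1 fit
#'
#' Fits the magnitude inversion-recovery model
#' `|M0 (1 - 2 eps exp(-TI/T1))|` per voxel by polarity restoration: for each
#' candidate null-crossing position the points before the crossing are
#' sign-flipped and the signed two-parameter model is fitted, the candidate
#' with the lowest SSE winning.  For fixed T1 the signed model is linear in
#' M0, so the fit profiles M0 out in closed form and searches T1 on a coarse
#' logarithmic grid refined by continuous 1D optimisation.
#'
#' @param series an IR [acquisition_series()] (magnitude data, >= 5 distinct
#'   TIs).  An unsorted TI list is sorted internally with a warning.
#' @param mask logical 3D array of voxels to fit; `NULL` fits everything.
#' @param options list; recognised entries `t1_range` (ms, default
#'   `c(50, 5000)`), `epsilon` (fixed inversion efficiency, default 1),
#'   `fit_epsilon` (logical, fit eps in (0, 1] as a free parameter),
#'   `grid_n` (coarse grid size, default 120), `tol` (optimiser tolerance on
#'   T1 in ms, default 1e-4).
#' @return list of class `c("ir_fit", "map_fit")` with 3D arrays `t1_ms`,
#'   `m0`, `epsilon`, `sse`, `status` (see source for codes), restricted to
#'   the mask.
#' @export
fit_t1_ir <- function(series, mask = NULL, options = list()) {
  stopifnot(inherits(series, "acquisition_series"))
  opt <- modifyList(list(t1_range = c(50, 5000), epsilon = 1,
                         fit_epsilon = FALSE, grid_n = 120, tol = 1e-4),
                    options)
  ti <- series$params$ti_ms
  if (length(unique(ti)) < 5)
    abort("inversion-recovery fit needs at least 5 distinct TIs")
  ord <- order(ti)
  if (is.unsorted(ti)) {
    warn("TI list is unsorted; sorting volumes by TI")
  }
  ti <- ti[ord]
  dims <- dim(series$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  idx <- which(mask)
  sig <- matrix(series$data[, , , ord, drop = FALSE][rep(mask, length(ti))],
                nrow = length(idx))
  t1g <- exp(seq(log(opt$t1_range[1]), log(opt$t1_range[2]),
                 length.out = opt$grid_n))
  E <- exp(-outer(ti, 1 / t1g))                     # nTI x nGrid
  nb <- length(idx)
  t1v <- rep(NA_real_, nb); m0v <- rep(NA_real_, nb)
  epsv <- rep(NA_real_, nb); ssev <- rep(NA_real_, nb)
  stat <- rep(FIT_OK, nb)
  for (i in seq_len(nb)) {
    s <- sig[i, ]
    r <- fit_t1_voxel(s, ti, t1g, E, opt)
    t1v[i] <- r$t1; m0v[i] <- r$m0; epsv[i] <- r$eps
    ssev[i] <- r$sse; stat[i] <- r$status
  }
  to_arr <- function(v, fill = NA_real_) { a <- array(fill, dims); a[idx] <- v; a }
  structure(list(t1_ms = to_arr(t1v), m0 = to_arr(m0v), epsilon = to_arr(epsv),
                 sse = to_arr(ssev), status = to_arr(stat, NA_integer_),
                 ti_ms = ti, options = opt, voxel_mm = series$voxel_mm),
            class = c("ir_fit", "map_fit"))
}

# Two-column linear profile when eps is free: y = a - 2 b exp(-TI/T1),
# a = M0, b = M0 * eps.  Constrained afterwards to eps in (0, 1].
ir_profile_sse_eps <- function(y, E) {
  n <- length(y)
  x2 <- -2 * E
  s1 <- sum(y)
  sx <- drop(crossprod(x2, y))
  sxx <- colSums(x2^2)
  sx1 <- colSums(x2)
  det <- n * sxx - sx1^2
  a <- (sxx * s1 - sx1 * sx) / det
  b <- (n * sx - sx1 * s1) / det
  eps <- pmin(pmax(b / a, 1e-6), 1)
  b <- a * eps
  fitted_sse <- vapply(seq_along(a), function(j)
    sum((y - a[j] - b[j] * x2[, j])^2), numeric(1))
  fitted_sse[!is.finite(a) | a <= 0] <- sum(y^2)   # M0 must be positive
  list(sse = fitted_sse, m0 = a, eps = eps)
}

fit_t1_voxel <- function(s, ti, t1g, E, opt) {
  bad <- list(t1 = NA_real_, m0 = NA_real_, eps = NA_real_, sse = NA_real_)
  if (all(s == 0) || anyNA(s))
    return(c(bad, status = FIT_EMPTY))
  if (sd(s) / max(abs(mean(s)), .Machine$double.eps) < 1e-6)
    return(c(bad, status = FIT_UNIDENT))   # flat series: no inversion contrast
  jmin <- which.min(s)
  cand <- unique(pmin(pmax(0:(jmin + 1), 0), length(s)))
  best <- list(sse = Inf)
  for (j in cand) {
    y <- s
    if (j > 0) y[seq_len(j)] <- -y[seq_len(j)]
    pr <- if (opt$fit_epsilon) ir_profile_sse_eps(y, E)
          else {
            G <- 1 - 2 * opt$epsilon * E
            num <- drop(crossprod(G, y)); den <- colSums(G^2)
            # physical constraint M0 > 0: candidates whose profiled M0 is
            # negative fall back to the null model
            list(sse = ifelse(num > 0, sum(y^2) - num^2 / den, sum(y^2)),
                 m0 = pmax(num / den, 0),
                 eps = rep(opt$epsilon, ncol(E)))
          }
    k <- which.min(pr$sse)
    # continuous refinement around the best grid point
    lo <- t1g[max(k - 1, 1)]; hi <- t1g[min(k + 1, length(t1g))]
    obj <- function(t1) {
      e <- exp(-ti / t1)
      if (opt$fit_epsilon) ir_profile_sse_eps(y, matrix(e))$sse
      else {
        g <- 1 - 2 * opt$epsilon * e
        num <- sum(g * y)
        if (num > 0) sum(y^2) - num^2 / sum(g^2) else sum(y^2)
      }
    }
    o <- optimize(obj, lower = lo, upper = hi, tol = opt$tol)
    if (o$objective < best$sse) {
      e <- exp(-ti / o$minimum)
      if (opt$fit_epsilon) {
        pe <- ir_profile_sse_eps(y, matrix(e))
        best <- list(sse = o$objective, t1 = o$minimum, m0 = pe$m0[1],
                     eps = pe$eps[1])
      } else {
        g <- 1 - 2 * opt$epsilon * e
        best <- list(sse = o$objective, t1 = o$minimum,
                     m0 = max(sum(g * y) / sum(g^2), 0), eps = opt$epsilon)
      }
    }
  }
  if (!is.finite(best$sse) || best$m0 <= 0)
    return(c(bad, status = FIT_UNIDENT))
  list(t1 = best$t1, m0 = best$m0, eps = best$eps, sse = best$sse,
       status = FIT_OK)
}

# Vectorised log-linear decay fit: OLS of log(signal) on x per voxel.
# Returns slope/intercept/r2/status; voxels with non-positive signals fall
# back to their positive points (>= min_points) or are flagged.
loglinear_fit <- function(sig, x, min_points = 3) {
  nb <- nrow(sig)
  slope <- rep(NA_real_, nb); intercept <- rep(NA_real_, nb)
  r2 <- rep(NA_real_, nb); status <- rep(FIT_OK, nb)
  allpos <- rowSums(sig <= 0 | is.na(sig)) == 0
  ols <- function(xv, yv) {
    mx <- mean(xv); my <- mean(yv)
    sxx <- sum((xv - mx)^2)
    b <- sum((xv - mx) * (yv - my)) / sxx
    a <- my - b * mx
    ssr <- sum((yv - a - b * xv)^2)
    sst <- sum((yv - my)^2)
    c(b, a, if (sst > 0) 1 - ssr / sst else 1)
  }
  if (any(allpos)) {
    Y <- log(sig[allpos, , drop = FALSE])
    mx <- mean(x); xc <- x - mx
    sxx <- sum(xc^2)
    b <- drop(Y %*% xc) / sxx
    a <- rowMeans(Y) - b * mx
    fitted <- outer(a, rep(1, length(x))) + outer(b, x)
    ssr <- rowSums((Y - fitted)^2)
    sst <- rowSums((Y - rowMeans(Y))^2)
    slope[allpos] <- b; intercept[allpos] <- a
    r2[allpos] <- ifelse(sst > 0, 1 - ssr / sst, 1)
  }
  for (i in which(!allpos)) {
    ok <- is.finite(sig[i, ]) & sig[i, ] > 0
    if (sum(ok) < min_points) { status[i] <- FIT_TOOFEW; next }
    fit <- ols(x[ok], log(sig[i, ok]))
    slope[i] <- fit[1]; intercept[i] <- fit[2]; r2[i] <- fit[3]
  }
  list(slope = slope, intercept = intercept, r2 = r2, status = status)
}

#' Voxel-wise T2* fit from multi-echo gradient-echo data
#'
#' Ordinary least squares of `log(S)` on echo time (the log of the
#' exponential signal decay); the slope is `-1/T2*` and the intercept
#' `log(S0)`.  Voxels with non-positive echoes keep their positive points
#' when at least 3 remain, otherwise they are flagged; a non-negative slope
#' (signal not decaying) is flagged rather than reported as a negative T2*.
#'
#' @param series an mFFE [acquisition_series()] with >= 3 echoes.
#' @param mask logical 3D array; `NULL` fits everything.
#' @param options list; `min_points` (default 3).
#' @return list of class `c("t2star_fit", "map_fit")` with arrays `t2star_ms`,
#'   `s0`, `r2`, `status`.
#' @export
fit_t2star <- function(series, mask = NULL, options = list()) {
  stopifnot(inherits(series, "acquisition_series"))
  opt <- modifyList(list(min_points = 3), options)
  te <- series$params$te_ms
  if (length(te) < 3) abort("T2* fit needs at least 3 echoes")
  dims <- dim(series$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  idx <- which(mask)
  sig <- matrix(series$data[, , , , drop = FALSE][rep(mask, length(te))],
                nrow = length(idx))
  fit <- loglinear_fit(sig, te, opt$min_points)
  t2s <- ifelse(fit$slope < 0, -1 / fit$slope, NA_real_)
  status <- fit$status
  status[fit$status == FIT_OK & (is.na(fit$slope) | fit$slope >= 0)] <- FIT_NONPHYS
  to_arr <- function(v, fill = NA_real_) { a <- array(fill, dims); a[idx] <- v; a }
  structure(list(t2star_ms = to_arr(t2s), s0 = to_arr(exp(fit$intercept)),
                 r2 = to_arr(fit$r2), status = to_arr(status, NA_integer_),
                 te_ms = te, voxel_mm = series$voxel_mm),
            class = c("t2star_fit", "map_fit"))
}
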