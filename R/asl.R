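#' ASL kinetic-model constants
#'
#' Fixed physiological constants of the pulsed-ASL quantification: blood T1
#' at 3T, labelling (inversion) efficiency, and the blood-tissue water
#' partition coefficient.
#'
#' @param t1_blood_ms longitudinal relaxation time of arterial blood (ms).
#' @param alpha inversion efficiency, in (0, 1].
#' @param lambda partition coefficient (mL/g).
#' @return list of class `asl_constants`.
#' @export
asl_constants <- function(t1_blood_ms = 1650, alpha = 0.95, lambda = 0.9) {
  stopifnot(t1_blood_ms > 0, alpha > 0, alpha <= 1, lambda > 0)
  structure(list(t1_blood_ms = t1_blood_ms, alpha = alpha, lambda = lambda),
            class = "asl_constants")
}

# Unit conversion: perfusion in mL/100g/min expressed per gram per ms.
# 1 mL/100g/min = 1 / (100 * 60000) mL/g/ms = 1/6e6 mL/g/ms.
PERFUSION_MS_FACTOR <- 6e6

#' Pulsed-ASL kinetic model forward signal
#'
#' Single-compartment general kinetic model for pulsed labelling: the
#' difference signal is zero before the labelled bolus arrives (`t < att`),
#' accrues while the bolus (duration `tau`) is delivered, and decays after
#' the bolus ends.  With `k = 1/T1b - 1/T1'`,
#' \deqn{\Delta M(t) = \frac{2 \alpha M_0}{\lambda} \frac{f}{6\times 10^6}
#'   e^{-t/T_1'} \frac{e^{-k\,att} - e^{-k \min(t, att+\tau)}}{k}, \quad t > att}
#' and 0 otherwise.  The apparent tissue decay T1' is the tissue T1 (outflow
#' neglected), which makes the signal exactly linear in `f`.
#'
#' Worked unit audit: `f = 250` mL/100g/min, `att = 500` ms, `tau = 800` ms,
#' `t = 1800` ms, `M0 = 100`, tissue T1 `1500` ms and default constants give a
#' delivery integral of 254.488 ms and `dM = 2 * 0.95 * (100/0.9) *
#' (250/6e6) * 254.488 = 2.2386` a.u.
#'
#' @param f perfusion, mL/100g/min (array or scalar).
#' @param att_ms arterial transit time, ms.
#' @param tau_ms labelled bolus duration, ms.
#' @param t_ms time since labelling (post-label delay), ms; scalar.
#' @param m0 equilibrium magnetization (a.u.).
#' @param t1_ms tissue T1, ms.
#' @param constants an [asl_constants()] list.
#' @return Difference signal dM in the same units as `m0`, same shape as `f`.
#' @export
asl_signal <- function(f, att_ms, tau_ms, t_ms, m0, t1_ms,
                       constants = asl_constants()) {
  stopifnot(length(t_ms) == 1, t_ms >= 0)
  out <- f * 0
  ok <- t_ms > att_ms & t1_ms > 0 & m0 > 0
  if (!any(ok)) return(out)
  t1 <- t1_ms[ok]
  k <- 1 / constants$t1_blood_ms - 1 / t1
  tend <- pmin(t_ms, att_ms[ok] + tau_ms[ok])
  integral <- ifelse(abs(k) < 1e-12,
                     tend - att_ms[ok],
                     (exp(-k * att_ms[ok]) - exp(-k * tend)) / k)
  out[ok] <- 2 * constants$alpha * (m0[ok] / constants$lambda) *
    (f[ok] / PERFUSION_MS_FACTOR) * exp(-t_ms / t1) * integral
  out
}

#' Perfusion-weighted difference maps from S/NS pairs
#'
#' Pairwise selective-minus-non-selective subtraction, averaged over the
#' repeats within each post-label delay.  The long-PLD average is the
#' conventional single perfusion-weighted map.
#'
#' @param series an ASL [acquisition_series()] (label/PLD/pair sidecar).
#' @return list of class `delta_m`: `maps` (named list of 3D arrays, one per
#'   PLD), `pld_ms`, `n_pairs`, `voxel_mm`, `m0`.
#' @export
compute_delta_m <- function(series) {
  stopifnot(inherits(series, "acquisition_series"), series$modality == "asl")
  p <- series$params
  plds <- sort(unique(p$pld_ms))
  maps <- lapply(plds, function(pl) {
    is_s <- which(p$pld_ms == pl & p$label == "S")
    is_ns <- which(p$pld_ms == pl & p$label == "NS")
    if (length(is_s) != length(is_ns) || length(is_s) == 0)
      abort("mismatched selective/non-selective pair counts")
    s <- apply(series$data[, , , is_s, drop = FALSE], 1:3, mean)
    ns <- apply(series$data[, , , is_ns, drop = FALSE], 1:3, mean)
    s - ns
  })
  names(maps) <- paste0("pld", plds)
  n_pairs <- vapply(plds, function(pl)
    sum(p$pld_ms == pl & p$label == "S"), integer(1))
  structure(list(maps = maps, pld_ms = plds, n_pairs = n_pairs,
                 voxel_mm = series$voxel_mm, m0 = series$m0),
            class = "delta_m")
}

# Delivery kernel: dM for unit perfusion (f = 1 mL/100g/min), voxelwise.
asl_kernel <- function(att_ms, tau_ms, t_ms, m0, t1_ms, constants) {
  asl_signal(rep(1, length(m0)), att_ms, tau_ms, t_ms, m0, t1_ms, constants)
}

#' Estimate arterial transit time and perfusion from multi-PLD ASL
#'
#' Voxelwise least-squares fit of the pulsed-ASL kinetic model to the
#' difference signal across post-label delays, with perfusion and transit
#' time free and bolus duration fixed.  Because the model is linear in
#' perfusion, each candidate transit time has a closed-form best perfusion;
#' the transit time is found by a coarse grid search (`att_grid`) refined
#' with a continuous 1D optimisation.
#'
#' @param dm a [compute_delta_m()] result covering several PLDs.
#' @param m0 3D M0 array (defaults to the one carried by `dm`).
#' @param t1_ms 3D tissue T1 array (from the T1 fit) or scalar.
#' @param mask logical 3D array of voxels to fit.
#' @param tau_ms fixed bolus duration, ms.
#' @param constants an [asl_constants()] list.
#' @param att_grid candidate transit times for initialisation, ms.
#' @return list of class `perfusion_fit`: `perfusion` (mL/100g/min), `att_ms`,
#'   `sse`, `status` (0 ok, 1 no-signal) arrays restricted to the mask.
#' @export
estimate_inflow <- function(dm, m0 = dm$m0, t1_ms, mask, tau_ms = 800,
                            constants = asl_constants(),
                            att_grid = seq(100, 1500, by = 25)) {
  stopifnot(inherits(dm, "delta_m"), length(dm$pld_ms) >= 2)
  dims <- dim(dm$maps[[1]])
  if (length(t1_ms) == 1) t1_ms <- array(t1_ms, dims)
  idx <- which(mask)
  y <- vapply(dm$maps, function(m) m[idx], numeric(length(idx)))  # vox x PLD
  m0v <- m0[idx]; t1v <- t1_ms[idx]
  nb <- length(idx)
  # kernel per (voxel, PLD) for each candidate att
  best_sse <- rep(Inf, nb); best_f <- rep(0, nb); best_att <- rep(NA_real_, nb)
  sum_y2 <- rowSums(y^2)
  for (att in att_grid) {
    kmat <- vapply(dm$pld_ms, function(t)
      asl_kernel(rep(att, nb), rep(tau_ms, nb), t, m0v, t1v, constants),
      numeric(nb))
    den <- rowSums(kmat^2)
    num <- rowSums(kmat * y)
    f <- ifelse(den > 0, pmax(num / den, 0), 0)
    sse <- sum_y2 - 2 * f * num + f^2 * den
    upd <- sse < best_sse
    best_sse[upd] <- sse[upd]; best_f[upd] <- f[upd]; best_att[upd] <- att
  }
  # continuous refinement of att per voxel
  step <- if (length(att_grid) > 1) diff(att_grid)[1] else 0
  for (i in seq_len(nb)) {
    if (sum_y2[i] == 0) next
    obj <- function(att) {
      kv <- vapply(dm$pld_ms, function(t)
        asl_kernel(att, tau_ms, t, m0v[i], t1v[i], constants), numeric(1))
      den <- sum(kv^2)
      f <- if (den > 0) max(sum(kv * y[i, ]) / den, 0) else 0
      sum(( y[i, ] - f * kv)^2)
    }
    if (step > 0) {
      o <- optimize(obj, lower = max(min(att_grid), best_att[i] - step),
                    upper = min(max(att_grid), best_att[i] + step), tol = 1e-3)
      if (o$objective <= best_sse[i]) {
        best_att[i] <- o$minimum
        kv <- vapply(dm$pld_ms, function(t)
          asl_kernel(best_att[i], tau_ms, t, m0v[i], t1v[i], constants),
          numeric(1))
        den <- sum(kv^2)
        best_f[i] <- if (den > 0) max(sum(kv * y[i, ]) / den, 0) else 0
        best_sse[i] <- o$objective
      }
    }
  }
  to_arr <- function(v, fill = NA_real_) {
    a <- array(fill, dims); a[idx] <- v; a
  }
  status <- as.integer(sum_y2 == 0)   # 1 = no signal, att undefined
  best_att[status == 1] <- NA_real_
  structure(list(perfusion = to_arr(best_f), att_ms = to_arr(best_att),
                 sse = to_arr(best_sse), status = to_arr(status, NA_integer_),
                 tau_ms = tau_ms, constants = constants,
                 pld_ms = dm$pld_ms, voxel_mm = dm$voxel_mm),
            class = c("perfusion_fit", "map_fit"))
}

#' Quantify perfusion from the long-PLD difference map
#'
#' Inverts the pulsed-ASL kinetic model at a single (long) post-label delay
#' for perfusion, given the transit-time map, M0 and tissue T1.  The model is
#' linear in perfusion, so the inversion is exact: `f = dM / kernel`, with the
#' kernel the model signal at unit perfusion.
#'
#' @param dm_map 3D difference-signal array at `pld_ms` (e.g. the 1800 ms
#'   entry of [compute_delta_m()]).
#' @param att_ms 3D transit-time array (e.g. from [estimate_inflow()]) or
#'   scalar.
#' @param m0,t1_ms M0 and tissue T1 arrays (or scalars).
#' @param mask logical array of voxels to quantify.
#' @param pld_ms the post-label delay of `dm_map`, ms.
#' @inheritParams estimate_inflow
#' @return list of class `perfusion_map`: `perfusion` (mL/100g/min) and
#'   `status` (0 ok, 1 kernel zero / bolus not arrived) arrays.
#' @export
quantify_perfusion <- function(dm_map, att_ms, m0, t1_ms, mask,
                               pld_ms = 1800, tau_ms = 800,
                               constants = asl_constants()) {
  dims <- dim(dm_map)
  expand <- function(x) if (length(x) == 1) array(x, dims) else x
  att_ms <- expand(att_ms); m0 <- expand(m0); t1_ms <- expand(t1_ms)
  idx <- which(mask)
  kern <- asl_kernel(att_ms[idx], rep(tau_ms, length(idx)), pld_ms,
                     m0[idx], t1_ms[idx], constants)
  f <- ifelse(kern > 0, dm_map[idx] / kern, NA_real_)
  status <- as.integer(kern <= 0)
  perf <- array(NA_real_, dims); perf[idx] <- f
  st <- array(NA_integer_, dims); st[idx] <- status
  structure(list(perfusion = perf, status = st, pld_ms = pld_ms,
                 tau_ms = tau_ms, constants = constants),
            class = c("perfusion_map", "map_fit"))
}
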