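#' Default ground-truth tissue parameter table
#'
#' Per-tissue truth values for the digital kidney phantom, typical of human
#' kidney at 3T: cortex T1 below medulla T1, cortex perfusion well above
#' medulla, ADC around 2e-3 mm^2/s.  `att_ms` is the arterial transit time and
#' `tau_ms` the labelled-bolus duration of the pulsed-ASL kinetic model.
#'
#' @return tibble with one row per tissue (cortex, medulla).
#' @export
default_tissue_truth <- function() {
  tibble(
    tissue = c("cortex", "medulla"),
    t1_ms = c(1500, 1900),
    m0 = c(100, 100),
    adc_mm2_s = c(2.2e-3, 2.0e-3),
    t2star_ms = c(55, 40),
    perfusion = c(250, 100),    # mL/100g/min
    att_ms = c(500, 700),
    tau_ms = c(800, 800)
  )
}

#' Default intra-tissue parameter dispersion
#'
#' Standard deviations of the voxelwise truth draws around the tissue means.
#' @return named numeric vector, same parameter names as
#'   [default_tissue_truth()].
#' @export
default_tissue_sd <- function() {
  c(t1_ms = 50, m0 = 5, adc_mm2_s = 1e-4, t2star_ms = 3,
    perfusion = 20, att_ms = 0, tau_ms = 0)
}

#' Specify a digital kidney phantom
#'
#' The phantom is two ellipsoidal "kidneys" on a 3D grid, each with an outer
#' cortical shell around an inner medullary core.  Every in-kidney voxel is
#' assigned ground-truth parameters drawn from the per-tissue table with
#' intra-tissue Gaussian dispersion; the same spec + seed always reproduces
#' the identical phantom.
#'
#' @param grid integer length-3 grid shape in voxels (all dims >= 8).
#' @param voxel_mm voxel size in mm; default 3 x 3 x 5 (coarse renal protocol
#'   resolution).
#' @param tissues ground-truth parameter table, see [default_tissue_truth()].
#' @param tissue_sd intra-tissue SDs, see [default_tissue_sd()].
#' @param noise_sd acquisition noise SD as a fraction of the mean in-kidney M0.
#' @param noise_model "gaussian" (default) or "rician".
#' @param medulla_scale linear scale of the inner medullary ellipsoid relative
#'   to the kidney ellipsoid.
#' @param seed RNG seed fixing all phantom randomness.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = c(40, 40, 12), voxel_mm = c(3, 3, 5),
                         tissues = default_tissue_truth(),
                         tissue_sd = default_tissue_sd(),
                         noise_sd = 0.02, noise_model = "gaussian",
                         medulla_scale = 0.6, seed = 42) {
  stopifnot(length(grid) == 3, noise_sd >= 0, length(voxel_mm) == 3,
            all(voxel_mm > 0), medulla_scale > 0, medulla_scale < 1)
  params <- setdiff(names(tissues), "tissue")
  if (any(tissues[params] <= 0))
    abort("all tissue ground-truth parameters must be > 0")
  structure(list(grid = as.integer(grid), voxel_mm = as.numeric(voxel_mm),
                 tissues = tissues, tissue_sd = tissue_sd,
                 noise_sd = noise_sd, noise_model = noise_model,
                 medulla_scale = medulla_scale, seed = seed),
            class = "phantom_spec")
}

# Logical array of voxels whose centres fall inside an axis-aligned ellipsoid.
ellipsoid_mask <- function(grid, centre, semi) {
  i <- slice.index(array(0, grid), 1)
  j <- slice.index(array(0, grid), 2)
  k <- slice.index(array(0, grid), 3)
  ((i - centre[1]) / semi[1])^2 + ((j - centre[2]) / semi[2])^2 +
    ((k - centre[3]) / semi[3])^2 <= 1
}

# Kidney geometry in voxel units for a given grid: two ellipsoids placed
# symmetrically about the mid-sagittal plane.
phantom_geometry <- function(grid, medulla_scale) {
  semi <- c(0.18, 0.28, 0.38) * grid
  c1 <- c(0.28, 0.5, 0.54) * grid + 0.5
  c2 <- c(0.72, 0.5, 0.54) * grid + 0.5
  list(left = list(centre = c1, semi = semi),
       right = list(centre = c2, semi = semi),
       medulla_scale = medulla_scale)
}

#' Build the digital kidney phantom
#'
#' Realises the masks and voxelwise ground-truth parameter maps of a
#' [phantom_spec()].  Background voxels have all parameters 0.
#'
#' @param spec a [phantom_spec()].
#' @return Object of class `kidney_phantom`: `masks` (a [tissue_masks()] plus
#'   `left`/`right` kidney arrays), `truth` (named list of 3D arrays, one per
#'   parameter), and the spec.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(spec$grid < 8))
    abort("degenerate grid: all dimensions must be >= 8 voxels")
  g <- spec$grid
  geo <- phantom_geometry(g, spec$medulla_scale)
  left <- ellipsoid_mask(g, geo$left$centre, geo$left$semi)
  right <- ellipsoid_mask(g, geo$right$centre, geo$right$semi)
  kidney <- left | right
  med <- ellipsoid_mask(g, geo$left$centre, geo$left$semi * spec$medulla_scale) |
    ellipsoid_mask(g, geo$right$centre, geo$right$semi * spec$medulla_scale)
  medulla <- kidney & med
  cortex <- kidney & !medulla
  params <- setdiff(names(spec$tissues), "tissue")
  truth <- with_local_seed(spec$seed, {
    out <- lapply(params, function(p) {
      arr <- array(0, g)
      for (tis in spec$tissues$tissue) {
        m <- if (tis == "cortex") cortex else medulla
        mu <- spec$tissues[[p]][spec$tissues$tissue == tis]
        sdv <- spec$tissue_sd[[p]]
        arr[m] <- rnorm(sum(m), mu, sdv)
      }
      arr
    })
    names(out) <- params
    out
  })
  masks <- tissue_masks(kidney, cortex, medulla, spec$voxel_mm)
  masks$left <- left
  masks$right <- right
  structure(list(masks = masks, truth = truth, spec = spec),
            class = "kidney_phantom")
}

#' @export
print.kidney_phantom <- function(x, ...) {
  cat(sprintf("<kidney_phantom: %s grid, %d kidney voxels (%d cortex, %d medulla)>\n",
              paste(x$spec$grid, collapse = "x"), sum(x$masks$kidney),
              sum(x$masks$cortex), sum(x$masks$medulla)))
  invisible(x)
}

# Absolute noise SD for a phantom: fraction-of-M0 spec times mean in-kidney M0.
phantom_noise_sd <- function(phantom, noise_sd) {
  if (is.null(noise_sd)) noise_sd <- phantom$spec$noise_sd
  noise_sd * mean(phantom$truth$m0[phantom$masks$kidney])
}

#' Simulate an inversion-recovery T1 mapping series
#'
#' Magnitude signal `|M0 (1 - 2 eps exp(-TI/T1))|` per voxel at each inversion
#' time, plus acquisition noise.  The default TI grid is the 13-point renal
#' protocol (200-1300 ms in 100 ms steps, then 1500 ms).
#'
#' @param phantom a [make_phantom()] result.
#' @param ti_ms inversion times in ms (all > 0).
#' @param epsilon inversion efficiency in (0, 1].
#' @param noise_sd noise SD as fraction of mean in-kidney M0; `NULL` uses the
#'   phantom spec value; 0 gives noiseless data.
#' @param seed optional local RNG seed for the noise draw.
#' @return an [acquisition_series()] with `modality = "ir"`.
#' @export
simulate_ir_series <- function(phantom, ti_ms = default_ti_ms(), epsilon = 1,
                               noise_sd = NULL, seed = NULL) {
  stopifnot(all(ti_ms > 0), epsilon > 0, epsilon <= 1)
  t1 <- phantom$truth$t1_ms
  m0 <- phantom$truth$m0
  sig <- vapply(ti_ms, function(ti) {
    s <- array(0, dim(t1))
    ok <- t1 > 0
    s[ok] <- abs(m0[ok] * (1 - 2 * epsilon * exp(-ti / t1[ok])))
    s
  }, FUN.VALUE = t1)
  with_local_seed(seed, {
    sig[] <- add_noise(sig, phantom_noise_sd(phantom, noise_sd),
                       phantom$spec$noise_model)
  })
  acquisition_series(sig, tibble(ti_ms = ti_ms), phantom$spec$voxel_mm, "ir")
}

#' Default acquisition protocol grids
#'
#' The renal multiparametric protocol: 13 inversion times, 11 b-values in
#' three orthogonal directions, 12 gradient echoes (TE 5 ms, spacing 3 ms),
#' and post-label delays 300/500/700/900 ms (4 pairs each) + 1800 ms
#' (25 pairs).
#' @name default_protocol
NULL

#' @rdname default_protocol
#' @export
default_ti_ms <- function() c(seq(200, 1300, by = 100), 1500)

#' @rdname default_protocol
#' @export
default_b_values <- function() c(0, 5, 10, 20, 30, 50, 100, 200, 300, 400, 500)

#' @rdname default_protocol
#' @export
default_te_ms <- function() seq(5, by = 3, length.out = 12)

#' @rdname default_protocol
#' @export
default_pld_ms <- function() c(300, 500, 700, 900, 1800)

#' @rdname default_protocol
#' @export
default_asl_pairs <- function() c(4, 4, 4, 4, 25)

#' Simulate a multi-b, multi-direction diffusion series
#'
#' Per voxel and direction `S0 exp(-b ADC)` plus noise; the truth is isotropic
#' unless `direction_scale` supplies per-direction multipliers of the ADC
#' truth (used to exercise the anisotropy-averaging behaviour).
#'
#' @inheritParams simulate_ir_series
#' @param b_values b-values in s/mm^2.
#' @param n_directions number of orthogonal diffusion directions.
#' @param direction_scale optional numeric vector (length `n_directions`) of
#'   per-direction ADC multipliers; default all 1 (isotropic).
#' @return an [acquisition_series()] with `modality = "dwi"`.
#' @export
simulate_dwi_series <- function(phantom, b_values = default_b_values(),
                                n_directions = 3, direction_scale = NULL,
                                noise_sd = NULL, seed = NULL) {
  stopifnot(all(b_values >= 0), n_directions >= 1)
  if (is.null(direction_scale)) direction_scale <- rep(1, n_directions)
  stopifnot(length(direction_scale) == n_directions)
  adc <- phantom$truth$adc_mm2_s
  m0 <- phantom$truth$m0
  params <- tidyr::expand_grid(b_s_mm2 = b_values,
                               direction = seq_len(n_directions))
  sig <- vapply(seq_len(nrow(params)), function(i) {
    m0 * exp(-params$b_s_mm2[i] * adc * direction_scale[params$direction[i]])
  }, FUN.VALUE = adc)
  with_local_seed(seed, {
    sig[] <- add_noise(sig, phantom_noise_sd(phantom, noise_sd),
                       phantom$spec$noise_model)
  })
  acquisition_series(sig, params, phantom$spec$voxel_mm, "dwi")
}

#' Simulate a multi-echo gradient-echo T2* series
#'
#' `S0 exp(-TE/T2*)` plus noise at each echo time.
#'
#' @inheritParams simulate_ir_series
#' @param te_ms echo times in ms (at least 3).
#' @return an [acquisition_series()] with `modality = "mfe"`.
#' @export
simulate_mfe_series <- function(phantom, te_ms = default_te_ms(),
                                noise_sd = NULL, seed = NULL) {
  if (length(te_ms) < 3)
    abort("T2* decay is under-determined with fewer than 3 echoes")
  stopifnot(all(te_ms > 0))
  t2s <- phantom$truth$t2star_ms
  m0 <- phantom$truth$m0
  sig <- vapply(te_ms, function(te) {
    s <- array(0, dim(t2s))
    ok <- t2s > 0
    s[ok] <- m0[ok] * exp(-te / t2s[ok])
    s
  }, FUN.VALUE = t2s)
  with_local_seed(seed, {
    sig[] <- add_noise(sig, phantom_noise_sd(phantom, noise_sd),
                       phantom$spec$noise_model)
  })
  acquisition_series(sig, tibble(te_ms = te_ms), phantom$spec$voxel_mm, "mfe")
}

#' Simulate FAIR ASL selective/non-selective pairs
#'
#' Emits, for each post-label delay, `pairs` selective (S) and non-selective
#' (NS) volumes whose noiseless difference follows the pulsed-ASL kinetic
#' model ([asl_signal()]) at the voxel's true perfusion, transit time and
#' bolus duration, together with the base M0 volume.  The static tissue
#' background of both members of a pair is `background_frac * M0`.
#'
#' @inheritParams simulate_ir_series
#' @param pld_ms post-label delays in ms.
#' @param pairs number of S/NS pairs per delay (recycled to `length(pld_ms)`).
#' @param constants an [asl_constants()] list.
#' @param background_frac static background signal as a fraction of M0.
#' @return an [acquisition_series()] with `modality = "asl"` and an `m0`
#'   volume.
#' @export
simulate_asl_pairs <- function(phantom, pld_ms = default_pld_ms(),
                               pairs = default_asl_pairs(),
                               constants = asl_constants(),
                               background_frac = 0.1,
                               noise_sd = NULL, seed = NULL) {
  stopifnot(all(pld_ms > 0), all(pairs >= 1))
  pairs <- rep_len(pairs, length(pld_ms))
  tr <- phantom$truth
  base <- background_frac * tr$m0
  dm <- lapply(pld_ms, function(t)
    asl_signal(tr$perfusion, tr$att_ms, tr$tau_ms, t, tr$m0, tr$t1_ms,
               constants))
  params <- purrr::map2(pld_ms, pairs, function(p, np)
    tibble(pld_ms = p, pair = rep(seq_len(np), each = 2),
           label = rep(c("S", "NS"), np))) %>% list_rbind()
  sig <- vapply(seq_len(nrow(params)), function(i) {
    k <- match(params$pld_ms[i], pld_ms)
    if (params$label[i] == "S") base + dm[[k]] else base
  }, FUN.VALUE = base)
  with_local_seed(seed, {
    sig[] <- add_noise(sig, phantom_noise_sd(phantom, noise_sd),
                       phantom$spec$noise_model)
  })
  acquisition_series(sig, params, phantom$spec$voxel_mm, "asl", m0 = tr$m0)
}
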