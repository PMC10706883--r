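#' Acquisition series container
#'
#' Bundles a 4D voxel array (x, y, z, volume) with the per-volume acquisition
#' parameter table and voxel geometry.  The parameter table has one row per
#' volume along the 4th dimension: `ti_ms` for inversion recovery, `b_s_mm2` +
#' `direction` for diffusion, `te_ms` for multi-echo gradient echo, and
#' `label` ("S"/"NS") + `pld_ms` + `pair` for ASL.
#'
#' @param data 4D numeric array, 4th dimension indexes acquired volumes.
#' @param params tibble with one row per volume.
#' @param voxel_mm numeric length-3 voxel size in mm.
#' @param modality one of "ir", "dwi", "mfe", "asl".
#' @param m0 optional 3D base M0 volume (ASL only).
#' @return An object of class `acquisition_series`.
#' @export
acquisition_series <- function(data, params, voxel_mm, modality, m0 = NULL) {
  stopifnot(length(dim(data)) == 4, nrow(params) == dim(data)[4],
            length(voxel_mm) == 3, all(voxel_mm > 0))
  structure(list(data = data, params = as_tibble(params),
                 voxel_mm = as.numeric(voxel_mm), modality = modality, m0 = m0),
            class = "acquisition_series")
}

#' @export
print.acquisition_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<acquisition_series: %s, %dx%dx%d voxels, %d volumes, voxel %s mm>\n",
              x$modality, d[1], d[2], d[3], d[4],
              paste(x$voxel_mm, collapse = "x")))
  invisible(x)
}

#' @export
tidy.acquisition_series <- function(x, ...) {
  x$params %>% mutate(volume = seq_len(nrow(x$params)), .before = 1)
}

# Additive noise on the simulated magnitude signal.  `sd_abs` is the absolute
# noise SD (already scaled from the fraction-of-M0 specification).  The
# Rician option forms sqrt((S + n1)^2 + n2^2), the magnitude of a complex
# signal with independent Gaussian channel noise.
add_noise <- function(signal, sd_abs, model = c("gaussian", "rician")) {
  model <- match.arg(model)
  if (sd_abs == 0) return(signal)
  n <- length(signal)
  if (model == "gaussian") {
    signal + rnorm(n, 0, sd_abs)
  } else {
    sqrt((signal + rnorm(n, 0, sd_abs))^2 + rnorm(n, 0, sd_abs)^2)
  }
}

#' Write / read an acquisition series as NIfTI + JSON sidecar
#'
#' The 4D data go to `<prefix>.nii.gz`; the sidecar `<prefix>.json` carries the
#' per-volume acquisition vectors, modality, units and voxel size, and an ASL
#' series additionally writes `<prefix>_m0.nii.gz`.
#'
#' @param series an [acquisition_series()].
#' @param prefix file path prefix (no extension).
#' @return `write_series()` returns the prefix invisibly; `read_series()`
#'   returns the reconstructed [acquisition_series()].
#' @export
write_series <- function(series, prefix) {
  img <- RNifti::asNifti(series$data, pixdim = c(series$voxel_mm, 1))
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  if (!is.null(series$m0))
    RNifti::writeNifti(RNifti::asNifti(series$m0, pixdim = series$voxel_mm),
                       paste0(prefix, "_m0.nii.gz"))
  sidecar <- list(modality = series$modality,
                  voxel_mm = series$voxel_mm,
                  units = switch(series$modality,
                                 ir = "ti_ms", dwi = "b_s_mm2", mfe = "te_ms",
                                 asl = "pld_ms", "index"),
                  volumes = series$params)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_series
#' @export
read_series <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  data <- array(as.numeric(RNifti::readNifti(paste0(prefix, ".nii.gz"))),
                dim = dim(RNifti::readNifti(paste0(prefix, ".nii.gz"))))
  m0path <- paste0(prefix, "_m0.nii.gz")
  m0 <- if (file.exists(m0path)) {
    v <- RNifti::readNifti(m0path)
    array(as.numeric(v), dim = dim(v))
  }
  acquisition_series(data, as_tibble(sidecar$volumes),
                     as.numeric(sidecar$voxel_mm), sidecar$modality, m0 = m0)
}

#' Write a 3D parameter map to NIfTI
#'
#' @param map 3D numeric array.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param voxel_mm voxel size in mm.
#' @param unit unit string recorded in a JSON sidecar next to the volume.
#' @export
write_map <- function(map, path, voxel_mm, unit = "") {
  RNifti::writeNifti(RNifti::asNifti(map, pixdim = voxel_mm), path)
  jsonlite::write_json(list(unit = unit, voxel_mm = voxel_mm),
                       sub("\\.nii(\\.gz)?$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
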