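#' Native-cartilage attenuation baseline
#'
#' Non-contrast-enhanced cartilage attenuates X-rays at 1.05 x the attenuation
#' of water. On the Hounsfield scale (water = 0, slope 1000 per mu_w) that is
#' `water_hu + 50`; on the linear-attenuation (mu) scale it is `1.05 * mu`.
#'
#' @param water_hu measured water attenuation (HU by default).
#' @param scale `"hu"` or `"mu"`.
#' @return The native-cartilage baseline on the same scale.
#' @export
native_baseline <- function(water_hu, scale = c("hu", "mu")) {
  scale <- match.arg(scale)
  stopifnot(is.finite(water_hu))
  if (scale == "mu") 1.05 * water_hu else water_hu + 50
}

#' Bath ioxaglate attenuation
#'
#' The BiNP suspension's own attenuation is subtracted from the dual-contrast
#' joint-cavity attenuation to obtain the attenuation of plain ioxaglate in
#' the cavity — the denominator of the partition.
#'
#' @param dual_bath_hu joint-cavity attenuation at t = 60 (HU).
#' @param binp_hu BiNP suspension attenuation (HU).
#' @return `dual_bath_hu - binp_hu`; an error if the result is not positive
#'   (the partition would be undefined).
#' @export
iox_bath_attenuation <- function(dual_bath_hu, binp_hu) {
  stopifnot(is.finite(dual_bath_hu), is.finite(binp_hu))
  out <- dual_bath_hu - binp_hu
  if (out <= 0) {
    stop("bath ioxaglate attenuation must be positive (degenerate partition denominator)",
         call. = FALSE)
  }
  out
}

#' Phantom calibration
#'
#' Bundles the reference attenuations the partition formula needs: the water
#' and BiNP phantom means, the joint-cavity (dual-bath) mean at t = 60, and
#' the derived bath-ioxaglate and native-cartilage values.
#'
#' @param water_hu water-phantom mean (HU).
#' @param binp_hu BiNP-phantom mean (HU).
#' @param dual_bath_hu joint-cavity mean at t = 60 (HU).
#' @param n_voxels,sd_hu optional provenance of the cavity measurement.
#' @return A list of class `phantom_calibration` with fields `water_hu`,
#'   `binp_hu`, `dual_bath_hu`, `iox_bath_hu`, `native_cartilage_hu`,
#'   `n_voxels`, `sd_hu`.
#' @export
phantom_calibration <- function(water_hu = 0, binp_hu = 0, dual_bath_hu = 1667,
                                n_voxels = NA_integer_, sd_hu = NA_real_) {
  structure(
    list(
      water_hu = water_hu, binp_hu = binp_hu, dual_bath_hu = dual_bath_hu,
      iox_bath_hu = iox_bath_attenuation(dual_bath_hu, binp_hu),
      native_cartilage_hu = native_baseline(water_hu),
      n_voxels = n_voxels, sd_hu = sd_hu
    ),
    class = "phantom_calibration"
  )
}

#' @export
print.phantom_calibration <- function(x, ...) {
  cat(sprintf(
    "<phantom_calibration> water %.1f, BiNP %.1f, dual bath %.1f HU\n  iox bath %.1f HU, native cartilage %.1f HU\n",
    x$water_hu, x$binp_hu, x$dual_bath_hu, x$iox_bath_hu, x$native_cartilage_hu
  ))
  invisible(x)
}

#' Calibrate from phantom scans and a cavity measurement
#'
#' Measures the water and BiNP tubes over their central cores (60 % of the
#' tube radius, excluding partial-volume rims) and combines them with the
#' joint-cavity attenuation into a [phantom_calibration()].
#'
#' @param scans a `phantom_scans` object from [make_phantom_scans()].
#' @param dual_bath_hu joint-cavity mean at t = 60 (HU), e.g. from
#'   [measure_mask_mean()] over a [cavity_roi()].
#' @return A `phantom_calibration`.
#' @export
calibrate_phantoms <- function(scans, dual_bath_hu) {
  stopifnot(inherits(scans, "phantom_scans"))
  w <- measure_mask_mean(scans$water, scans$core_mask)
  b <- measure_mask_mean(scans$binp, scans$core_mask)
  phantom_calibration(
    water_hu = w$mean_hu, binp_hu = b$mean_hu, dual_bath_hu = dual_bath_hu,
    n_voxels = w$n_voxels, sd_hu = w$sd_hu
  )
}

#' Provisional bath estimate from the volume top
#'
#' Before any segmentation exists, the dual-bath attenuation is estimated as
#' the median of the top 0.4 mm of the volume, which the scan geometry
#' guarantees to be joint cavity; voxels below -300 HU (air bubbles) are
#' ignored. Used to seed surface detection, after which the bath is re-measured
#' over the detected cavity.
#'
#' @param volume an [attenuation_volume()] at t = 60.
#' @param depth_mm slab thickness to sample (default 0.4).
#' @return Median attenuation (HU).
#' @export
estimate_bath_hu <- function(volume, depth_mm = 0.4) {
  stopifnot(is_volume(volume))
  k <- max(1L, floor(depth_mm / (volume$voxel_size_um[1] / 1000)))
  v <- volume$voxels[seq_len(k), , , drop = FALSE]
  stats::median(v[v > -300])
}

#' Read / write calibrations as JSON
#'
#' @param cal a `phantom_calibration`.
#' @param path JSON file path.
#' @export
write_calibration <- function(cal, path) {
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  phantom_calibration(x$water_hu, x$binp_hu, x$dual_bath_hu,
                      n_voxels = x$n_voxels %||% NA_integer_,
                      sd_hu = x$sd_hu %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
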