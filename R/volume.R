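#' Attenuation volume
#'
#' Light container for a 3-D grid of X-ray attenuation in Hounsfield units
#' (HU; water = 0, HU = 1000 (mu - mu_w) / mu_w). Axis order is fixed as
#' (depth, dorsopalmar, lateromedial), with the depth axis oriented from the
#' joint cavity towards the subchondral bone. Voxel sizes are per-axis so that
#' derived volumes (e.g. after slab averaging along one axis) remain valid.
#'
#' @param voxels numeric 3-D array of attenuations (HU); all values finite.
#' @param voxel_size_um voxel edge length(s) in micrometres; scalar or length 3,
#'   recycled to the three axes. Default 80.
#' @param timepoint_min acquisition time point in minutes after contrast-agent
#'   injection, usually 0 or 60.
#' @param meta free-form named list of scan metadata (kV, mAs, ...).
#'
#' @return An object of class `attenuation_volume`.
#' @export
attenuation_volume <- function(voxels, voxel_size_um = 80, timepoint_min = 60,
                               meta = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3-D array", call. = FALSE)
  }
  if (!all(is.finite(voxels))) stop("attenuations must be finite", call. = FALSE)
  voxel_size_um <- rep_len(as.numeric(voxel_size_um), 3L)
  if (any(voxel_size_um <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  if (any(dim(voxels) < 2L)) stop("each dimension needs at least 2 voxels", call. = FALSE)
  structure(
    list(
      voxels = voxels,
      voxel_size_um = voxel_size_um,
      axes = c("depth", "dorsopalmar", "lateromedial"),
      timepoint_min = timepoint_min,
      meta = meta
    ),
    class = "attenuation_volume"
  )
}

#' @export
print.attenuation_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<attenuation_volume> %d x %d x %d voxels (%s), %s um, t = %s min\n",
    d[1], d[2], d[3], paste(x$axes, collapse = " x "),
    paste(signif(x$voxel_size_um, 4), collapse = " x "), x$timepoint_min
  ))
  cat(sprintf("  HU range [%.0f, %.0f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.attenuation_volume <- function(x) dim(x$voxels)

is_volume <- function(x) inherits(x, "attenuation_volume")

#' Mean attenuation over a mask
#'
#' Arithmetic mean (plus SD and voxel count) of the attenuation over a logical
#' mask, the elementary measurement behind all phantom and bath calibrations.
#'
#' @param volume an [attenuation_volume()].
#' @param mask logical array with the volume's dimensions (or a vector of voxel
#'   indices).
#' @return A one-row tibble with columns `mean_hu`, `sd_hu`, `n_voxels`.
#' @export
measure_mask_mean <- function(volume, mask) {
  stopifnot(is_volume(volume))
  if (is.logical(mask)) {
    if (!identical(dim(mask), dim(volume$voxels))) {
      stop("mask dimensions must match the volume", call. = FALSE)
    }
    idx <- which(mask)
  } else {
    idx <- as.integer(mask)
    if (length(idx) && (min(idx) < 1L || max(idx) > length(volume$voxels))) {
      stop("mask indices outside the volume", call. = FALSE)
    }
  }
  if (length(idx) == 0L) stop("empty mask", call. = FALSE)
  v <- volume$voxels[idx]
  tibble::tibble(
    mean_hu = mean(v),
    sd_hu = stats::sd(v),
    n_voxels = length(idx)
  )
}

#' Average consecutive slices into slabs
#'
#' Replaces non-overlapping groups of `n` consecutive slices along one axis by
#' their mean, emulating the noise-reduction step in which analysis images are
#' the average of six consecutive 80 um slices (slab thickness 0.48 mm). A
#' trailing remainder of fewer than `n` slices is dropped with a message.
#'
#' @param volume an [attenuation_volume()].
#' @param n slices per slab (default 6).
#' @param axis axis to average along (1-3); default 3, the lateromedial
#'   (along-groove) axis, so slabs are coronal.
#' @return An `attenuation_volume` of slab means with the averaged axis's voxel
#'   size multiplied by `n`.
#' @export
average_slices <- function(volume, n = 6, axis = 3) {
  stopifnot(is_volume(volume))
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("`n` must be a positive integer", call. = FALSE)
  axis <- as.integer(axis)
  stopifnot(axis %in% 1:3)
  d <- dim(volume$voxels)
  if (d[axis] < n) stop("fewer slices than the slab size along that axis", call. = FALSE)
  if (n == 1L) return(volume)
  k <- d[axis] %/% n
  dropped <- d[axis] - k * n
  if (dropped > 0L) {
    message(sprintf("average_slices: dropping %d trailing slice(s) along axis %d",
                    dropped, axis))
  }
  # move target axis last, reshape to (other, n, k) and mean over n
  perm <- c(setdiff(1:3, axis), axis)
  a <- aperm(volume$voxels, perm)
  da <- dim(a)
  a <- a[, , seq_len(k * n), drop = FALSE]
  dim(a) <- c(da[1] * da[2], n, k)
  m <- colMeans(aperm(a, c(2, 1, 3)))  # (da1*da2, k)
  dim(m) <- c(da[1], da[2], k)
  out <- aperm(m, order(perm))
  vs <- volume$voxel_size_um
  vs[axis] <- vs[axis] * n
  attenuation_volume(out, voxel_size_um = vs,
                     timepoint_min = volume$timepoint_min, meta = volume$meta)
}
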