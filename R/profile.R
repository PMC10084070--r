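#' Extract per-column attenuation profiles from a VOI
#'
#' Each VOI column is clipped to its half-open cartilage span
#' `[surface_idx, interface_idx)`; groove-void voxels lie above the detected
#' surface and are therefore excluded automatically. Columns whose surface or
#' interface is flagged are dropped and counted; fewer than 80 % usable
#' columns is an error. A partial-volume guard trims leading samples that
#' exceed the next sample by more than `guard_hu` — a bright first sample is a
#' cavity-contaminated boundary voxel, not cartilage.
#'
#' @param volume slab-averaged t = 60 [attenuation_volume()].
#' @param voi a `voi_spec` row from [place_vois()].
#' @param maps the `surface_maps` for the same grid.
#' @param guard_hu surface partial-volume guard (default 150 HU;
#'   ~9 noise SDs after 6-slice averaging).
#' @return List of class `voi_columns`: `columns` (list of numeric vectors),
#'   `n_dropped`, `role`.
#' @export
extract_columns <- function(volume, voi, maps, guard_hu = 150) {
  stopifnot(is_volume(volume), inherits(voi, "voi_spec"))
  ys <- voi$cols_dorsopalmar[[1]]
  xs <- voi$cols_lateromedial[[1]]
  cols <- list()
  n_dropped <- 0L
  for (x in xs) {
    for (y in ys) {
      if (isTRUE(maps$flagged[y, x])) { n_dropped <- n_dropped + 1L; next }
      s <- maps$surface_idx[y, x]; i <- maps$interface_idx[y, x]
      if (is.na(s) || is.na(i) || i <= s) { n_dropped <- n_dropped + 1L; next }
      v <- volume$voxels[s:(i - 1L), y, x]
      while (length(v) > 2 && v[1] > v[2] + guard_hu) v <- v[-1]
      cols[[length(cols) + 1L]] <- v
    }
  }
  total <- length(xs) * length(ys)
  if (length(cols) < 0.8 * total) {
    stop(sprintf("VOI '%s': only %d of %d columns usable (< 80%%)",
                 voi$role, length(cols), total), call. = FALSE)
  }
  structure(list(columns = cols, n_dropped = n_dropped, role = voi$role),
            class = "voi_columns")
}

#' Resample columns onto a common normalized depth grid
#'
#' Removes the natural curvature of the surface and interface by linearly
#' interpolating every attenuation (or OD) column onto `n_points` equally
#' spaced positions spanning normalized depth \[0, 1\] (0 = articulating
#' surface, 1 = cartilage-bone interface). Endpoint values are preserved;
#' single-sample columns cannot be resampled and are dropped with a warning.
#'
#' @param columns list of numeric vectors (or a `voi_columns`).
#' @param n_points number of depth positions (default 100).
#' @return Numeric matrix `n_points x n_columns`.
#' @export
normalize_depth <- function(columns, n_points = 100) {
  if (inherits(columns, "voi_columns")) columns <- columns$columns
  stopifnot(n_points >= 2)
  keep <- lengths(columns) >= 2
  if (any(!keep)) {
    warning(sprintf("dropping %d single-sample column(s)", sum(!keep)))
    columns <- columns[keep]
  }
  if (!length(columns)) stop("no resamplable columns", call. = FALSE)
  grid <- seq(0, 1, length.out = n_points)
  vapply(columns, function(v) {
    stats::approx(seq(0, 1, length.out = length(v)), v, xout = grid)$y
  }, numeric(n_points))
}

#' Average resampled columns into one depth profile
#'
#' Position-wise mean and SD over the VOI's columns — one profile over the
#' full thickness of the hyaline cartilage layer.
#'
#' @param columns matrix from [normalize_depth()] (or a list of equal-length
#'   columns).
#' @param kind value kind: `"attenuation_hu"`, `"partition_pct"` or `"od"`.
#' @return A `depth_profile` tibble: `depth`, `value`, `sd`, with attributes
#'   `n_columns` and `kind`.
#' @export
mean_profile <- function(columns, kind = "attenuation_hu") {
  if (is.list(columns)) columns <- do.call(cbind, columns)
  stopifnot(is.matrix(columns), ncol(columns) >= 1)
  out <- tibble::tibble(
    depth = seq(0, 1, length.out = nrow(columns)),
    value = rowMeans(columns),
    sd = apply(columns, 1, stats::sd)
  )
  if (ncol(columns) == 1L) out$sd <- 0
  new_depth_profile(out, n_columns = ncol(columns), kind = kind)
}

new_depth_profile <- function(df, n_columns, kind) {
  structure(df, n_columns = n_columns, kind = kind,
            class = c("depth_profile", class(tibble::tibble())))
}

#' Convert an attenuation profile to an ioxaglate-partition profile
#'
#' The estimated native (non-contrast-enhanced) cartilage attenuation is
#' subtracted from the acquired attenuation profile, and the remainder is
#' expressed relative to the bath ioxaglate attenuation:
#' `partition(z) = 100 * (A(z) - native) / iox_bath` (percent). Values are
#' reported as-is; values outside \[0, 100\] are flagged with a message, not
#' clipped.
#'
#' @param profile a `depth_profile` of attenuations (HU).
#' @param cal a [phantom_calibration()] with `iox_bath_hu > 0`.
#' @return A `depth_profile` with `kind = "partition_pct"`.
#' @export
attenuation_to_partition <- function(profile, cal) {
  stopifnot(inherits(profile, "depth_profile"))
  if (!is.finite(cal$iox_bath_hu) || cal$iox_bath_hu <= 0) {
    stop("bath ioxaglate attenuation must be positive", call. = FALSE)
  }
  out <- profile
  out$value <- 100 * (profile$value - cal$native_cartilage_hu) / cal$iox_bath_hu
  out$sd <- 100 * profile$sd / cal$iox_bath_hu
  n_out <- sum(out$value < 0 | out$value > 100)
  if (n_out > 0) {
    message(sprintf("%d of %d partition values outside [0, 100]%%", n_out, nrow(out)))
  }
  new_depth_profile(out, attr(profile, "n_columns"), "partition_pct")
}

#' Full-thickness mean of a depth profile
#'
#' Unweighted mean over the equally spaced normalized-depth positions (equal
#' depth weighting, matching the normalized-profile representation).
#'
#' @param profile a `depth_profile`.
#' @return Scalar mean (percent for partition profiles).
#' @export
full_thickness_mean <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  mean(profile$value)
}

#' Depth profile and full-thickness partition for one VOI
#'
#' Convenience chain: [extract_columns()] -> [normalize_depth()] ->
#' [mean_profile()] -> [attenuation_to_partition()].
#'
#' @inheritParams extract_columns
#' @param cal a [phantom_calibration()].
#' @param n_points resampling positions (default 100).
#' @return List: `profile` (partition `depth_profile`),
#'   `mean_partition_pct`, `n_columns`.
#' @export
voi_partition <- function(volume, voi, maps, cal, n_points = 100) {
  cols <- extract_columns(volume, voi, maps)
  mat <- normalize_depth(cols, n_points)
  prof <- attenuation_to_partition(mean_profile(mat), cal)
  list(profile = prof,
       mean_partition_pct = full_thickness_mean(prof),
       n_columns = ncol(mat))
}
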