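# centred moving average with edge windows shrunk to the available samples
moving_avg <- function(x, window = 5) {
  if (window <= 1 || length(x) < 2) return(x)
  half <- window %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect the articulating surface
#'
#' The BiNP-laden joint cavity is markedly brighter than even fully
#' contrast-enhanced cartilage, so the surface is found per depth column
#' (cavity to bone) as the first crossing below the midpoint threshold
#' `(dual_bath_hu + expected_cartilage_hu) / 2` after 1-D smoothing, with two
#' consecutive sub-threshold samples required so single noise outliers cannot
#' trigger a crossing. The detected map follows groove floors. Columns with no
#' crossing (e.g. cavity and cartilage equally attenuating) are flagged `NA`.
#'
#' @param volume an [attenuation_volume()] at t = 60 (possibly slab-averaged).
#' @param cal a [phantom_calibration()] supplying `dual_bath_hu`,
#'   `native_cartilage_hu` and `iox_bath_hu`.
#' @param expected_cartilage_hu attenuation assumed for cartilage at the
#'   articulating surface; default `native + 0.85 * iox_bath`, an upper bound
#'   for near-equilibrated superficial tissue.
#' @param smooth_window depth smoothing window (samples, default 3).
#' @return Integer matrix (dorsopalmar x lateromedial) of surface depth
#'   indices, `NA` where undefined.
#' @export
detect_surface <- function(volume, cal, expected_cartilage_hu = NULL,
                           smooth_window = 3) {
  stopifnot(is_volume(volume))
  if (is.null(expected_cartilage_hu)) {
    expected_cartilage_hu <- cal$native_cartilage_hu + 0.85 * cal$iox_bath_hu
  }
  thr <- (cal$dual_bath_hu + expected_cartilage_hu) / 2
  if (thr >= cal$dual_bath_hu) {
    return(matrix(NA_integer_, dim(volume$voxels)[2], dim(volume$voxels)[3]))
  }
  d <- dim(volume$voxels)
  out <- matrix(NA_integer_, d[2], d[3])
  for (x in seq_len(d[3])) {
    sl <- volume$voxels[, , x]
    for (y in seq_len(d[2])) {
      raw <- sl[, y]
      p <- moving_avg(raw, smooth_window)
      below <- p < thr
      k <- which(below[-d[1]] & below[-1])
      if (length(k)) {
        # refine against the raw profile: smoothing can pull the crossing one
        # voxel into the cavity
        k0 <- max(k[1] - 1L, 1L)
        kr <- which(raw[k0:d[1]] < thr)
        out[y, x] <- if (length(kr)) k0 + kr[1] - 1L else k[1]
      }
    }
  }
  out
}

#' Detect the cartilage-bone interface in one depth profile
#'
#' The interface is taken at the null point of the first derivative: the
#' local attenuation minimum preceding the rise into (bright) subchondral
#' bone, searched below the detected surface. Multiple null points are
#' tie-broken by the greatest subsequent rise, which on these profiles always
#' selects the deep-cartilage minimum (the rise into bone dwarfs noise dips).
#' The returned index is the first sample past the minimum, so the half-open
#' cartilage span `[surface, interface)` excludes bone-contaminated samples.
#' The derivative is taken on the raw profile by default: slab averaging has
#' already suppressed the noise, and depth smoothing shifts the null point on
#' thin groove-floor columns whose cartilage remnant is only 2-3 samples.
#'
#' @param column_profile numeric attenuation profile along depth.
#' @param surface_idx detected surface index for the column (default 1).
#' @param smooth_window optional centred moving-average window before
#'   differencing (default 1 = none).
#' @return Integer interface index, or `NA` if no derivative sign change
#'   exists (e.g. monotone profile).
#' @export
detect_bone_interface <- function(column_profile, surface_idx = 1,
                                  smooth_window = 1) {
  n <- length(column_profile)
  if (is.na(surface_idx) || surface_idx >= n - 1) return(NA_integer_)
  p <- moving_avg(column_profile, smooth_window)
  dd <- diff(p)
  # candidate minima at or below the surface sample
  idx <- seq(max(surface_idx, 2L), n - 1L)
  cand <- idx[dd[idx - 1] < 0 & dd[idx] >= 0]
  if (!length(cand)) return(NA_integer_)
  rise <- vapply(cand, function(m) max(p[m:n]) - p[m], numeric(1))
  m <- cand[which.max(rise)]
  as.integer(m + 1L)
}

#' Surface and interface maps for a volume
#'
#' Runs [detect_surface()] and [detect_bone_interface()] over every column and
#' assembles the per-column maps with thickness QC flags.
#'
#' @inheritParams detect_surface
#' @param thickness_range_mm plausible cartilage thickness range; columns
#'   outside it are flagged (default `c(0.1, 1.5)`).
#' @return A list of class `surface_maps`: `surface_idx`, `interface_idx`
#'   (integer matrices), `thickness_mm`, `flagged` (logical matrix),
#'   `voxel_size_um`.
#' @export
segment_volume <- function(volume, cal, expected_cartilage_hu = NULL,
                           thickness_range_mm = c(0.1, 1.5)) {
  surf <- detect_surface(volume, cal, expected_cartilage_hu)
  d <- dim(volume$voxels)
  intf <- matrix(NA_integer_, d[2], d[3])
  for (x in seq_len(d[3])) {
    for (y in seq_len(d[2])) {
      if (!is.na(surf[y, x])) {
        intf[y, x] <- detect_bone_interface(volume$voxels[, y, x], surf[y, x])
      }
    }
  }
  hz <- volume$voxel_size_um[1] / 1000
  thick <- (intf - surf) * hz
  flagged <- is.na(surf) | is.na(intf) | thick < thickness_range_mm[1] |
    thick > thickness_range_mm[2] | intf <= surf
  structure(
    list(surface_idx = surf, interface_idx = intf, thickness_mm = thick,
         flagged = flagged, voxel_size_um = volume$voxel_size_um),
    class = "surface_maps"
  )
}

#' @export
print.surface_maps <- function(x, ...) {
  cat(sprintf("<surface_maps> %d x %d columns, %d flagged\n",
              nrow(x$surface_idx), ncol(x$surface_idx), sum(x$flagged, na.rm = TRUE)))
  invisible(x)
}

#' Tidy a surface map
#'
#' @param x a `surface_maps`.
#' @param ... unused.
#' @return Tibble with one row per column: `dorsopalmar`, `lateromedial`,
#'   `surface_idx`, `interface_idx`, `thickness_mm`, `flagged`.
#' @export
tidy.surface_maps <- function(x, ...) {
  d <- dim(x$surface_idx)
  tibble::tibble(
    dorsopalmar = rep(seq_len(d[1]), d[2]),
    lateromedial = rep(seq_len(d[2]), each = d[1]),
    surface_idx = as.vector(x$surface_idx),
    interface_idx = as.vector(x$interface_idx),
    thickness_mm = as.vector(x$thickness_mm),
    flagged = as.vector(x$flagged)
  )
}

#' Locate the groove on a surface map
#'
#' Grooves run lateromedially, so each lateromedial slice contributes a
#' dorsopalmar surface-depression profile relative to a running-median
#' reference surface. The centreline is the depression maximum per slice; the
#' centre is the (rounded) centroid of near-maximal columns of the
#' slice-median depression. A median depression of at least `min_depth_vox`
#' voxels is required — grooves are ~5 voxels deep, and the cut guards against
#' single-voxel surface jitter on ungrooved joints.
#'
#' @param maps a `surface_maps` (or surface index matrix).
#' @param min_depth_vox minimum median depression to accept (default 2).
#' @param ref_window running-median window in columns (default 25).
#' @return List of class `groove_location`: `center` (named vector
#'   `dorsopalmar`, `lateromedial`), `depth_vox`, `centerline` (tibble), or an
#'   error `"no groove found"` when the depression is too shallow.
#' @export
locate_groove <- function(maps, min_depth_vox = 2, ref_window = 25) {
  surf <- if (inherits(maps, "surface_maps")) maps$surface_idx else maps
  ny <- nrow(surf); nx <- ncol(surf)
  depr <- matrix(NA_real_, ny, nx)
  for (x in seq_len(nx)) {
    col <- surf[, x]
    ok <- !is.na(col)
    if (sum(ok) < 5) next
    filled <- col
    filled[!ok] <- stats::median(col, na.rm = TRUE)
    k <- min(ref_window, ny - (1 - ny %% 2))
    if (k %% 2 == 0) k <- k - 1
    ref <- stats::runmed(filled, k)
    depr[, x] <- filled - ref
  }
  med_depr <- apply(depr, 1, stats::median, na.rm = TRUE)
  peak <- max(med_depr, na.rm = TRUE)
  if (!is.finite(peak) || peak < min_depth_vox) {
    stop("no groove found", call. = FALSE)
  }
  # near-maximal columns within one voxel of the peak: surface indices are
  # quantized, so a fixed band (not a fraction) keeps the whole channel
  near <- which(med_depr >= peak - 1)
  center_y <- as.integer(round(mean(near)))
  center_x <- which.max(apply(depr, 2, max, na.rm = TRUE))
  centerline <- tibble::tibble(
    lateromedial = seq_len(nx),
    dorsopalmar = apply(depr, 2, which.max),
    depth_vox = apply(depr, 2, max, na.rm = TRUE)
  )
  structure(
    list(center = c(dorsopalmar = center_y, lateromedial = as.integer(center_x)),
         depth_vox = peak, centerline = centerline),
    class = "groove_location"
  )
}

#' Place an analysis volume of interest
#'
#' VOIs follow the study design: the lesion VOI (0.48 x 0.48 mm footprint,
#' full cartilage thickness) is centred on the groove; the ungrooved VOIs
#' (1.04 x 0.48 mm, enlarged to reduce noise) sit 3 mm dorsal of the groove
#' centreline (`away_3mm`) or at the mirrored anatomical location in the
#' contralateral control volume (`contralateral`). Footprints are
#' (along-groove x across-groove) mm.
#'
#' @param groove_center named vector `(dorsopalmar, lateromedial)` in voxel
#'   indices of the grid the VOI is placed on (for `contralateral`, the groove
#'   centre of the paired grooved joint; it is mirrored internally).
#' @param maps a `surface_maps` for the target volume.
#' @param role `"lesion"`, `"away_3mm"` or `"contralateral"`.
#' @param voxel_size_um per-axis voxel size of the target grid.
#' @return One-row tibble of class `voi_spec`: role, footprint, centre indices
#'   and the dorsopalmar / lateromedial column index sets (list-columns).
#' @export
place_vois <- function(groove_center, maps, role = c("lesion", "away_3mm", "contralateral"),
                       voxel_size_um = c(80, 80, 80)) {
  role <- match.arg(role)
  ny <- nrow(maps$surface_idx); nx <- ncol(maps$surface_idx)
  hy <- voxel_size_um[2] / 1000
  hx <- voxel_size_um[3] / 1000
  footprint <- if (role == "lesion") c(0.48, 0.48) else c(1.04, 0.48)
  cy <- as.integer(groove_center[["dorsopalmar"]])
  cx <- as.integer(groove_center[["lateromedial"]])
  if (role == "away_3mm") cy <- cy + as.integer(round(3 / hy))
  if (role == "contralateral") cy <- ny - cy + 1L
  ky <- max(1L, as.integer(round(footprint[2] / hy)))
  kx <- max(1L, as.integer(round(footprint[1] / hx)))
  cols_y <- seq(cy - (ky - 1L) %/% 2L, length.out = ky)
  cols_x <- seq(cx - (kx - 1L) %/% 2L, length.out = kx)
  if (kx > nx) cols_x <- seq_len(nx)  # footprint spans the whole averaged axis
  cols_x <- cols_x[cols_x >= 1L & cols_x <= nx]
  if (any(cols_y < 1L) || any(cols_y > ny) || !length(cols_x)) {
    stop(sprintf("VOI '%s' footprint exceeds volume bounds", role), call. = FALSE)
  }
  structure(
    tibble::tibble(
      role = role,
      footprint_along_mm = footprint[1], footprint_across_mm = footprint[2],
      center_dorsopalmar = cy, center_lateromedial = cx,
      cols_dorsopalmar = list(cols_y), cols_lateromedial = list(cols_x)
    ),
    class = c("voi_spec", "tbl_df", "tbl", "data.frame")
  )
}

#' Detect air bubbles in the joint cavity
#'
#' Injection can trap air bubbles that locally prevent contrast-agent
#' diffusion. Bubbles are connected components (6-connectivity) of cavity
#' voxels darker than `threshold_hu`; a joint is excluded when any component
#' exceeds `min_volume_mm3` or touches an analysis VOI footprint.
#'
#' @param volume t = 60 [attenuation_volume()] (full resolution).
#' @param cavity_mask logical array marking the joint cavity (ground truth or
#'   detected).
#' @param vois optional `voi_spec` rows (on the same grid) to test footprint
#'   overlap against.
#' @param threshold_hu air threshold (default -300).
#' @param min_volume_mm3 exclusion size (default 5).
#' @return List of class `qc_report`: `bubbles` (tibble with centroid and
#'   volume), `excluded`, `reason`.
#' @export
detect_air_bubbles <- function(volume, cavity_mask, vois = NULL,
                               threshold_hu = -300, min_volume_mm3 = 5) {
  stopifnot(is_volume(volume))
  d <- dim(volume$voxels)
  cand <- which(cavity_mask & volume$voxels < threshold_hu)
  vox_mm3 <- prod(volume$voxel_size_um / 1000)
  bubbles <- tibble::tibble(centroid_z = numeric(0), centroid_y = numeric(0),
                            centroid_x = numeric(0), volume_mm3 = numeric(0),
                            touches_voi = logical(0))
  excluded <- FALSE; reason <- ""
  if (length(cand)) {
    comp <- label_components(cand, d)
    voi_y <- if (!is.null(vois)) {
      unique(unlist(purrr::map2(vois$cols_dorsopalmar, vois$role, function(c, r) c)))
    } else integer(0)
    bubbles <- purrr::map_dfr(split(cand, comp), function(ix) {
      ai <- arrayInd(ix, d)
      tibble::tibble(
        centroid_z = mean(ai[, 1]), centroid_y = mean(ai[, 2]),
        centroid_x = mean(ai[, 3]),
        volume_mm3 = length(ix) * vox_mm3,
        touches_voi = any(ai[, 2] %in% voi_y)
      )
    })
    big <- bubbles$volume_mm3 > min_volume_mm3
    if (any(big) || any(bubbles$touches_voi)) {
      excluded <- TRUE
      reason <- if (any(big)) {
        sprintf("air bubble of %.1f mm3 in the joint cavity", max(bubbles$volume_mm3))
      } else "air bubble overlapping an analysis VOI"
    }
  }
  structure(list(bubbles = bubbles, excluded = excluded, reason = reason),
            class = "qc_report")
}

# 6-connected component labelling of a sparse voxel index set (BFS over a
# linear-index membership map)
label_components <- function(idx, d) {
  n_all <- prod(d)
  member <- integer(n_all)       # 0 = not candidate, else position in idx
  member[idx] <- seq_along(idx)
  comp <- integer(length(idx))
  cur <- 0L
  # linear-index offsets of the 6 face neighbours, with bounds guards below
  pos <- arrayInd(idx, d)
  offs <- c(1L, -1L, d[1], -d[1], d[1] * d[2], -d[1] * d[2])
  for (i in seq_along(idx)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- integer(length(idx))
    queue[1] <- i
    head <- 1L; tail <- 1L
    comp[i] <- cur
    while (head <= tail) {
      j <- queue[head]; head <- head + 1L
      lin <- idx[j]
      p <- pos[j, ]
      for (k in 1:6) {
        # skip neighbours that would wrap across an axis boundary
        if (k == 1L && p[1] == d[1]) next
        if (k == 2L && p[1] == 1L) next
        if (k == 3L && p[2] == d[2]) next
        if (k == 4L && p[2] == 1L) next
        if (k == 5L && p[3] == d[3]) next
        if (k == 6L && p[3] == 1L) next
        m <- member[lin + offs[k]]
        if (m > 0L && comp[m] == 0L) {
          comp[m] <- cur
          tail <- tail + 1L
          queue[tail] <- m
        }
      }
    }
  }
  comp
}
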