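# full-scale white of the simulated 16-bit densitometry sensor
OD_WHITE <- 65535

#' Neutral-density calibration filter values
#'
#' The ten optical densities of the neutral-density filter set used to
#' calibrate digital densitometry.
#' @return Numeric vector of ODs.
#' @export
od_filters <- function() c(0.0, 0.3, 0.6, 1.0, 1.3, 1.6, 2.0, 2.3, 2.6, 3.0)

#' Simulate a Safranin-O histology section with calibration strip
#'
#' Renders a grey-level (16-bit) transmitted-light image of one stained
#' cartilage section. Optical density is proportional to the local
#' proteoglycan profile, scaled so the section's mean OD hits `od_mean`;
#' pixel grey level is transmittance `10^(-OD)` times the sensor's full
#' scale, plus sensor noise. A 10-step neutral-density calibration strip at
#' exactly the filter ODs occupies the left edge. ODs above the top filter
#' (3.0) saturate there, with a message.
#'
#' @param pg_profile relative proteoglycan density in \[0, 1\] versus
#'   normalized depth (numeric vector, surface to bone).
#' @param od_mean target section-mean optical density.
#' @param thickness_mm cartilage thickness the section spans (default 0.5).
#' @param width_mm lateral tissue width (default 0.48).
#' @param pixel_size_um pixel size at 4x magnification (default 1.4).
#' @param noise_sd_grey additive grey-level noise SD (default 300, ~0.5 % of
#'   full scale).
#' @param tilt_deg section tilt relative to the CT slab plane: shifts the
#'   depth coordinate linearly across the width, emulating imperfect
#'   parallelism between histology and CT slices (default 0).
#' @param seed integer seed.
#' @return List of class `od_section`: `image` (grey-level matrix, rows =
#'   depth), `tissue_cols` (column indices of tissue), `strip` (tibble with
#'   per-filter row ranges and ODs), `od_truth` (matrix of noiseless ODs over
#'   the tissue), `pixel_size_um`.
#' @export
synth_od_section <- function(pg_profile, od_mean, thickness_mm = 0.5,
                             width_mm = 0.48, pixel_size_um = 1.4,
                             noise_sd_grey = 300, tilt_deg = 0, seed = 1) {
  stopifnot(all(pg_profile >= 0), all(pg_profile <= 1), od_mean >= 0)
  h_mm <- pixel_size_um / 1000
  n_rows <- max(8L, round(thickness_mm / h_mm))
  n_tissue <- max(8L, round(width_mm / h_mm))
  strip_w <- 24L
  gap <- 8L
  n_cols <- strip_w + gap + n_tissue
  tissue_cols <- seq(strip_w + gap + 1L, n_cols)

  zeta <- (seq_len(n_rows) - 0.5) / n_rows
  pg_fun <- stats::approxfun(seq(0, 1, length.out = length(pg_profile)),
                             pg_profile, rule = 2)
  # per-column depth shift from section tilt
  xrel <- (seq_len(n_tissue) - (n_tissue + 1) / 2) * h_mm
  shift <- tan(tilt_deg * pi / 180) * xrel / thickness_mm
  od_truth <- vapply(seq_len(n_tissue), function(j) {
    pg_fun(pmin(pmax(zeta + shift[j], 0), 1))
  }, numeric(n_rows))
  mpg <- mean(od_truth)
  if (mpg <= 0) stop("proteoglycan profile is identically zero", call. = FALSE)
  od_truth <- od_truth * od_mean / mpg
  n_sat <- sum(od_truth > 3.0)
  if (n_sat > 0) {
    message(sprintf("%d pixel(s) above OD 3.0 saturate at the top filter", n_sat))
    od_truth[od_truth > 3.0] <- 3.0
  }

  img <- matrix(OD_WHITE, n_rows, n_cols)
  img[, tissue_cols] <- OD_WHITE * 10^(-od_truth)

  filters <- od_filters()
  bounds <- round(seq(0, n_rows, length.out = length(filters) + 1))
  strip <- tibble::tibble(
    filter_od = filters,
    row_from = bounds[-length(bounds)] + 1L,
    row_to = bounds[-1]
  )
  for (i in seq_len(nrow(strip))) {
    img[strip$row_from[i]:strip$row_to[i], seq_len(strip_w)] <-
      OD_WHITE * 10^(-strip$filter_od[i])
  }

  set.seed(as.integer(seed %% .Machine$integer.max))
  if (noise_sd_grey > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd_grey),
                        n_rows, n_cols)
  }
  img <- round(pmin(pmax(img, 0), OD_WHITE))

  structure(
    list(image = img, tissue_cols = tissue_cols, strip = strip,
         od_truth = od_truth, pixel_size_um = pixel_size_um),
    class = "od_section"
  )
}

#' Measure the calibration strip of a synthetic section
#'
#' @param section an `od_section`.
#' @return Tibble with `filter_od` and the measured mean `grey` per filter
#'   patch.
#' @export
measure_strip <- function(section) {
  stopifnot(inherits(section, "od_section"))
  strip_w <- min(section$tissue_cols) - 9L
  dplyr::mutate(
    section$strip,
    grey = purrr::map2_dbl(.data$row_from, .data$row_to, function(a, b) {
      mean(section$image[a:b, seq_len(strip_w)])
    })
  )[, c("filter_od", "grey")]
}

#' Fit the grey-level to optical-density calibration
#'
#' Monotone piecewise-linear interpolation in log-transmittance space: since
#' grey level is proportional to transmittance `10^(-OD)`, `log10(grey)` is
#' linear in OD between the filter nodes, so interpolation through the ten
#' measured `(grey, OD)` pairs reproduces every filter point exactly by
#' construction. Greys outside the filter range are clamped to \[0, 3.0\].
#'
#' @param filter_grey measured mean grey level per filter.
#' @param filter_od the filter ODs (default [od_filters()]).
#' @return List of class `od_calibration`: `filter_od`, `filter_grey`, and
#'   `fun(grey)` mapping grey level to OD.
#' @export
fit_od_calibration <- function(filter_grey, filter_od = od_filters()) {
  stopifnot(length(filter_grey) == length(filter_od))
  ord <- order(filter_od)
  filter_od <- filter_od[ord]; filter_grey <- filter_grey[ord]
  if (any(diff(filter_grey) >= 0)) {
    stop("filter grey levels must decrease strictly with OD (stage lighting fault)",
         call. = FALSE)
  }
  lg <- log10(filter_grey)
  fun <- function(grey) {
    out <- stats::approx(rev(lg), rev(filter_od), xout = log10(pmax(grey, 0.5)),
                         rule = 2)$y
    pmin(pmax(out, 0), 3.0)
  }
  structure(list(filter_od = filter_od, filter_grey = filter_grey, fun = fun),
            class = "od_calibration")
}

#' Convert a grey-level image to optical densities
#'
#' @param image grey-level matrix (or an `od_section`).
#' @param cal an `od_calibration`.
#' @param mask optional logical matrix restricting the conversion.
#' @return Numeric OD matrix (NA outside the mask).
#' @export
grey_to_od <- function(image, cal, mask = NULL) {
  if (inherits(image, "od_section")) image <- image$image
  stopifnot(inherits(cal, "od_calibration"), is.matrix(image))
  od <- matrix(cal$fun(as.vector(image)), nrow(image), ncol(image))
  if (!is.null(mask)) od[!mask] <- NA_real_
  od
}

#' Depth-resolved optical-density profile
#'
#' Applies the same depth-normalization machinery as the CT partition
#' profiles to the OD columns of a converted section: each tissue column is
#' linearly resampled onto `n_points` normalized-depth positions and the
#' position-wise mean profile is returned.
#'
#' @param od OD matrix (rows = depth) or an `od_section` plus `cal`.
#' @param tissue_cols column indices spanning the tissue (default: all
#'   columns with no NA).
#' @param n_points resampling positions (default 100).
#' @return A `depth_profile` with `kind = "od"`.
#' @export
od_depth_profile <- function(od, tissue_cols = NULL, n_points = 100) {
  stopifnot(is.matrix(od))
  if (is.null(tissue_cols)) tissue_cols <- which(colSums(is.na(od)) == 0)
  if (!length(tissue_cols)) stop("footprint outside the tissue mask", call. = FALSE)
  cols <- lapply(tissue_cols, function(j) {
    v <- od[, j]
    v[!is.na(v)]
  })
  mat <- normalize_depth(cols, n_points)
  mean_profile(mat, kind = "od")
}

#' Section-level OD analysis of a synthetic section
#'
#' Full densitometry chain for one section: measure the calibration strip,
#' fit the calibration, convert the tissue to OD and profile it.
#'
#' @param section an `od_section`.
#' @param n_points resampling positions.
#' @return List: `profile` (`depth_profile`), `mean_od`, `cal`.
#' @export
analyze_od_section <- function(section, n_points = 100) {
  strip <- measure_strip(section)
  cal <- fit_od_calibration(strip$grey, strip$filter_od)
  od <- grey_to_od(section$image[, section$tissue_cols, drop = FALSE], cal)
  prof <- od_depth_profile(od, n_points = n_points)
  list(profile = prof, mean_od = full_thickness_mean(prof), cal = cal)
}

#' Pair CT partition results with OD results
#'
#' CT and histology are matched by distance from the groove: the same
#' `(joint_id, role)` keys identify the 0 mm (lesion), 3 mm and contralateral
#' locations on both sides. Unmatched rows are reported, not silently
#' dropped.
#'
#' @param ct_results tibble with at least `joint_id`, `role` and a CT value
#'   column (e.g. `mean_partition_pct`).
#' @param od_results tibble with `joint_id`, `role` and `mean_od`.
#' @return Tibble of inner-joined pairs; unmatched rows are attached as the
#'   `"unmatched"` attribute and summarised in a message.
#' @export
match_ct_od <- function(ct_results, od_results) {
  keys <- c("joint_id", "role")
  stopifnot(all(keys %in% names(ct_results)), all(keys %in% names(od_results)))
  pairs <- dplyr::inner_join(ct_results, od_results, by = keys)
  un_ct <- dplyr::anti_join(ct_results, od_results, by = keys)
  un_od <- dplyr::anti_join(od_results, ct_results, by = keys)
  unmatched <- dplyr::bind_rows(
    ct = un_ct[keys], od = un_od[keys], .id = "side"
  )
  if (nrow(unmatched)) {
    message(sprintf("match_ct_od: %d unmatched row(s)", nrow(unmatched)))
  }
  attr(pairs, "unmatched") <- unmatched
  pairs
}
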