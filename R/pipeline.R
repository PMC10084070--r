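#' Analyse one grooved joint + contralateral control pair
#'
#' Full CT analysis chain for a joint pair, mirroring the study protocol:
#' six-slice averaging along the groove axis, provisional bath estimate,
#' surface and interface detection, bath re-measurement over the detected
#' cavity, groove localisation, VOI placement (lesion and 3 mm on the grooved
#' joint; mirrored contralateral on the control), air-bubble QC, depth
#' normalization, and conversion to ioxaglate partition.
#'
#' @param pair a `joint_pair` from [build_joint_pair()] (or a list with
#'   `grooved` / `control` `joint_phantom`s).
#' @param phantoms optional `phantom_scans` for the water / BiNP calibration;
#'   defaults to noiseless set-point phantoms at the scenario's offsets.
#' @param n_points depth-resampling positions (default 100).
#' @param slab_slices slices per averaged slab (default 6).
#' @param joint_id label recorded in the results (default the pair seed).
#' @return List of class `joint_result`: `results` (tibble, one row per VOI:
#'   `joint_id`, `groove_kind`, `role`, `mean_partition_pct`, `n_columns`,
#'   `profile` list-column), `calibration`, `qc`, `groove`.
#' @export
analyze_joint_pair <- function(pair, phantoms = NULL, n_points = 100,
                               slab_slices = 6, joint_id = NULL) {
  grooved <- pair$grooved; control <- pair$control
  if (is.null(joint_id)) joint_id <- paste0("joint_", pair$seed)
  scen <- grooved$scenario
  if (is.null(phantoms)) {
    calm_scen <- scen
    calm_scen$noise_sd_hu <- 0
    phantoms <- make_phantom_scans(calm_scen, seed = 1)
  }
  w <- measure_mask_mean(phantoms$water, phantoms$core_mask)$mean_hu
  b <- measure_mask_mean(phantoms$binp, phantoms$core_mask)$mean_hu

  seg <- function(phantom) {
    avg <- suppressMessages(average_slices(phantom$t60, slab_slices, axis = 3))
    bath0 <- estimate_bath_hu(avg)
    cal0 <- phantom_calibration(w, b, bath0)
    maps0 <- segment_volume(avg, cal0)
    bath <- measure_detected_cavity(avg, maps0)
    cal <- phantom_calibration(w, b, bath)
    maps <- segment_volume(avg, cal)
    list(avg = avg, cal = cal, maps = maps)
  }
  # big-bubble QC first: a large air bubble prevents contrast diffusion and
  # invalidates surface detection, so the joint is excluded before analysis
  qc0 <- qc_joint(grooved, NULL, NULL)
  if (qc0$excluded) {
    empty <- tibble::tibble(
      joint_id = character(0), groove_kind = character(0), role = character(0),
      mean_partition_pct = numeric(0), n_columns = integer(0), profile = list()
    )
    return(structure(list(results = empty, calibration = NULL, qc = qc0,
                          groove = NULL), class = "joint_result"))
  }

  sg <- seg(grooved)
  sc <- seg(control)

  groove <- locate_groove(sg$maps)
  qc <- qc_joint(grooved, groove, sg$avg)

  voi_les <- place_vois(groove$center, sg$maps, "lesion", sg$avg$voxel_size_um)
  voi_away <- place_vois(groove$center, sg$maps, "away_3mm", sg$avg$voxel_size_um)
  voi_con <- place_vois(groove$center, sc$maps, "contralateral", sc$avg$voxel_size_um)

  one <- function(volope, voi, maps, cal) {
    r <- voi_partition(volope, voi, maps, cal, n_points)
    tibble::tibble(
      joint_id = joint_id, groove_kind = scen$groove_kind, role = voi$role,
      mean_partition_pct = r$mean_partition_pct, n_columns = r$n_columns,
      profile = list(r$profile)
    )
  }
  results <- dplyr::bind_rows(
    one(sg$avg, voi_les, sg$maps, sg$cal),
    one(sg$avg, voi_away, sg$maps, sg$cal),
    one(sc$avg, voi_con, sc$maps, sc$cal)
  )
  structure(
    list(results = results, calibration = sg$cal, qc = qc, groove = groove),
    class = "joint_result"
  )
}

# bath re-measurement over the detected cavity: voxels at least 0.3 mm above
# the detected surface, ignoring air (< -300 HU)
measure_detected_cavity <- function(avg, maps, margin_mm = 0.3) {
  d <- dim(avg$voxels)
  m_vox <- ceiling(margin_mm / (avg$voxel_size_um[1] / 1000))
  vals <- c()
  for (x in seq_len(d[3])) {
    for (y in seq_len(d[2])) {
      s <- maps$surface_idx[y, x]
      if (is.na(s) || s - m_vox - 1L < 1L) next
      v <- avg$voxels[seq_len(s - m_vox - 1L), y, x]
      vals <- c(vals, v[v > -300])
    }
  }
  if (!length(vals)) stop("no cavity voxels available for the bath measurement",
                          call. = FALSE)
  mean(vals)
}

# QC on the grooved joint: bubbles in the full-resolution cavity (everything
# above the per-column articulating surface)
qc_joint <- function(phantom, groove, avg) {
  truth_like <- phantom$t60
  d <- dim(truth_like$voxels)
  surf_map <- phantom$truth$surface_height_map
  depth_idx <- array(seq_len(d[1]), dim = d)
  surf <- array(rep(surf_map, each = d[1]), dim = d)
  cav <- depth_idx < surf
  vois <- NULL
  if (!is.null(groove)) {
    vois <- dplyr::bind_rows(
      place_like(groove$center, d, "lesion"),
      place_like(groove$center, d, "away_3mm")
    )
  }
  detect_air_bubbles(truth_like, cav, vois)
}

# minimal footprint spec on the full-resolution grid for QC overlap tests
place_like <- function(center, d, role) {
  cy <- as.integer(center[["dorsopalmar"]])
  if (role == "away_3mm") cy <- cy + 38L
  ky <- 6L
  cols_y <- seq(cy - 2L, length.out = ky)
  structure(
    tibble::tibble(role = role, cols_dorsopalmar = list(cols_y),
                   cols_lateromedial = list(seq_len(d[3]))),
    class = c("voi_spec", "tbl_df", "tbl", "data.frame")
  )
}

#' Simulate and analyse a cohort of joint pairs
#'
#' Generates one joint pair per seed from a scenario and pushes each through
#' [analyze_joint_pair()], returning the stacked per-VOI results. Joints
#' excluded by air-bubble QC are reported in the `"qc"` attribute, not
#' silently dropped.
#'
#' @param scenario a grooved [scenario_config()].
#' @param seeds integer vector, one joint pair per seed.
#' @param include_od also simulate and analyse matched histology sections
#'   (adds `mean_od` per row via [match_ct_od()] keys).
#' @param n_points depth-resampling positions.
#' @return Tibble of VOI results (rows = joints x locations) with attributes
#'   `qc` (tibble of per-joint QC outcomes) and `excluded` (joint ids).
#' @export
simulate_cohort <- function(scenario, seeds, include_od = FALSE, n_points = 100) {
  qc_rows <- list(); res <- list(); od_rows <- list()
  for (s in seeds) {
    pair <- build_joint_pair(scenario, s)
    jr <- analyze_joint_pair(pair, joint_id = paste0(scenario$name, "_", s))
    qc_rows[[length(qc_rows) + 1L]] <- tibble::tibble(
      joint_id = jr$results$joint_id[1],
      excluded = jr$qc$excluded, reason = jr$qc$reason
    )
    if (!jr$qc$excluded) {
      res[[length(res) + 1L]] <- jr$results
      if (include_od) {
        od_rows[[length(od_rows) + 1L]] <- simulate_cohort_od(pair, jr$results$joint_id[1])
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (include_od && length(od_rows)) {
    out <- match_ct_od(out, dplyr::bind_rows(od_rows))
  }
  qc <- dplyr::bind_rows(qc_rows)
  attr(out, "qc") <- qc
  attr(out, "excluded") <- qc$joint_id[qc$excluded]
  out
}

# matched synthetic histology for one joint pair: one section per location,
# calibrated to the joint's OD truth, analysed with the densitometry chain
simulate_cohort_od <- function(pair, joint_id) {
  scen <- pair$grooved$scenario
  draws <- pair$grooved$truth$draws
  u <- scen$uptake
  zeta <- seq(0, 1, length.out = 64)
  purrr::map_dfr(c("lesion", "away_3mm", "contralateral"), function(role) {
    m <- draws$partition_mean[[role]]
    shape <- u$profile_surface + (u$profile_bone - u$profile_surface) * zeta
    pg <- pmin(pmax(1 - m * shape / u$p_max, 0), 1)
    sec <- synth_od_section(pg, od_mean = draws$od_mean[[role]],
                            thickness_mm = pair$grooved$truth$thickness_mm,
                            seed = pair$seed + match(role, c("lesion", "away_3mm",
                                                            "contralateral")) * 7919)
    a <- analyze_od_section(sec)
    tibble::tibble(joint_id = joint_id, role = role, mean_od = a$mean_od)
  })
}

#' Run the full study pipeline
#'
#' Executes simulate -> calibrate -> segment -> profile -> (densitometry) ->
#' stats for a manifest of scenarios and seeds and assembles a summary table
#' shaped like the study's results table (3 locations x \{partition, OD\} x
#' groove type), plus combined-group comparisons.
#'
#' @param manifest list (or YAML path) with elements `blunt_seeds`,
#'   `sharp_seeds` (integer vectors), optional `bubble_seed` (a sharp-arm
#'   seed rendered with a large cavity bubble over the groove, which QC then
#'   excludes), `include_od` (default TRUE), `n_points`, and optional
#'   `out_dir` to write CSV/JSON artifacts.
#' @return List of class `pipeline_run`: `voi_results`, `summary`,
#'   `comparisons` (per groove kind and combined), `qc`, `manifest`.
#' @export
run_pipeline <- function(manifest) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  stopifnot(is.list(manifest))
  if (is.null(manifest$blunt_seeds) && is.null(manifest$sharp_seeds)) {
    stop("manifest must name at least one of blunt_seeds / sharp_seeds", call. = FALSE)
  }
  include_od <- manifest$include_od %||% TRUE
  n_points <- manifest$n_points %||% 100

  parts <- list(); qcs <- list()
  if (length(manifest$blunt_seeds)) {
    blunt <- simulate_cohort(cartipart_scenario("blunt"), manifest$blunt_seeds,
                             include_od = include_od, n_points = n_points)
    parts$blunt <- blunt; qcs$blunt <- attr(blunt, "qc")
  }
  if (length(manifest$sharp_seeds) || !is.null(manifest$bubble_seed)) {
    scen <- cartipart_scenario("sharp")
    sharp <- simulate_cohort(scen, manifest$sharp_seeds %||% integer(0),
                             include_od = include_od, n_points = n_points)
    qcs$sharp <- attr(sharp, "qc")
    if (!is.null(manifest$bubble_seed)) {
      bscen <- scen
      bscen$bubble <- list(center_mm = c(0.6, 1.6, 0.96), radius_mm = 2,
                           allow_over_voi = TRUE)
      bpair <- build_joint_pair(bscen, manifest$bubble_seed)
      bres <- analyze_joint_pair(bpair, joint_id = paste0("sharp_", manifest$bubble_seed))
      qcs$sharp <- dplyr::bind_rows(qcs$sharp, tibble::tibble(
        joint_id = paste0("sharp_", manifest$bubble_seed),
        excluded = bres$qc$excluded, reason = bres$qc$reason
      ))
      if (!bres$qc$excluded) sharp <- dplyr::bind_rows(sharp, bres$results)
    }
    parts$sharp <- sharp
  }
  voi <- dplyr::bind_rows(parts)
  qc <- dplyr::bind_rows(qcs, .id = "arm")

  summary <- summarize_cohort(voi)
  # group comparisons need at least two joints per location
  safe_compare <- function(df, value) {
    if (min(table(df$role)) < 2) return(NULL)
    compare_locations(df, !!rlang::enquo(value))
  }
  comparisons <- list(combined = safe_compare(voi, mean_partition_pct))
  for (gk in unique(voi$groove_kind)) {
    comparisons[[gk]] <- safe_compare(
      dplyr::filter(voi, .data$groove_kind == gk), mean_partition_pct)
  }
  if ("mean_od" %in% names(voi)) {
    comparisons$combined_od <- safe_compare(voi, mean_od)
  }
  comparisons <- purrr::compact(comparisons)

  run <- structure(
    list(voi_results = voi, summary = summary, comparisons = comparisons,
         qc = qc, manifest = manifest),
    class = "pipeline_run"
  )
  if (!is.null(manifest$out_dir)) write_run(run, manifest$out_dir)
  run
}

#' Summarise a cohort of VOI results
#'
#' Mean +/- SD per groove kind and location (and OD, if present), the shape
#' of the study's results table.
#'
#' @param voi_results tibble from [simulate_cohort()] / [run_pipeline()].
#' @return Tibble with `groove_kind`, `role`, `n`, `partition_mean`,
#'   `partition_sd` (and `od_mean`, `od_sd`).
#' @export
summarize_cohort <- function(voi_results) {
  out <- dplyr::summarise(
    dplyr::group_by(voi_results, .data$groove_kind, .data$role),
    n = dplyr::n(),
    partition_mean = mean(.data$mean_partition_pct),
    partition_sd = stats::sd(.data$mean_partition_pct),
    .groups = "drop"
  )
  if ("mean_od" %in% names(voi_results)) {
    od <- dplyr::summarise(
      dplyr::group_by(voi_results, .data$groove_kind, .data$role),
      od_mean = mean(.data$mean_od), od_sd = stats::sd(.data$mean_od),
      .groups = "drop"
    )
    out <- dplyr::left_join(out, od, by = c("groove_kind", "role"))
  }
  dplyr::arrange(out, .data$groove_kind,
                 match(.data$role, c("lesion", "away_3mm", "contralateral")))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$summary)
  excl <- x$qc$joint_id[x$qc$excluded]
  if (length(excl)) {
    cat("QC-excluded joints:", paste(excl, collapse = ", "), "\n")
  }
  invisible(x)
}

# write CSV/JSON artifacts of a run
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  voi <- run$voi_results
  profiles <- tidyr::unnest(
    dplyr::mutate(voi[, c("joint_id", "role", "profile")],
                  profile = purrr::map(.data$profile, tibble::as_tibble)),
    "profile"
  )
  readr::write_csv(dplyr::select(voi, -"profile"), file.path(out_dir, "voi_results.csv"))
  readr::write_csv(profiles, file.path(out_dir, "profiles.csv"))
  readr::write_csv(run$summary, file.path(out_dir, "summary.csv"))
  readr::write_csv(run$qc, file.path(out_dir, "qc.csv"))
  if (length(run$comparisons)) {
    comp <- purrr::imap_dfr(run$comparisons, function(cmp, nm) {
      dplyr::mutate(tidy(cmp), comparison = nm, .before = 1)
    })
    readr::write_csv(comp, file.path(out_dir, "comparisons.csv"))
  }
  jsonlite::write_json(
    list(manifest = run$manifest,
         omnibus = purrr::map(run$comparisons, function(cmp) as.list(glance(cmp)))),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
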