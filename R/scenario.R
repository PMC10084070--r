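#' Scenario configuration for the synthetic joint generator
#'
#' A scenario bundles everything the generator needs to emulate one study
#' condition: groove geometry, cartilage thickness statistics, contrast-agent
#' attenuations, the per-location ioxaglate-partition and optical-density
#' truths the rendered fields are calibrated to, noise, and rendering options.
#'
#' Partition / OD truths carry two spreads: `sd`, the observed between-joint
#' standard deviation of the reference cohort (used verbatim by the
#' stats-module simulations), and `between_sd`, the component the image
#' generator injects as joint-level biological variation (default half of
#' `sd`; the remainder of the observed variance is attributed to scanner
#' effects such as beam hardening, which the generator deliberately omits).
#'
#' @param name scenario label.
#' @param groove_kind `"blunt"`, `"sharp"` or `"none"`.
#' @param groove_depth_um groove penetration depth below the local articulating
#'   surface (default 400).
#' @param groove_width_um channel width; defaults 500 (blunt) / 150 (sharp).
#' @param cartilage_thickness_mm list with `mean`, `sd` and truncation bounds
#'   `min`, `max` for per-joint thickness draws (default 0.501 +/- 0.101,
#'   truncated to \[0.45, 0.65\] so a 400 um groove never breaches into bone).
#' @param cavity_hu_t60 joint-cavity (dual-bath) attenuation at t = 60 min
#'   (default 1667 HU).
#' @param binp_bath_hu_offset HU contribution of the bismuth-nanoparticle
#'   suspension alone (default 0; see the methods vignette).
#' @param bone_hu subchondral bone attenuation (default 2500 HU, brighter than
#'   the cavity so interface detection is exercised).
#' @param noise_sd_hu additive Gaussian noise SD per voxel (default 40 HU).
#' @param partition_truth named list (`lesion`, `away_3mm`, `contralateral`) of
#'   lists with `mean`, `sd` (and optional `between_sd`) on the partition scale
#'   (percent).
#' @param od_truth same structure on the optical-density scale.
#' @param bubble optional list `(center_mm = c(z, y, x), radius_mm,
#'   allow_over_voi = FALSE)` describing an air bubble in the cavity.
#' @param geometry list of grid / anatomy settings; see Details.
#' @param uptake list with the uptake-law settings: `profile_surface` /
#'   `profile_bone` (relative partition at the two ends of the depth profile,
#'   mean 1 across depth), `p_max` and `slope` of the linear partition-PG law,
#'   `peri_decay_mm` (lateral decay length of peri-groove degeneration) and
#'   `lesion_swelling_frac` (peri-groove thickness increase).
#' @param supersample integer rendering supersampling factor for
#'   partial-volume emulation (default 2; 1 renders by voxel-centre labels).
#'
#' @details Default geometry: a 30 x 96 x 24 voxel grid at 80 um (2.4 x 7.68 x
#'   1.92 mm), articulating surface 1.1 mm deep at the dorsopalmar centre with
#'   cylindrical curvature (radius 20 mm, axis lateromedial), groove centred
#'   1.56 mm from the dorsal edge.
#'
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(name = "custom",
                            groove_kind = c("blunt", "sharp", "none"),
                            groove_depth_um = 400,
                            groove_width_um = NULL,
                            cartilage_thickness_mm = list(mean = 0.501, sd = 0.101,
                                                          min = 0.45, max = 0.65),
                            cavity_hu_t60 = 1667,
                            binp_bath_hu_offset = 0,
                            bone_hu = 2500,
                            noise_sd_hu = 40,
                            partition_truth = NULL,
                            od_truth = NULL,
                            bubble = NULL,
                            geometry = list(),
                            uptake = list(),
                            supersample = 2) {
  groove_kind <- match.arg(groove_kind)
  if (is.null(groove_width_um)) {
    groove_width_um <- switch(groove_kind, blunt = 500, sharp = 150, none = NA_real_)
  }
  geom_default <- list(
    dims = c(30L, 96L, 24L), voxel_size_um = 80,
    surface_depth_mm = 1.1, curvature_radius_mm = 20,
    groove_y_mm = 1.56, air_hu = -1000
  )
  geometry <- utils::modifyList(geom_default, geometry)
  uptake_default <- list(
    profile_surface = 1.1, profile_bone = 0.9,
    p_max = 150, slope = 150,
    peri_decay_mm = 0.5, lesion_swelling_frac = 0.4
  )
  uptake <- utils::modifyList(uptake_default, uptake)
  if (is.null(partition_truth)) {
    partition_truth <- list(
      lesion = list(mean = 66, sd = 18),
      away_3mm = list(mean = 45, sd = 11),
      contralateral = list(mean = 42, sd = 9)
    )
  }
  if (is.null(od_truth)) {
    od_truth <- list(
      lesion = list(mean = 0.7, sd = 0.2),
      away_3mm = list(mean = 1.2, sd = 0.2),
      contralateral = list(mean = 1.1, sd = 0.2)
    )
  }
  partition_truth <- lapply(partition_truth, complete_truth)
  od_truth <- lapply(od_truth, complete_truth)
  cfg <- list(
    name = name, groove_kind = groove_kind,
    groove_depth_um = groove_depth_um, groove_width_um = groove_width_um,
    cartilage_thickness_mm = cartilage_thickness_mm,
    cavity_hu_t60 = cavity_hu_t60, binp_bath_hu_offset = binp_bath_hu_offset,
    bone_hu = bone_hu, noise_sd_hu = noise_sd_hu,
    partition_truth = partition_truth, od_truth = od_truth,
    bubble = bubble, geometry = geometry, uptake = uptake,
    supersample = as.integer(supersample)
  )
  validate_scenario(cfg)
  structure(cfg, class = "scenario_config")
}

complete_truth <- function(x) {
  stopifnot(is.list(x), !is.null(x$mean))
  if (is.null(x$sd)) x$sd <- 0
  if (is.null(x$between_sd)) x$between_sd <- x$sd / 2
  x
}

validate_scenario <- function(cfg) {
  th <- cfg$cartilage_thickness_mm
  stopifnot(th$sd >= 0, th$min > 0, th$max >= th$min)
  for (loc in names(cfg$partition_truth)) {
    tr <- cfg$partition_truth[[loc]]
    if (tr$sd < 0 || tr$mean < 0 || tr$mean > 150) {
      stop("partition truth means must lie in [0, 150] percent with sd >= 0",
           call. = FALSE)
    }
  }
  if (cfg$noise_sd_hu < 0) stop("noise_sd_hu must be >= 0", call. = FALSE)
  if (cfg$groove_kind != "none") {
    min_remaining <- th$min * (1 + cfg$uptake$lesion_swelling_frac) -
      cfg$groove_depth_um / 1000
    if (min_remaining < 2 * cfg$geometry$voxel_size_um / 1000 - 1e-9) {
      stop("groove would breach the full cartilage thickness into bone",
           call. = FALSE)
    }
    if (cfg$groove_width_um / 1000 >
        cfg$geometry$dims[2] * cfg$geometry$voxel_size_um / 1000) {
      stop("groove wider than the volume", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Read / write scenario files
#'
#' Scenarios are stored as YAML; values present in the file override the
#' [scenario_config()] defaults.
#'
#' @param path YAML file path.
#' @return [read_scenario()] returns a `scenario_config`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(scenario_config)))]
  do.call(scenario_config, args)
}

#' @rdname read_scenario
#' @param scenario a `scenario_config`.
#' @export
write_scenario <- function(scenario, path) {
  x <- unclass(scenario)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Bundled study scenarios
#'
#' Returns one of the scenarios shipped with the package: `"blunt"` and
#' `"sharp"` reproduce the two groove arms (location means calibrated to the
#' reference cohort table), `"control"` is an ungrooved joint.
#'
#' @param name `"blunt"`, `"sharp"` or `"control"`.
#' @return A `scenario_config`.
#' @export
cartipart_scenario <- function(name = c("blunt", "sharp", "control")) {
  name <- match.arg(name)
  path <- system.file("scenarios", paste0(name, ".yaml"), package = "cartipart")
  if (!nzchar(path)) stop("bundled scenario not found", call. = FALSE)
  read_scenario(path)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> '%s': %s groove", x$name, x$groove_kind))
  if (x$groove_kind != "none") {
    cat(sprintf(" (%g um deep, %g um wide)", x$groove_depth_um, x$groove_width_um))
  }
  cat(sprintf("\n  cavity %g HU at t60, noise sd %g HU\n",
              x$cavity_hu_t60, x$noise_sd_hu))
  pt <- x$partition_truth
  cat(sprintf("  partition truth: lesion %g%%, 3 mm %g%%, contralateral %g%%\n",
              pt$lesion$mean, pt$away_3mm$mean, pt$contralateral$mean))
  invisible(x)
}
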