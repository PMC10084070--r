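#' @importFrom rlang .data
NULL

# Label codes used by the generator's ground-truth mask volume.
LABELS <- c(cavity = 1L, cartilage = 2L, bone = 3L, groove_void = 4L, bubble = 5L)

#' Ground-truth label codes
#'
#' Named integer codes used in `ground_truth$masks`.
#' @return Named integer vector.
#' @export
label_codes <- function() LABELS

# Hounsfield-unit equivalent of the native (non-contrast-enhanced) cartilage
# baseline, 1.05 x the attenuation of water: HU(1.05 mu_w) = 50.
NATIVE_BASELINE_HU <- 50

# Low-discrepancy standard-normal stream indexed by seed. Consecutive seeds
# fill the unit interval near-uniformly (golden-ratio Kronecker sequence), so
# cohorts of consecutive seeds realise the configured location means with
# minimal sampling drift. Quantiles are clamped so single draws stay within
# ~2 SD, keeping extreme joints physically renderable.
golden_normal <- function(seed, shift = 0) {
  phi <- (sqrt(5) - 1) / 2
  u <- (phi * seed + shift) %% 1
  stats::qnorm(pmin(pmax(u, 0.02), 0.98))
}

# Per-joint biological draws: location-mean offsets (partition %, OD) and
# cartilage thickness (mm). OD offsets are the negated partition stream --
# the same underlying proteoglycan variation drives both, with opposite sign.
joint_draws <- function(scenario, seed) {
  shifts <- c(lesion = 0.00, away_3mm = 0.21, contralateral = 0.47)
  part <- purrr::imap_dbl(shifts, function(s, loc) {
    tr <- scenario$partition_truth[[loc]]
    tr$mean + tr$between_sd * golden_normal(seed, s)
  })
  od <- purrr::imap_dbl(shifts, function(s, loc) {
    tr <- scenario$od_truth[[loc]]
    tr$mean - tr$between_sd * golden_normal(seed, s)
  })
  th <- scenario$cartilage_thickness_mm
  tk <- th$mean + th$sd * golden_normal(seed, 0.83)
  list(
    partition_mean = part,
    od_mean = od,
    thickness_mm = min(max(tk, th$min), th$max)
  )
}

#' Carve a groove into a surface height map
#'
#' Removes a lateromedially running channel of the configured width and depth
#' from the cartilage: groove columns (nearest-voxel rasterisation of the
#' analytic channel, `round(width / voxel)` columns wide) have their surface
#' index lowered by `round(depth / voxel)` voxels so the map follows the
#' groove floor.
#'
#' @param surface_height_map integer matrix (dorsopalmar x lateromedial) of
#'   per-column articulating-surface depth indices.
#' @param config a [scenario_config()] with `groove_kind != "none"`.
#' @return List with `surface_height_map` (updated), `groove_columns` (integer
#'   vector of dorsopalmar column indices) and `depth_vox`.
#' @export
carve_groove <- function(surface_height_map, config) {
  if (config$groove_kind == "none") {
    return(list(surface_height_map = surface_height_map,
                groove_columns = integer(0), depth_vox = 0L))
  }
  h <- config$geometry$voxel_size_um
  w_vox <- max(1L, as.integer(round(config$groove_width_um / h)))
  if (w_vox > nrow(surface_height_map)) stop("groove wider than the volume", call. = FALSE)
  d_vox <- as.integer(round(config$groove_depth_um / h))
  yg <- as.integer(round(config$geometry$groove_y_mm / (h / 1000) + 0.5))
  cols <- seq(yg - (w_vox - 1L) %/% 2L, length.out = w_vox)
  if (any(cols < 1L) || any(cols > nrow(surface_height_map))) {
    stop("groove channel outside the volume", call. = FALSE)
  }
  out <- surface_height_map
  out[cols, ] <- out[cols, ] + d_vox
  list(surface_height_map = out, groove_columns = cols, depth_vox = d_vox)
}

#' Linear ioxaglate uptake law
#'
#' Ioxaglate is anionic, so its equilibrium partition in cartilage is inversely
#' related to the (negatively charged) proteoglycan content. The generator uses
#' the linear law `partition = target_mean + slope * (mean(pg) - pg)`: a field
#' with uniform PG sits exactly at the target mean, and PG depletion raises the
#' partition with the configured slope. At `t = 0` (before diffusion) the
#' partition is zero everywhere.
#'
#' @param pg_field numeric array/vector of relative proteoglycan density in
#'   \[0, 1\] (NA outside cartilage).
#' @param timepoint_min 0 or 60.
#' @param target_mean full-thickness mean partition (percent) the field is
#'   calibrated to.
#' @param slope percentage points of partition per unit PG (default 150).
#' @return Partition field (percent), same shape as `pg_field`; negative values
#'   are clipped to 0 with a warning.
#' @export
simulate_uptake <- function(pg_field, timepoint_min, target_mean, slope = 150) {
  stopifnot(timepoint_min %in% c(0, 60))
  rng <- range(pg_field, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("pg_field must lie in [0, 1]", call. = FALSE)
  out <- pg_field
  if (timepoint_min == 0) {
    out[!is.na(out)] <- 0
    return(out)
  }
  mpg <- mean(pg_field, na.rm = TRUE)
  part <- target_mean + slope * (mpg - pg_field)
  if (any(part < 0, na.rm = TRUE)) {
    warning("negative partitions clipped to 0")
    part[part < 0] <- 0
  }
  part
}

# Continuous joint geometry shared by rendering and ground truth.
# All functions of dorsopalmar position y (mm). Depth z grows cavity -> bone.
joint_geometry <- function(scenario, draws) {
  g <- scenario$geometry
  u <- scenario$uptake
  h_mm <- g$voxel_size_um / 1000
  ny <- g$dims[2]
  yc <- ny * h_mm / 2
  tk <- draws$thickness_mm

  grooved <- scenario$groove_kind != "none"
  if (grooved) {
    w_vox <- max(1L, as.integer(round(scenario$groove_width_um / g$voxel_size_um)))
    yg_idx <- as.integer(round(g$groove_y_mm / h_mm + 0.5))
    groove_cols <- seq(yg_idx - (w_vox - 1L) %/% 2L, length.out = w_vox)
    ch_lo <- (min(groove_cols) - 1) * h_mm
    ch_hi <- max(groove_cols) * h_mm
  } else {
    groove_cols <- integer(0)
    ch_lo <- ch_hi <- NA_real_
  }

  dist_groove <- function(y) {
    if (!grooved) return(rep(Inf, length(y)))
    pmax(0, pmax(ch_lo - y, y - ch_hi))
  }
  surf0 <- function(y) g$surface_depth_mm + (y - yc)^2 / (2 * g$curvature_radius_mm)
  swell <- function(y) {
    if (!grooved) return(rep(0, length(y)))
    u$lesion_swelling_frac * exp(-dist_groove(y) / u$peri_decay_mm)
  }
  z_surf <- function(y) surf0(y) - tk * swell(y)          # swollen surface
  z_int <- function(y) surf0(y) + tk                      # smooth bone interface
  in_channel <- function(y) {
    if (!grooved) return(rep(FALSE, length(y)))
    y > ch_lo & y < ch_hi
  }
  gd_mm <- scenario$groove_depth_um / 1000
  z_top <- function(y) z_surf(y) + ifelse(in_channel(y), gd_mm, 0)  # tissue top

  # Location mean field m(y): far field at the 3-mm truth, peri-groove bump
  # scaled so the mean over the lesion-VOI footprint hits the lesion truth.
  m_les <- draws$partition_mean[["lesion"]]
  m_away <- draws$partition_mean[["away_3mm"]]
  m_contra <- draws$partition_mean[["contralateral"]]
  y_centers <- (seq_len(ny) - 0.5) * h_mm
  if (grooved) {
    center_idx <- as.integer(round(mean(groove_cols)))
    voi_cols <- seq(center_idx - 2L, length.out = 6L)
    gfun <- function(y) exp(-dist_groove(y) / u$peri_decay_mm)
    c_les <- (m_les - m_away) / mean(gfun(y_centers[voi_cols]))
    m_fun <- function(y) m_away + c_les * gfun(y)
  } else {
    voi_cols <- integer(0)
    m_fun <- function(y) rep(m_contra, length(y))
  }
  shape <- function(zeta) {
    u$profile_surface + (u$profile_bone - u$profile_surface) * zeta
  }

  list(
    h_mm = h_mm, grooved = grooved, groove_cols = groove_cols,
    lesion_voi_cols = voi_cols, dist_groove = dist_groove,
    z_surf = z_surf, z_int = z_int, z_top = z_top, in_channel = in_channel,
    m_fun = m_fun, shape = shape, thickness_mm = tk
  )
}

# Render the x-invariant (z, y) attenuation template at a supersampling
# factor and box-downsample to the final grid. Returns t0 and t60 templates.
render_templates <- function(scenario, geom) {
  g <- scenario$geometry
  f <- max(1L, scenario$supersample)
  nz <- g$dims[1]; ny <- g$dims[2]
  h_sub <- geom$h_mm / f
  z_sub <- (seq_len(nz * f) - 0.5) * h_sub
  y_sub <- (seq_len(ny * f) - 0.5) * h_sub

  zs <- matrix(z_sub, nz * f, ny * f)
  surf_row <- geom$z_surf(y_sub)
  top_row <- geom$z_top(y_sub)
  int_row <- geom$z_int(y_sub)
  surf <- matrix(surf_row, nz * f, ny * f, byrow = TRUE)
  top <- matrix(top_row, nz * f, ny * f, byrow = TRUE)
  zint <- matrix(int_row, nz * f, ny * f, byrow = TRUE)

  iox_bath <- scenario$cavity_hu_t60 - scenario$binp_bath_hu_offset
  cart <- zs >= top & zs < zint
  zeta <- (zs - top) / (zint - top)
  m_row <- geom$m_fun(y_sub)
  part <- matrix(m_row, nz * f, ny * f, byrow = TRUE) * geom$shape(zeta)

  t60 <- matrix(scenario$cavity_hu_t60, nz * f, ny * f)  # cavity + groove void
  t0 <- t60
  t60[cart] <- NATIVE_BASELINE_HU + part[cart] / 100 * iox_bath
  t0[cart] <- NATIVE_BASELINE_HU
  bone <- zs >= zint
  t60[bone] <- scenario$bone_hu
  t0[bone] <- scenario$bone_hu

  list(t0 = box_down(t0, f), t60 = box_down(t60, f))
}

# Box-downsample a matrix by integer factor f in both dimensions.
box_down <- function(m, f) {
  if (f == 1L) return(m)
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  dim(m) <- c(f, nr, f * nc)
  m <- colMeans(m)                      # (nr, f*nc)
  dim(m) <- c(nr, f, nc)
  out <- colMeans(aperm(m, c(2, 1, 3)))  # (nr, nc)
  matrix(out, nr, nc)
}

# Voxel-centre labels and ground-truth fields on the final grid (2-D template).
truth_templates <- function(scenario, geom) {
  g <- scenario$geometry
  nz <- g$dims[1]; ny <- g$dims[2]
  z_c <- (seq_len(nz) - 0.5) * geom$h_mm
  y_c <- (seq_len(ny) - 0.5) * geom$h_mm
  zs <- matrix(z_c, nz, ny)
  surf <- matrix(geom$z_surf(y_c), nz, ny, byrow = TRUE)
  top <- matrix(geom$z_top(y_c), nz, ny, byrow = TRUE)
  zint <- matrix(geom$z_int(y_c), nz, ny, byrow = TRUE)

  lab <- matrix(LABELS[["cavity"]], nz, ny)
  lab[zs >= surf & zs < top] <- LABELS[["groove_void"]]
  cart <- zs >= top & zs < zint
  lab[cart] <- LABELS[["cartilage"]]
  lab[zs >= zint] <- LABELS[["bone"]]

  zeta <- (zs - top) / (zint - top)
  part <- matrix(geom$m_fun(y_c), nz, ny, byrow = TRUE) * geom$shape(zeta)
  part[!cart] <- NA_real_

  # per-column maps: first voxel centre inside tissue / bone
  surface_idx <- apply(zs >= top, 2, function(col) which(col)[1])
  interface_idx <- apply(zs >= zint, 2, function(col) which(col)[1])

  list(labels = lab, partition = part,
       surface_idx = as.integer(surface_idx),
       interface_idx = as.integer(interface_idx))
}

#' Build a synthetic dual-contrast joint phantom
#'
#' Renders one osteochondral region at the two acquisition time points: a
#' curved ~0.5 mm cartilage layer on bone under a joint cavity filled with
#' dual contrast agent (ioxaglate + BiNP), optionally carrying a blunt or
#' sharp groove with peri-lesion proteoglycan depletion (elevated ioxaglate
#' partition) and swelling, plus CT noise and an optional air bubble. Partial
#' volume is emulated by rendering at `supersample` x resolution and
#' box-downsampling. All randomness is governed by `seed`; identical
#' `(scenario, seed)` give bit-identical output.
#'
#' @param scenario a [scenario_config()].
#' @param seed integer seed; also indexes the joint-level biological draws.
#' @param draws optional list overriding the per-joint draws (fields
#'   `partition_mean`, `od_mean`, `thickness_mm`); by default derived
#'   deterministically from `seed`.
#' @return A list of class `joint_phantom` with elements `t0`, `t60`
#'   ([attenuation_volume()]s), `truth` (class `ground_truth`: `masks`,
#'   `partition_field`, `pg_field`, `surface_height_map`,
#'   `interface_height_map`, `voi_truth`, `draws`), `scenario` and `seed`.
#' @export
build_joint_phantom <- function(scenario, seed = 1, draws = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  validate_scenario(scenario)
  if (is.null(draws)) draws <- joint_draws(scenario, seed)
  g <- scenario$geometry
  if (any(g$dims < 8L)) stop("scan volumes need at least 8 voxels per axis", call. = FALSE)
  geom <- joint_geometry(scenario, draws)

  if (geom$grooved) {
    remaining <- geom$thickness_mm * (1 + scenario$uptake$lesion_swelling_frac) -
      scenario$groove_depth_um / 1000
    if (remaining < 2 * geom$h_mm - 1e-9) {
      stop("groove breaches the full cartilage thickness into bone", call. = FALSE)
    }
  }

  tmpl <- render_templates(scenario, geom)
  tt <- truth_templates(scenario, geom)
  nz <- g$dims[1]; ny <- g$dims[2]; nx <- g$dims[3]

  vox_t0 <- array(tmpl$t0, dim = c(nz, ny, nx))
  vox_t60 <- array(tmpl$t60, dim = c(nz, ny, nx))
  labels <- array(tt$labels, dim = c(nz, ny, nx))
  part <- array(tt$partition, dim = c(nz, ny, nx))
  surface_map <- matrix(tt$surface_idx, ny, nx)
  interface_map <- matrix(tt$interface_idx, ny, nx)

  # optional air bubble (carved at final resolution, air = g$air_hu)
  if (!is.null(scenario$bubble)) {
    b <- scenario$bubble
    h <- geom$h_mm
    dz2 <- ((seq_len(nz) - 0.5) * h - b$center_mm[1])^2
    dy2 <- ((seq_len(ny) - 0.5) * h - b$center_mm[2])^2
    dx2 <- ((seq_len(nx) - 0.5) * h - b$center_mm[3])^2
    sph <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= b$radius_mm^2
    inside <- sph & (labels == LABELS[["cavity"]] | labels == LABELS[["groove_void"]])
    if (any(inside)) {
      cols <- unique(which(inside, arr.ind = TRUE)[, 2])
      voi_cols <- c(geom$lesion_voi_cols,
                    geom$lesion_voi_cols + round(3 / geom$h_mm))
      if (any(cols %in% voi_cols) && !isTRUE(b$allow_over_voi)) {
        stop("bubble overlaps an analysis VOI footprint; set allow_over_voi = TRUE",
             call. = FALSE)
      }
      labels[inside] <- LABELS[["bubble"]]
      vox_t0[inside] <- g$air_hu
      vox_t60[inside] <- g$air_hu
    }
  }

  if (scenario$noise_sd_hu > 0) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    vox_t0 <- vox_t0 + array(stats::rnorm(length(vox_t0), 0, scenario$noise_sd_hu),
                             dim = dim(vox_t0))
    vox_t60 <- vox_t60 + array(stats::rnorm(length(vox_t60), 0, scenario$noise_sd_hu),
                               dim = dim(vox_t60))
  }

  pg <- 1 - part / scenario$uptake$p_max
  pg[pg < 0] <- 0
  pg[pg > 1] <- 1

  voi_truth <- tibble::tibble(
    role = c("lesion", "away_3mm", "contralateral"),
    mean_partition_pct = unname(draws$partition_mean),
    mean_od = unname(draws$od_mean)
  )

  meta <- list(kv = 90, mas = 200, scenario = scenario$name, seed = seed)
  truth <- structure(
    list(
      masks = labels, partition_field = part, pg_field = pg,
      surface_height_map = surface_map, interface_height_map = interface_map,
      thickness_mm = geom$thickness_mm,
      groove_columns = geom$groove_cols, lesion_voi_cols = geom$lesion_voi_cols,
      voi_truth = voi_truth, draws = draws
    ),
    class = "ground_truth"
  )
  structure(
    list(
      t0 = attenuation_volume(vox_t0, g$voxel_size_um, 0, meta),
      t60 = attenuation_volume(vox_t60, g$voxel_size_um, 60, meta),
      truth = truth, scenario = scenario, seed = seed
    ),
    class = "joint_phantom"
  )
}

#' @export
print.joint_phantom <- function(x, ...) {
  cat(sprintf("<joint_phantom> scenario '%s' (%s groove), seed %s\n",
              x$scenario$name, x$scenario$groove_kind, x$seed))
  cat(sprintf("  thickness %.3f mm; truth partitions: %s\n",
              x$truth$thickness_mm,
              paste(sprintf("%s %.1f%%", x$truth$voi_truth$role,
                            x$truth$voi_truth$mean_partition_pct), collapse = ", ")))
  invisible(x)
}

#' Derive the ungrooved control from a scenario
#'
#' The contralateral (sham-operated) joint of a pair: same anatomy and
#' contrast conditions, no groove, laterally homogeneous partition at the
#' contralateral truth mean.
#'
#' @param scenario a `scenario_config`.
#' @return A `scenario_config` with `groove_kind = "none"`.
#' @export
as_control <- function(scenario) {
  scenario$groove_kind <- "none"
  scenario$groove_width_um <- NA_real_
  scenario$name <- paste0(scenario$name, "_control")
  scenario
}

#' Build a grooved joint and its contralateral control
#'
#' @param scenario a grooved `scenario_config`.
#' @param seed seed for the grooved joint; the control joint uses a derived
#'   seed (same biological stream index, offset noise stream).
#' @return List of class `joint_pair` with `grooved` and `control`
#'   `joint_phantom`s and the shared `seed`.
#' @export
build_joint_pair <- function(scenario, seed = 1) {
  grooved <- build_joint_phantom(scenario, seed)
  ctrl_seed <- (seed + 1000000) %% .Machine$integer.max
  ctrl_scenario <- as_control(scenario)
  ctrl_draws <- joint_draws(scenario, seed)  # same animal: shared biology
  control <- build_joint_phantom(ctrl_scenario, ctrl_seed, draws = ctrl_draws)
  structure(list(grooved = grooved, control = control, seed = seed),
            class = "joint_pair")
}

#' Simulate homogeneous phantom-tube scans
#'
#' Water and BiNP suspension phantoms imaged separately from the joints: a
#' homogeneous tube (water at 0 HU; BiNP at the configured suspension offset)
#' in air, with the scanner's additive noise. The central cylindrical core at
#' 60 % of the tube radius serves as the measurement mask, avoiding
#' partial-volume rims.
#'
#' @param scenario a [scenario_config()] (supplies the BiNP offset and noise).
#' @param seed integer seed.
#' @return A list of class `phantom_scans`: `water`, `binp`
#'   ([attenuation_volume()]s), `tube_mask`, `core_mask` (logical arrays).
#' @export
make_phantom_scans <- function(scenario, seed = 1) {
  h_mm <- scenario$geometry$voxel_size_um / 1000
  dims <- c(40L, 40L, 24L)
  radius_mm <- 1.2
  cz <- dims[1] / 2 * h_mm; cy <- dims[2] / 2 * h_mm
  dz2 <- ((seq_len(dims[1]) - 0.5) * h_mm - cz)^2
  dy2 <- ((seq_len(dims[2]) - 0.5) * h_mm - cy)^2
  r2 <- outer(dz2, dy2, `+`)
  tube2d <- r2 <= radius_mm^2
  core2d <- r2 <= (0.6 * radius_mm)^2
  tube <- array(tube2d, dim = dims)
  core <- array(core2d, dim = dims)

  base <- function(fill) {
    v <- array(scenario$geometry$air_hu, dim = dims)
    v[tube] <- fill
    v
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  noise <- function(v) {
    if (scenario$noise_sd_hu > 0) {
      v + array(stats::rnorm(length(v), 0, scenario$noise_sd_hu), dim = dims)
    } else v
  }
  water <- noise(base(0))
  binp <- noise(base(scenario$binp_bath_hu_offset))
  structure(
    list(
      water = attenuation_volume(water, scenario$geometry$voxel_size_um, 0,
                                 list(phantom = "water")),
      binp = attenuation_volume(binp, scenario$geometry$voxel_size_um, 0,
                                list(phantom = "binp")),
      tube_mask = tube, core_mask = core, radius_mm = radius_mm
    ),
    class = "phantom_scans"
  )
}

#' Eroded cavity measurement mask
#'
#' The joint-cavity (dual-bath) attenuation is sampled away from tissue:
#' cavity-labelled voxels at least `margin_mm` above the articulating surface
#' in every column, excluding voxels within `margin_mm` of an air bubble.
#' This keeps partial-volume mixtures at the tissue and bubble boundaries out
#' of the bath measurement.
#'
#' @param truth a `ground_truth` (from [build_joint_phantom()]).
#' @param margin_mm erosion margin (default 0.3).
#' @param voxel_size_um voxel size of the depth axis (default 80).
#' @return Logical array marking the cavity ROI.
#' @export
cavity_roi <- function(truth, margin_mm = 0.3, voxel_size_um = 80) {
  stopifnot(inherits(truth, "ground_truth"))
  d <- dim(truth$masks)
  m_vox <- ceiling(margin_mm / (voxel_size_um / 1000))
  roi <- truth$masks == LABELS[["cavity"]]
  depth_idx <- array(seq_len(d[1]), dim = d)
  surf <- array(rep(truth$surface_height_map, each = d[1]), dim = d)
  roi <- roi & depth_idx <= surf - m_vox - 1L
  if (any(truth$masks == LABELS[["bubble"]])) {
    bub <- which(truth$masks == LABELS[["bubble"]], arr.ind = TRUE)
    lo <- pmax(apply(bub, 2, min) - m_vox, 1L)
    hi <- pmin(apply(bub, 2, max) + m_vox, d)
    roi[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- FALSE
  }
  roi
}
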