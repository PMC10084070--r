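test_that("slice averaging forms slab means and drops the remainder", {
  vol <- attenuation_volume(array(7, dim = c(4, 4, 12)))
  expect_identical(average_slices(vol, 1), vol)

  out <- average_slices(vol, 6, axis = 3)
  expect_equal(dim(out$voxels), c(4L, 4L, 2L))
  expect_true(all(out$voxels == 7))
  expect_equal(out$voxel_size_um[3], 480)

  ramp <- attenuation_volume(
    aperm(array(rep(1:12, each = 16), dim = c(4, 4, 12)), c(1, 2, 3))
  )
  slabs <- average_slices(ramp, 6, axis = 3)
  expect_equal(as.vector(slabs$voxels[1, 1, ]), c(3.5, 9.5))

  expect_error(average_slices(vol, 0), "positive")
  odd <- attenuation_volume(array(1, dim = c(4, 4, 13)))
  expect_message(average_slices(odd, 6, axis = 3), "dropping 1")
})

test_that("surface detection matches ground truth within one voxel", {
  cal <- phantom_calibration(0, 0, 1667)

  # noiseless: every column exact to a voxel
  ph <- build_joint_phantom(quiet_scenario("blunt", noise_sd_hu = 0), 1)
  avg <- suppressMessages(average_slices(ph$t60, 6, 3))
  surf <- detect_surface(avg, cal)
  truth <- truth_map_col(ph$truth, "surface")
  err <- abs(sweep(surf, 1, truth))
  expect_true(all(err <= 1))

  # default noise: at least 95 % of columns within one voxel, several seeds
  for (s in 1:5) {
    ph <- build_joint_phantom(quiet_scenario("blunt"), s)
    avg <- suppressMessages(average_slices(ph$t60, 6, 3))
    surf <- detect_surface(avg, cal)
    err <- abs(sweep(surf, 1, truth_map_col(ph$truth, "surface")))
    expect_gte(mean(err <= 1, na.rm = TRUE), 0.95)
  }
})

test_that("surface detection flags columns with no cavity contrast", {
  # cavity attenuates like cartilage: the measured bath equals the tissue
  # level and no crossing exists anywhere
  flat <- attenuation_volume(array(800, dim = c(20, 10, 6)))
  cal <- phantom_calibration(0, 0, 800)
  surf <- detect_surface(flat, cal)
  expect_true(all(is.na(surf)))
})

test_that("bone interface sits at the pre-rise attenuation minimum", {
  prof <- c(10, 8, 6, 4, 2, 5, 9, 14)     # minimum at index 5
  expect_equal(detect_bone_interface(prof, 1), 6L)
  expect_true(is.na(detect_bone_interface(1:10, 1)))  # monotone: flagged

  ph <- build_joint_phantom(quiet_scenario("blunt", noise_sd_hu = 0), 2)
  avg <- suppressMessages(average_slices(ph$t60, 6, 3))
  cal <- phantom_calibration(0, 0, 1667)
  maps <- segment_volume(avg, cal)
  err <- abs(sweep(maps$interface_idx, 1, truth_map_col(ph$truth, "interface")))
  expect_true(all(err <= 1, na.rm = TRUE))
  expect_true(all(!is.na(maps$interface_idx)))
})

test_that("thickness is recovered within a voxel on noiseless joints", {
  ph <- build_joint_phantom(quiet_scenario("blunt", noise_sd_hu = 0), 3)
  avg <- suppressMessages(average_slices(ph$t60, 6, 3))
  maps <- segment_volume(avg, phantom_calibration(0, 0, 1667))
  true_thick <- (truth_map_col(ph$truth, "interface") -
                   truth_map_col(ph$truth, "surface")) * 0.08
  err <- abs(sweep(maps$thickness_mm, 1, true_thick))
  expect_true(all(err <= 0.08 + 1e-9, na.rm = TRUE))

  noisy <- build_joint_phantom(quiet_scenario("blunt"), 3)
  avgn <- suppressMessages(average_slices(noisy$t60, 6, 3))
  mapsn <- segment_volume(avgn, phantom_calibration(0, 0, 1667))
  errn <- abs(sweep(mapsn$thickness_mm, 1, true_thick))
  expect_lte(median(errn, na.rm = TRUE), 0.08 + 1e-9)
})

test_that("groove localisation finds the channel and controls stay clean", {
  cal <- phantom_calibration(0, 0, 1667)
  for (name in c("blunt", "sharp")) {
    ph <- build_joint_phantom(quiet_scenario(name), 1)
    avg <- suppressMessages(average_slices(ph$t60, 6, 3))
    g <- locate_groove(segment_volume(avg, cal))
    true_center <- mean(ph$truth$groove_columns)
    expect_within(g$center[["dorsopalmar"]], true_center, 1)
    expect_gte(g$depth_vox, 4)
  }
  ctrl <- build_joint_phantom(quiet_scenario("control"), 1)
  avg <- suppressMessages(average_slices(ctrl$t60, 6, 3))
  expect_error(locate_groove(segment_volume(avg, cal)), "no groove found")
})

test_that("VOI footprints and placement follow the study design", {
  ph <- build_joint_phantom(quiet_scenario("blunt"), 1)
  # full-resolution grid: footprints in 80 um columns
  maps_fr <- list(surface_idx = matrix(15L, 96, 24))
  center <- c(dorsopalmar = 20, lateromedial = 12)
  les <- place_vois(center, maps_fr, "lesion", c(80, 80, 80))
  expect_length(les$cols_dorsopalmar[[1]], 6L)    # 0.48 / 0.08
  expect_length(les$cols_lateromedial[[1]], 6L)
  away <- place_vois(center, maps_fr, "away_3mm", c(80, 80, 80))
  expect_length(away$cols_dorsopalmar[[1]], 6L)
  expect_length(away$cols_lateromedial[[1]], 13L) # 1.04 / 0.08
  # centre-to-centreline distance 3.00 mm within half a voxel
  d_mm <- (away$center_dorsopalmar - les$center_dorsopalmar) * 0.08
  expect_within(d_mm, 3.0, 0.04)
  # mirrored contralateral placement
  con <- place_vois(center, maps_fr, "contralateral", c(80, 80, 80))
  expect_equal(con$center_dorsopalmar, 96 - 20 + 1)
  # out-of-bounds footprint errors
  expect_error(place_vois(c(dorsopalmar = 94, lateromedial = 12), maps_fr,
                          "away_3mm", c(80, 80, 80)), "bounds")
})

test_that("air-bubble QC excludes only joints with large cavity bubbles", {
  scen <- quiet_scenario("sharp")
  ph <- build_joint_phantom(scen, 1)
  cav <- ph$truth$masks == label_codes()[["cavity"]]
  clean <- detect_air_bubbles(ph$t60, cav)
  expect_false(clean$excluded)
  expect_equal(nrow(clean$bubbles), 0L)

  scen$bubble <- list(center_mm = c(0.6, 1.6, 0.96), radius_mm = 2,
                      allow_over_voi = TRUE)
  bub <- build_joint_phantom(scen, 1)
  cavb <- bub$truth$masks %in% label_codes()[c("cavity", "bubble")]
  rep <- detect_air_bubbles(bub$t60, array(cavb, dim = dim(bub$truth$masks)))
  expect_true(rep$excluded)
  expect_gte(max(rep$bubbles$volume_mm3), 5)
})

test_that("a cohort with one bubble joint keeps 17 of 18 joints", {
  # cheap proxy of the cohort fixture: per-joint QC decisions only
  decisions <- vapply(1:18, function(s) {
    scen <- quiet_scenario(if (s <= 9) "blunt" else "sharp")
    if (s == 18) {
      scen$bubble <- list(center_mm = c(0.6, 1.6, 0.96), radius_mm = 2,
                          allow_over_voi = TRUE)
    }
    ph <- build_joint_phantom(scen, s)
    cav <- ph$truth$masks %in% label_codes()[c("cavity", "bubble")]
    detect_air_bubbles(ph$t60, array(cav, dim = dim(ph$truth$masks)))$excluded
  }, logical(1))
  expect_equal(sum(!decisions), 17L)
  expect_true(decisions[18])
})
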