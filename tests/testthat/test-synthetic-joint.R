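test_that("seeded generation is bit-reproducible", {
  scen <- quiet_scenario("blunt")
  a <- build_joint_phantom(scen, 1)
  b <- build_joint_phantom(scen, 1)
  expect_identical(a$t0$voxels, b$t0$voxels)
  expect_identical(a$t60$voxels, b$t60$voxels)
  expect_identical(a$truth$partition_field, b$truth$partition_field)
  c <- build_joint_phantom(scen, 2)
  expect_false(identical(a$t60$voxels, c$t60$voxels))
})

test_that("labels partition the volume and geometry is layered", {
  ph <- build_joint_phantom(quiet_scenario("blunt"), 3)
  labs <- ph$truth$masks
  expect_true(all(labs %in% label_codes()))
  # every column: surface above interface, cartilage between them
  surf <- ph$truth$surface_height_map
  intf <- ph$truth$interface_height_map
  expect_true(all(intf > surf))
  d <- dim(labs)
  for (y in c(1, 20, 58, 77, d[2])) {
    col <- labs[, y, 1]
    s <- surf[y, 1]; i <- intf[y, 1]
    expect_true(all(col[s:(i - 1)] == label_codes()[["cartilage"]]))
    expect_true(all(col[i:d[1]] == label_codes()[["bone"]]))
    expect_true(all(col[seq_len(s - 1)] %in%
                      label_codes()[c("cavity", "groove_void")]))
  }
})

test_that("noiseless nearest-voxel rendering reproduces configured attenuations exactly", {
  scen <- exact_scenario("blunt")
  ph <- build_joint_phantom(scen, 1)
  labs <- ph$truth$masks
  expect_equal(unique(as.vector(ph$t60$voxels[labs == label_codes()[["cavity"]]])),
               scen$cavity_hu_t60)
  expect_equal(unique(as.vector(ph$t60$voxels[labs == label_codes()[["bone"]]])),
               scen$bone_hu)
  # t0 cartilage sits exactly at the native baseline (no uptake, no noise)
  cart <- labs == label_codes()[["cartilage"]]
  expect_equal(unique(as.vector(ph$t0$voxels[cart])), native_baseline(0))
  # t60 cartilage encodes the partition field exactly
  iox <- scen$cavity_hu_t60 - scen$binp_bath_hu_offset
  expected <- native_baseline(0) + ph$truth$partition_field[cart] / 100 * iox
  expect_equal(as.vector(ph$t60$voxels[cart]), expected)
})

test_that("cavity attenuation at t60 hits the 1667 HU set point", {
  ph <- build_joint_phantom(quiet_scenario("blunt"), 1)
  m <- measure_mask_mean(ph$t60, cavity_roi(ph$truth))
  se <- m$sd_hu / sqrt(m$n_voxels)
  expect_within(m$mean_hu, 1667, 3 * se + 0.5)
})

test_that("groove rasterization follows the nearest-voxel rule", {
  scen <- quiet_scenario("sharp")
  surf <- matrix(15L, scen$geometry$dims[2], scen$geometry$dims[3])
  cg <- carve_groove(surf, scen)
  expect_length(cg$groove_columns, 2L)           # 150 um at 80 um voxels
  expect_equal(cg$depth_vox, 5L)                 # 400 / 80
  expect_true(all(cg$surface_height_map[cg$groove_columns, ] == 20L))
  expect_true(all(cg$surface_height_map[-cg$groove_columns, ] == 15L))

  blunt <- carve_groove(surf, quiet_scenario("blunt"))
  expect_length(blunt$groove_columns, 6L)        # 500 um -> 6 voxels

  none <- carve_groove(surf, quiet_scenario("control"))
  expect_identical(none$surface_height_map, surf)
  expect_length(none$groove_columns, 0L)
})

test_that("rendered groove floor sits 5 voxels below the local surface", {
  ph <- build_joint_phantom(exact_scenario("blunt"), 1)
  tr <- ph$truth
  g <- tr$groove_columns
  expect_length(g, 6L)
  # floor depth relative to what the surface would be without the groove:
  # compare against a control joint sharing the same draws
  ctrl <- build_joint_phantom(as_control(exact_scenario("blunt")), 1,
                              draws = tr$draws)
  # the swollen grooved-joint surface differs from the control's, so measure
  # the void thickness instead: groove_void spans exactly 5 voxels
  void_span <- sapply(g, function(y) {
    sum(tr$masks[, y, 1] == label_codes()[["groove_void"]])
  })
  expect_true(all(abs(void_span - 5L) <= 1L))
})

test_that("uptake law is linear, inverse in PG, and calibrated to location means", {
  # degenerate calibration: uniform PG gives a constant field at the target
  pg <- array(1, dim = c(4, 4, 4))
  p <- simulate_uptake(pg, 60, target_mean = 41)
  expect_equal(unique(as.vector(p)), 41)
  expect_equal(unique(as.vector(simulate_uptake(pg, 0, target_mean = 41))), 0)

  # PG depletion raises the partition (monotonicity of the stated law)
  pg2 <- pg; pg2[1:2, , ] <- 0.5
  p2 <- simulate_uptake(pg2, 60, target_mean = 41)
  expect_true(mean(p2[1:2, , ]) > mean(p2[3:4, , ]))

  # rendered fields: perfect inverse correlation before clipping
  ph <- build_joint_phantom(exact_scenario("blunt"), 2)
  cart <- !is.na(ph$truth$partition_field)
  expect_equal(
    cor(ph$truth$pg_field[cart], ph$truth$partition_field[cart]),
    -1, tolerance = 1e-12
  )
})

test_that("truth fields are calibrated to the configured location means", {
  scen <- exact_scenario("blunt")
  # pin the joint-level draws at the scenario means
  draws <- list(
    partition_mean = c(lesion = 66, away_3mm = 45, contralateral = 42),
    od_mean = c(lesion = 0.7, away_3mm = 1.2, contralateral = 1.1),
    thickness_mm = 0.501
  )
  ph <- build_joint_phantom(scen, 1, draws = draws)
  tr <- ph$truth
  # lesion: mean of per-column full-thickness means over the VOI footprint
  les_cols <- tr$lesion_voi_cols
  col_means <- sapply(les_cols, function(y) {
    mean(tr$partition_field[, y, 1], na.rm = TRUE)
  })
  expect_within(mean(col_means), 66, 0.6)
  # far field (3 mm away) at the away mean
  away_cols <- les_cols + round(3 / 0.08)
  away_means <- sapply(away_cols, function(y) {
    mean(tr$partition_field[, y, 1], na.rm = TRUE)
  })
  expect_within(mean(away_means), 45, 0.6)
  # control joint: laterally homogeneous at the contralateral mean
  ctrl <- build_joint_phantom(as_control(scen), 1, draws = draws)
  cart <- !is.na(ctrl$truth$partition_field)
  prof_means <- apply(ctrl$truth$partition_field, 2,
                      function(m) mean(m, na.rm = TRUE))
  expect_true(all(abs(prof_means - 42) < 0.5))
})

test_that("invalid configurations are rejected", {
  expect_error(
    scenario_config(groove_kind = "blunt", groove_depth_um = 700),
    "breach"
  )
  expect_error(
    scenario_config(groove_kind = "blunt", groove_width_um = 10000),
    "wider"
  )
  scen <- quiet_scenario("blunt")
  scen$bubble <- list(center_mm = c(0.6, 1.6, 0.96), radius_mm = 1)
  expect_error(build_joint_phantom(scen, 1), "allow_over_voi")
  scen$bubble$allow_over_voi <- TRUE
  ph <- build_joint_phantom(scen, 1)
  expect_true(any(ph$truth$masks == label_codes()[["bubble"]]))
})

test_that("phantom tubes hit their set points", {
  scen <- exact_scenario("blunt")
  scans <- make_phantom_scans(scen, 1)
  expect_equal(measure_mask_mean(scans$water, scans$core_mask)$mean_hu, 0)
  expect_equal(measure_mask_mean(scans$binp, scans$core_mask)$mean_hu,
               scen$binp_bath_hu_offset)

  # with noise: two seeds agree within 3 standard errors
  noisy <- quiet_scenario("blunt")
  s1 <- make_phantom_scans(noisy, 1)
  s2 <- make_phantom_scans(noisy, 2)
  m1 <- measure_mask_mean(s1$water, s1$core_mask)
  m2 <- measure_mask_mean(s2$water, s2$core_mask)
  se <- sqrt(m1$sd_hu^2 / m1$n_voxels + m2$sd_hu^2 / m2$n_voxels)
  expect_within(m1$mean_hu, m2$mean_hu, 3 * se)
})
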