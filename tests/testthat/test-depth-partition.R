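flat_maps <- function(surface, interface, ny, nx) {
  s <- matrix(as.integer(surface), ny, nx)
  i <- matrix(as.integer(interface), ny, nx)
  structure(list(surface_idx = s, interface_idx = i,
                 thickness_mm = (i - s) * 0.08,
                 flagged = matrix(FALSE, ny, nx),
                 voxel_size_um = c(80, 80, 480)),
            class = "surface_maps")
}

small_voi <- function(ys, xs, role = "lesion") {
  structure(
    tibble::tibble(role = role, footprint_along_mm = 0.48,
                   footprint_across_mm = 0.48,
                   center_dorsopalmar = as.integer(stats::median(ys)),
                   center_lateromedial = as.integer(stats::median(xs)),
                   cols_dorsopalmar = list(as.integer(ys)),
                   cols_lateromedial = list(as.integer(xs))),
    class = c("voi_spec", "tbl_df", "tbl", "data.frame")
  )
}

test_that("column extraction clips to the cartilage span", {
  vol <- attenuation_volume(array(rep(1:20, 6 * 4), dim = c(20, 6, 4)))
  maps <- flat_maps(5, 11, 6, 4)
  voi <- small_voi(1:6, 1:2)
  cols <- extract_columns(vol, voi, maps)
  expect_length(cols$columns, 12L)
  expect_true(all(lengths(cols$columns) == 6L))   # [5, 11): 6 samples
  expect_equal(cols$columns[[1]], 5:10)

  # flagged columns drop; below 80 % usable errors out
  maps$flagged[1:3, ] <- TRUE
  expect_error(extract_columns(vol, voi, maps), "80%")
})

test_that("groove-floor columns are about five voxels shorter than rim columns", {
  ph <- build_joint_phantom(quiet_scenario("sharp", noise_sd_hu = 0), 1)
  avg <- suppressMessages(average_slices(ph$t60, 6, 3))
  maps <- segment_volume(avg, phantom_calibration(0, 0, 1667))
  g <- locate_groove(maps)
  voi <- place_vois(g$center, maps, "lesion", avg$voxel_size_um)
  cols <- extract_columns(avg, voi, maps)
  lens <- lengths(cols$columns)
  expect_within(max(lens) - min(lens), 5, 1)
})

test_that("depth normalization is exact for constants, ramps, and vs a brute-force oracle", {
  expect_equal(normalize_depth(list(rep(7, 6)), 10), matrix(7, 10, 1))

  ramp <- normalize_depth(list(seq(0, 10, length.out = 6)), 25)
  expect_equal(as.vector(ramp), seq(0, 10, length.out = 25))

  # brute-force linear interpolation oracle on an arbitrary column
  set.seed(42)
  v <- cumsum(rnorm(9))
  n_points <- 50
  oracle <- vapply(seq(0, 1, length.out = n_points), function(t) {
    x <- t * (length(v) - 1) + 1
    i <- min(floor(x), length(v) - 1)
    v[i] + (x - i) * (v[i + 1] - v[i])
  }, numeric(1))
  expect_lt(max(abs(normalize_depth(list(v), n_points) - oracle)), 1e-9)

  expect_warning(out <- normalize_depth(list(c(1, 2), 5), 10), "single-sample")
  expect_equal(ncol(out), 1L)
})

test_that("profile averaging records position-wise mean, SD and column count", {
  one <- mean_profile(matrix(1:5, 5, 1))
  expect_equal(one$value, 1:5)
  expect_equal(one$sd, rep(0, 5))
  expect_equal(attr(one, "n_columns"), 1L)

  two <- mean_profile(cbind(c(1, 2, 3), c(3, 4, 5)))
  expect_equal(two$value, c(2, 3, 4))
  expect_true(all(two$sd > 0))
})

test_that("partition conversion matches the reference worked examples", {
  cal <- phantom_calibration(0, 0, 1667)

  base <- mean_profile(matrix(50, 100, 1))
  expect_equal(attenuation_to_partition(base, cal)$value, rep(0, 100))

  bath <- mean_profile(matrix(50 + 1667, 100, 1))
  expect_equal(attenuation_to_partition(bath, cal)$value, rep(100, 100))

  # reference mean lesion attenuation 1054 HU against the 1667 HU bath: 60 %
  lesion <- mean_profile(matrix(1054, 100, 1))
  p <- full_thickness_mean(attenuation_to_partition(lesion, cal))
  expect_equal(round(p), 60)
  # reference ungrooved attenuation 747 HU: 42 %
  un <- mean_profile(matrix(747, 100, 1))
  expect_equal(round(full_thickness_mean(attenuation_to_partition(un, cal))), 42)

  bad <- phantom_calibration(0, 0, 1667); bad$iox_bath_hu <- 0
  expect_error(attenuation_to_partition(base, bad), "positive")
})

test_that("full-thickness mean is the unweighted mean over depth positions", {
  const <- mean_profile(matrix(42, 100, 1))
  expect_equal(full_thickness_mean(const), 42)
  lin <- mean_profile(matrix(seq(100, 0, length.out = 100), 100, 1))
  expect_equal(full_thickness_mean(lin), 50)
})

test_that("pipeline recovers ground-truth VOI partitions within 3 points", {
  for (s in 1:9) {
    scen <- cartipart_scenario(if (s %% 2) "blunt" else "sharp")
    pair <- build_joint_pair(scen, s)
    jr <- analyze_joint_pair(pair)
    truth <- pair$grooved$truth$voi_truth
    merged <- merge(jr$results, truth, by = "role")
    err <- abs(merged$mean_partition_pct.x - merged$mean_partition_pct.y)
    expect_true(all(err <= 3),
                label = sprintf("seed %d recovery errors %s", s,
                                paste(round(err, 2), collapse = "/")))
  }
})

test_that("partition is invariant to a common contrast-dose scaling", {
  scen <- quiet_scenario("blunt", noise_sd_hu = 0)
  scen2 <- scen
  scen2$cavity_hu_t60 <- scen$cavity_hu_t60 * 2   # doubles bath and uptake HU
  a <- analyze_joint_pair(build_joint_pair(scen, 5))
  b <- analyze_joint_pair(build_joint_pair(scen2, 5))
  expect_equal(a$results$mean_partition_pct, b$results$mean_partition_pct,
               tolerance = 0.02)
})

test_that("control profiles are depth-smooth after averaging", {
  pair <- build_joint_pair(cartipart_scenario("blunt"), 6)
  jr <- analyze_joint_pair(pair)
  prof <- jr$results$profile[[which(jr$results$role == "contralateral")]]
  expect_lt(max(abs(diff(prof$value))), 10)
})
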