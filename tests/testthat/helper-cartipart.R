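# shared fixtures: small deterministic scenarios built in code

quiet_scenario <- function(name = "blunt", ...) {
  scen <- cartipart_scenario(name)
  mods <- list(...)
  for (nm in names(mods)) scen[[nm]] <- mods[[nm]]
  scen
}

# noiseless, nearest-voxel-rendered scenario: rendering equals the label rule,
# so mask means reproduce configured attenuations exactly
exact_scenario <- function(name = "blunt", ...) {
  quiet_scenario(name, noise_sd_hu = 0, supersample = 1L, ...)
}

# flat truth maps are constant along the lateromedial axis; collapse for
# comparisons against detected maps on the slab-averaged grid
truth_map_col <- function(truth, what = "surface") {
  m <- if (what == "surface") truth$surface_height_map else truth$interface_height_map
  m[, 1]
}

expect_within <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol + 1e-9,
              label = sprintf("|%.3f - %.3f| <= %.3f", object, expected, tol))
}
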