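test_that("lumen voxels carry the contrast attenuation by construction", {
  ph <- straight_phantom()
  cfg <- ph$config
  centers <- stentfai:::voxel_centers(ph$volume)
  ax <- ph$truth$centerline$points[1, 1:2]
  r <- sqrt((centers[, 1] - ax[1])^2 + (centers[, 2] - ax[2])^2)
  hu <- as.vector(ph$volume$data)
  expect_true(all(hu[r < cfg$lumen_radius_mm] == cfg$lumen_hu))
  # and the truth lumen mask is exactly the voxel-center rule
  expect_identical(as.vector(ph$truth$lumen_mask), r < cfg$lumen_radius_mm)
})

test_that("phantom generation is bitwise deterministic under a fixed seed", {
  cfg <- phantom_config(noise_sd_hu = 5, seed = 11)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$shell_mask, b$truth$shell_mask)
  c2 <- generate_phantom(phantom_config(noise_sd_hu = 5, seed = 12))
  expect_false(identical(a$volume$data, c2$volume$data))
})

test_that("shell-voxel mean attenuation matches the configured fat mean", {
  ph <- generate_phantom(phantom_config(fat_mean_hu = -78.1, fat_sd_hu = 6.2,
                                        noise_sd_hu = 0, seed = 21))
  hu <- ph$volume$data[ph$truth$shell_mask]
  fat <- hu < -30  # wall voxels intruding on the shell sit at +40 HU
  se <- 6.2 / sqrt(sum(fat))
  expect_lt(abs(mean(hu[fat]) - (-78.1)), 3 * se)
})

test_that("truth masks are mutually disjoint and diameters positive", {
  for (ph in list(straight_phantom(), helical_phantom())) {
    expect_false(any(ph$truth$lumen_mask & ph$truth$stent_mask))
    expect_false(any(ph$truth$lumen_mask & ph$truth$shell_mask))
    expect_false(any(ph$truth$stent_mask & ph$truth$shell_mask))
    expect_gt(ph$truth$min_stent_diameter_mm, 0)
    expect_gt(ph$truth$reference_diameter_mm, 0)
  }
})

test_that("invalid phantom geometry is rejected", {
  expect_error(generate_phantom(phantom_config(stent_end_mm = 1e4)),
               "outside curve")
  expect_error(generate_phantom(phantom_config(dims = c(12, 12, 60))),
               "too small")
  expect_error(phantom_config(stent_start_mm = 10, stent_end_mm = 9))
  expect_error(phantom_config(stenosis_severity = 1.5))
})

test_that("fat_fraction mixes in non-fat contaminant voxels", {
  ph <- generate_phantom(phantom_config(fat_fraction = 0.5, noise_sd_hu = 0,
                                        seed = 31))
  hu <- ph$volume$data[ph$truth$shell_mask]
  # shell includes a thin wall ring; restrict to the fat compartment proper
  frac_fat <- mean(hu < -30)
  expect_gt(frac_fat, 0.3)
  expect_lt(frac_fat, 0.6)
})
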