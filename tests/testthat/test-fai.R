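test_that("straight-vessel shell volume matches the analytic annulus", {
  ph <- straight_phantom()
  ann <- ph$truth$annotation
  shell <- build_pvat_shell(ph$volume, ph$truth$centerline, ann)
  vol <- sum(shell) * prod(ph$volume$spacing)
  L <- ann$end_mm - ann$start_mm
  analytic <- 2 * pi * ann$diameter_mm^2 * L
  expect_lt(abs(vol / analytic - 1), 0.05)
})

test_that("shell mask construction matches the phantom truth mask", {
  ph <- straight_phantom()
  shell <- build_pvat_shell(ph$volume, ph$truth$centerline,
                            ph$truth$annotation)
  expect_identical(shell, ph$truth$shell_mask)
})

test_that("degenerate shell configurations error", {
  ph <- straight_phantom()
  expect_error(fai_config(thickness_multiplier = 0))
  ann0 <- ph$truth$annotation
  ann0$end_mm <- ann0$start_mm + 1e-12
  expect_error(build_pvat_shell(ph$volume, ph$truth$centerline, ann0),
               "extent")
})

test_that("windowed mean follows forced arithmetic", {
  g <- voxel_grid(array(0, c(2, 2, 1)), 1)
  g$data[] <- c(-200, -100, -60, -20)
  mask <- array(TRUE, c(2, 2, 1))
  m <- compute_fai(g, mask)
  expect_equal(m$fai_hu, -80)
  expect_equal(m$n_shell, 4L)
  expect_equal(m$n_window, 2L)
  expect_equal(m$window_fraction, 0.5)
  # identity: uniform -80 shell
  g$data[] <- -80
  expect_equal(compute_fai(g, mask)$fai_hu, -80)
})

test_that("a shell with no adipose-window voxels is an error", {
  g <- voxel_grid(array(100, c(3, 3, 3)), 1)
  expect_error(compute_fai(g, array(TRUE, c(3, 3, 3))),
               class = "no_adipose_voxels")
})

test_that("FAI equals the brute-force voxel loop on a small grid", {
  cfg <- phantom_config(dims = c(32, 32, 32), lumen_radius_mm = 1.0,
                        strut_thickness_mm = 0.25, stent_start_mm = 5,
                        stent_end_mm = 11, noise_sd_hu = 0, seed = 13)
  ph <- generate_phantom(cfg)
  m <- measure_peristent_fai(ph$volume, ph$truth$centerline,
                             ph$truth$annotation)
  # independent brute force: loop every voxel, apply the geometric and
  # window predicates against the analytic straight axis
  d <- dim(ph$volume$data)
  ax <- ph$truth$centerline$points[1, 1:2]
  R <- ph$truth$annotation$diameter_mm / 2
  D <- ph$truth$annotation$diameter_mm
  vals <- c()
  n_shell <- 0L
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    x <- (i - 1) * 0.5; y <- (j - 1) * 0.5; z <- (k - 1) * 0.5
    r <- sqrt((x - ax[1])^2 + (y - ax[2])^2)
    if (z >= 5 && z <= 11 && r > R && r <= R + D) {
      n_shell <- n_shell + 1L
      hu <- ph$volume$data[i, j, k]
      if (hu >= -190 && hu <= -30) vals <- c(vals, hu)
    }
  }
  expect_equal(m$n_shell, n_shell)
  expect_equal(m$n_window, length(vals))
  expect_equal(m$fai_hu, mean(vals))
})

test_that("FAI is monotone in shell attenuation and window-bounded", {
  g <- voxel_grid(array(-300, c(4, 4, 4)), 1)
  mask <- array(FALSE, c(4, 4, 4))
  mask[2:3, 2:3, 2:3] <- TRUE
  set.seed(1)
  g$data[mask] <- runif(sum(mask), -120, -60)
  f1 <- compute_fai(g, mask)$fai_hu
  g2 <- g
  g2$data[mask] <- g$data[mask] + 5  # still inside the window
  f2 <- compute_fai(g2, mask)$fai_hu
  expect_gt(f2, f1)
  expect_gte(f1, -190); expect_lte(f1, -30)
  # narrowing the window bounds the mean from below
  cfg <- fai_config(window_hu = c(-80, -30))
  g$data[mask] <- rnorm(sum(mask), -90, 10)
  expect_gte(compute_fai(g, mask, cfg)$fai_hu, -80)
})

test_that("matched ISR-condition phantoms read higher FAI than non-ISR", {
  n_pairs <- 8
  higher <- logical(n_pairs)
  for (i in seq_len(n_pairs)) {
    base <- list(noise_sd_hu = 2)
    ph1 <- generate_phantom(phantom_config(fat_mean_hu = -78.1,
                                           fat_sd_hu = 6.2,
                                           noise_sd_hu = 2, seed = 200 + i))
    ph0 <- generate_phantom(phantom_config(fat_mean_hu = -87.2,
                                           fat_sd_hu = 7.3,
                                           noise_sd_hu = 2, seed = 500 + i))
    f1 <- measure_peristent_fai(ph1$volume, ph1$truth$centerline,
                                ph1$truth$annotation)$fai_hu
    f0 <- measure_peristent_fai(ph0$volume, ph0$truth$centerline,
                                ph0$truth$annotation)$fai_hu
    higher[i] <- f1 > f0
  }
  expect_true(all(higher))
})

test_that("noise-free uniform fat is measured exactly", {
  ph <- generate_phantom(phantom_config(fat_mean_hu = -90, fat_sd_hu = 0,
                                        noise_sd_hu = 0, seed = 3))
  m <- measure_peristent_fai(ph$volume, ph$truth$centerline,
                             ph$truth$annotation)
  expect_equal(m$fai_hu, -90)
})

test_that("no shell voxel lies within the stent radius of the centerline", {
  ph <- straight_phantom()
  shell <- build_pvat_shell(ph$volume, ph$truth$centerline,
                            ph$truth$annotation)
  centers <- stentfai:::voxel_centers(ph$volume, which(shell))
  ax <- ph$truth$centerline$points[1, 1:2]
  r <- sqrt((centers[, 1] - ax[1])^2 + (centers[, 2] - ax[2])^2)
  expect_true(all(r > ph$truth$annotation$diameter_mm / 2))
})

test_that("stent_edges extent widens the shell longitudinally", {
  ph <- straight_phantom()
  s1 <- build_pvat_shell(ph$volume, ph$truth$centerline,
                         ph$truth$annotation, fai_config())
  s2 <- build_pvat_shell(ph$volume, ph$truth$centerline,
                         ph$truth$annotation,
                         fai_config(extent = "stent_edges"))
  expect_gt(sum(s2), sum(s1))
  expect_true(all(s1[s2 == FALSE] == FALSE))
})
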