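# Shared phantom fixtures, generated once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

# Noise-free straight-tube phantom at the default geometry.
straight_phantom <- function() {
  fixture("straight", function() {
    generate_phantom(phantom_config(noise_sd_hu = 0, seed = 42))
  })
}

straight_centerline <- function() {
  fixture("straight_cl", function() {
    ph <- straight_phantom()
    extract_centerline(voxel_grid(ph$truth$lumen_mask, ph$volume$spacing))
  })
}

helical_phantom <- function() {
  fixture("helical", function() {
    generate_phantom(phantom_config(
      dims = c(72, 72, 60),
      curve = list(type = "helical", radius = 4, pitch = 60),
      noise_sd_hu = 0, seed = 43))
  })
}

# High-resolution phantom with a 50% diameter stenosis mid-stent.
stenosed_phantom <- function() {
  fixture("stenosed", function() {
    generate_phantom(phantom_config(
      dims = c(108, 108, 144), spacing_mm = 0.25,
      stenosis_severity = 0.5, stent_start_mm = 12, stent_end_mm = 24,
      noise_sd_hu = 0, seed = 44))
  })
}

# Axis-aligned tube volume (no stent) along a chosen axis; for
# rotation-invariance checks.
tube_along <- function(axis, radius = 1.5, hu_in = 350, hu_out = 40,
                       n_lat = 33, n_ax = 40, spacing = 0.5) {
  dims <- c(n_lat, n_lat, n_lat)
  dims[axis] <- n_ax
  g <- voxel_grid(array(hu_out, dims), spacing)
  centers <- stentfai:::voxel_centers(g)
  lat <- setdiff(1:3, axis)
  c0 <- (dims - 1) / 2 * spacing
  r <- sqrt((centers[, lat[1]] - c0[lat[1]])^2 +
              (centers[, lat[2]] - c0[lat[2]])^2)
  g$data[r < radius] <- hu_in
  ends <- matrix(c0, 2, 3, byrow = TRUE)
  ends[1, axis] <- 0
  ends[2, axis] <- (dims[axis] - 1) * spacing
  mid <- (ends[1, ] + ends[2, ]) / 2
  list(volume = g, cl = centerline(rbind(ends[1, ], mid, ends[2, ])))
}
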