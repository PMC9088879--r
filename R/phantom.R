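#' Configuration for a synthetic CT vessel/stent phantom
#'
#' Describes a contrast-filled vessel (straight or helical-arc centerline)
#' with a stented segment, a soft-tissue wall, an annular stent strut layer,
#' a perivascular fat compartment and a soft-tissue background, voxelised on
#' a regular grid. Geometry mirrors a coronary CT angiogram closely enough
#' for the downstream centerline, lumen-profile and fat-attenuation
#' measurements to be validated against known ground truth.
#'
#' The nominal stent diameter is `2 * (lumen_radius + strut_thickness)`
#' (outer strut surface); the perivascular fat compartment extends from the
#' outer wall to `fat_outer_radius` (default large enough to contain a
#' peri-stent shell of one stent diameter thickness).
#'
#' An in-stent stenosis can be simulated: the lumen radius is reduced by a
#' smooth squared-cosine bump of depth `stenosis_severity` (fraction of the
#' radius) and full width `stenosis_length_mm`, centred mid-stent, with the
#' displaced lumen replaced by soft tissue (neointima).
#'
#' @param dims Grid size in voxels per axis (length 3).
#' @param spacing_mm Isotropic voxel spacing, mm.
#' @param curve `list(type = "straight")` for an axial tube, or
#'   `list(type = "helical", radius = , pitch = )` for a helical arc
#'   (radius and pitch in mm).
#' @param lumen_radius_mm Unstented lumen radius, mm.
#' @param wall_thickness_mm Vessel wall thickness, mm.
#' @param strut_thickness_mm Stent strut annulus thickness, mm.
#' @param stent_start_mm,stent_end_mm Stent extent in arc length, mm.
#' @param strut_hu,lumen_hu,wall_hu Attenuations (HU) of struts, contrast
#'   lumen and vessel wall/neointima.
#' @param background_mean_hu,background_sd_hu Background soft-tissue
#'   attenuation distribution (HU).
#' @param fat_mean_hu,fat_sd_hu Perivascular fat attenuation distribution
#'   (HU); calibrate to the adipose window \[−190, −30\].
#' @param fat_fraction Fraction of perivascular-compartment voxels drawn
#'   from the fat distribution (remainder from the background distribution).
#' @param fat_outer_radius_mm Outer radius of the fat compartment, mm;
#'   `NULL` = 1.5 stent diameters + one voxel.
#' @param stenosis_severity Fractional diameter reduction at the stenosis
#'   apex, in \[0, 1\].
#' @param stenosis_length_mm Full width of the stenosis bump, mm; `NULL` =
#'   half the stent length.
#' @param noise_sd_hu SD of additive Gaussian image noise, HU.
#' @param seed RNG seed; a fixed seed gives a bitwise-identical volume.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(dims = c(54, 54, 60),
                           spacing_mm = 0.5,
                           curve = list(type = "straight"),
                           lumen_radius_mm = 1.5,
                           wall_thickness_mm = 0.5,
                           strut_thickness_mm = 0.25,
                           stent_start_mm = 9,
                           stent_end_mm = 21,
                           strut_hu = 800,
                           lumen_hu = 350,
                           wall_hu = 40,
                           background_mean_hu = 40,
                           background_sd_hu = 10,
                           fat_mean_hu = -87.2,
                           fat_sd_hu = 7.3,
                           fat_fraction = 1,
                           fat_outer_radius_mm = NULL,
                           stenosis_severity = 0,
                           stenosis_length_mm = NULL,
                           noise_sd_hu = 0,
                           seed = 1) {
  cfg <- list(dims = as.integer(dims), spacing_mm = spacing_mm,
              curve = curve, lumen_radius_mm = lumen_radius_mm,
              wall_thickness_mm = wall_thickness_mm,
              strut_thickness_mm = strut_thickness_mm,
              stent_start_mm = stent_start_mm, stent_end_mm = stent_end_mm,
              strut_hu = strut_hu, lumen_hu = lumen_hu, wall_hu = wall_hu,
              background_mean_hu = background_mean_hu,
              background_sd_hu = background_sd_hu,
              fat_mean_hu = fat_mean_hu, fat_sd_hu = fat_sd_hu,
              fat_fraction = fat_fraction,
              fat_outer_radius_mm = fat_outer_radius_mm,
              stenosis_severity = stenosis_severity,
              stenosis_length_mm = stenosis_length_mm,
              noise_sd_hu = noise_sd_hu, seed = seed)
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

stent_diameter_mm <- function(config) {
  2 * (config$lumen_radius_mm + config$strut_thickness_mm)
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$dims) != 3L || any(cfg$dims < 4L))
    stopf("`dims` must be 3 integers >= 4")
  if (!is_number(cfg$spacing_mm) || cfg$spacing_mm <= 0)
    stopf("`spacing_mm` must be > 0")
  if (!is_number(cfg$lumen_radius_mm) || cfg$lumen_radius_mm <= 0)
    stopf("`lumen_radius_mm` must be > 0")
  if (cfg$stent_end_mm <= cfg$stent_start_mm)
    stopf("stent extent must have end > start")
  if (cfg$stenosis_severity < 0 || cfg$stenosis_severity > 1)
    stopf("`stenosis_severity` must be in [0, 1]")
  if (cfg$fat_fraction < 0 || cfg$fat_fraction > 1)
    stopf("`fat_fraction` must be in [0, 1]")
  if (!cfg$curve$type %in% c("straight", "helical"))
    stopf("curve type must be 'straight' or 'helical'")
  invisible(cfg)
}

# True centerline of the configured curve, sampled at `step` mm, spanning
# the grid's axial extent.
phantom_true_centerline <- function(config, step = 0.25) {
  d <- config$dims; sp <- config$spacing_mm
  cx <- (d[1] - 1) / 2 * sp
  cy <- (d[2] - 1) / 2 * sp
  z_max <- (d[3] - 1) * sp
  if (config$curve$type == "straight") {
    z <- seq(0, z_max, by = step)
    if (z[length(z)] < z_max) z <- c(z, z_max)
    pts <- cbind(cx, cy, z)
  } else {
    R <- config$curve$radius
    pitch <- config$curve$pitch
    dz_dtheta <- pitch / (2 * pi)
    ds_dtheta <- sqrt(R^2 + dz_dtheta^2)
    theta_max <- z_max / dz_dtheta
    theta <- seq(0, theta_max, by = step / ds_dtheta)
    if (theta[length(theta)] < theta_max) theta <- c(theta, theta_max)
    pts <- cbind(cx + R * (cos(theta) - 1),
                 cy + R * sin(theta),
                 dz_dtheta * theta)
  }
  centerline(pts)
}

#' Generate a CT phantom volume with ground truth
#'
#' Voxelises the configured vessel by the voxel-center rule: each voxel is
#' assigned the attenuation of the compartment (lumen, neointima/wall, stent
#' strut, perivascular fat, background) containing its center, by radial
#' distance from the centerline. Fat-compartment voxels are drawn i.i.d.
#' from `N(fat_mean_hu, fat_sd_hu^2)` (with probability `fat_fraction`;
#' otherwise from the background distribution), background voxels from
#' `N(background_mean_hu, background_sd_hu^2)`. Additive Gaussian image
#' noise is applied last; the truth masks are noise-free.
#'
#' @param config A [phantom_config()].
#' @return A list of class `phantom` with `volume` (a [voxel_grid()]) and
#'   `truth`: the true `centerline`, logical `lumen_mask`, `stent_mask` and
#'   `shell_mask` arrays, the [stent_annotation()], the fat parameters used,
#'   and the true minimal in-stent and proximal reference lumen diameters
#'   (mm).
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  cfg <- config
  sp <- cfg$spacing_mm
  d_stent <- stent_diameter_mm(cfg)
  fat_outer <- cfg$fat_outer_radius_mm
  if (is.null(fat_outer)) fat_outer <- 1.5 * d_stent + sp
  cl <- phantom_true_centerline(cfg)
  total_len <- arc_length(cl)
  if (cfg$stent_start_mm < 0 || cfg$stent_end_mm > total_len)
    stopf("stent extent [%.1f, %.1f] mm outside curve length %.2f mm",
          cfg$stent_start_mm, cfg$stent_end_mm, total_len)
  # lateral fit: shell outer radius (1.5 stent diameters) must lie inside
  half_x <- (cfg$dims[1] - 1) / 2 * sp
  half_y <- (cfg$dims[2] - 1) / 2 * sp
  excur <- if (cfg$curve$type == "helical") 2 * cfg$curve$radius else 0
  need <- 1.5 * d_stent + excur
  if (need > min(half_x, half_y))
    stopf("grid too small to contain the perivascular shell (need %.1f mm half-width, have %.1f mm)",
          need, min(half_x, half_y))

  grid <- voxel_grid(array(0, cfg$dims), sp)
  centers <- voxel_centers(grid)
  if (cfg$curve$type == "straight") {
    axis_xy <- cl$points[1, 1:2]
    r <- sqrt((centers[, 1] - axis_xy[1])^2 + (centers[, 2] - axis_xy[2])^2)
    s <- centers[, 3]
  } else {
    pr <- project_to_polyline(centers, cl)
    r <- pr$r; s <- pr$s
  }

  # lumen radius profile along arc length (stenosis bump mid-stent)
  sten_len <- cfg$stenosis_length_mm
  if (is.null(sten_len)) sten_len <- (cfg$stent_end_mm - cfg$stent_start_mm) / 2
  mid <- (cfg$stent_start_mm + cfg$stent_end_mm) / 2
  bump <- numeric(length(s))
  if (cfg$stenosis_severity > 0 && sten_len > 0) {
    inb <- abs(s - mid) < sten_len / 2
    bump[inb] <- cos(pi * (s[inb] - mid) / sten_len)^2
  }
  r_lumen <- cfg$lumen_radius_mm * (1 - cfg$stenosis_severity * bump)

  in_stent <- s >= cfg$stent_start_mm & s <= cfg$stent_end_mm
  r0 <- cfg$lumen_radius_mm
  lumen <- r < r_lumen
  strut <- in_stent & r >= r0 & r < r0 + cfg$strut_thickness_mm
  wall_outer <- r0 + cfg$wall_thickness_mm
  wall <- !lumen & !strut & r < wall_outer
  fat <- !lumen & !strut & !wall & r < fat_outer

  hu <- numeric(length(r))
  with_seed(cfg$seed, {
    n_fat <- sum(fat)
    hu[lumen] <- cfg$lumen_hu
    hu[strut] <- cfg$strut_hu
    hu[wall] <- cfg$wall_hu
    bg <- !(lumen | strut | wall | fat)
    hu[bg] <- stats::rnorm(sum(bg), cfg$background_mean_hu, cfg$background_sd_hu)
    if (n_fat > 0) {
      from_fat <- stats::runif(n_fat) <= cfg$fat_fraction
      fat_hu <- numeric(n_fat)
      fat_hu[from_fat] <- stats::rnorm(sum(from_fat), cfg$fat_mean_hu, cfg$fat_sd_hu)
      fat_hu[!from_fat] <- stats::rnorm(sum(!from_fat), cfg$background_mean_hu,
                                        cfg$background_sd_hu)
      hu[fat] <- fat_hu
    }
    if (cfg$noise_sd_hu > 0)
      hu <- hu + stats::rnorm(length(hu), 0, cfg$noise_sd_hu)
  })
  grid$data <- array(hu, cfg$dims)

  R_in <- d_stent / 2
  shell <- in_stent & r > R_in & r <= R_in + d_stent
  ann <- stent_annotation(vessel = "LAD", segment = "middle",
                          start_mm = cfg$stent_start_mm,
                          end_mm = cfg$stent_end_mm,
                          diameter_mm = d_stent,
                          stent_class = "DES")
  truth <- list(
    centerline = cl,
    lumen_mask = array(lumen, cfg$dims),
    stent_mask = array(strut, cfg$dims),
    shell_mask = array(shell, cfg$dims),
    annotation = ann,
    fat_mean_hu = cfg$fat_mean_hu,
    fat_sd_hu = cfg$fat_sd_hu,
    min_stent_diameter_mm = 2 * cfg$lumen_radius_mm *
      (1 - cfg$stenosis_severity),
    reference_diameter_mm = 2 * cfg$lumen_radius_mm
  )
  structure(list(volume = grid, truth = truth, config = cfg),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>\n")
  print(x$volume)
  cat(sprintf("  stent [%.1f, %.1f] mm, diameter %.2f mm; fat N(%.1f, %.1f^2) HU\n",
              x$config$stent_start_mm, x$config$stent_end_mm,
              stent_diameter_mm(x$config),
              x$config$fat_mean_hu, x$config$fat_sd_hu))
  invisible(x)
}
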