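#' Configuration for the peri-stent fat attenuation index
#'
#' Perivascular adipose tissue (PVAT) around a stent is the annular shell
#' whose inner boundary is the outer stent surface (radius = stent
#' diameter / 2 from the centerline) and whose radial thickness equals
#' `thickness_multiplier` stent diameters, following the convention that
#' PVAT extends a radial distance equal to the vessel diameter. The FAI is
#' the mean attenuation of shell voxels inside the adipose Hounsfield
#' window (inclusive at both ends).
#'
#' @param window_hu Adipose attenuation window `c(low, high)`, HU.
#' @param thickness_multiplier Shell thickness as a multiple of the stent
#'   diameter (> 0).
#' @param extent `"stent"` (shell over the stented segment only, default)
#'   or `"stent_edges"` (extended 5 mm beyond either end, matching the ISR
#'   edge definition).
#' @param edge_mm Edge margin used when `extent = "stent_edges"`, mm.
#' @return A `fai_config` list.
#' @export
fai_config <- function(window_hu = c(-190, -30), thickness_multiplier = 1,
                       extent = c("stent", "stent_edges"), edge_mm = 5) {
  extent <- match.arg(extent)
  if (length(window_hu) != 2L || window_hu[1] >= window_hu[2])
    stopf("HU window must be c(low, high) with low < high")
  if (!is_number(thickness_multiplier) || thickness_multiplier <= 0)
    stopf("`thickness_multiplier` must be > 0")
  structure(list(window_hu = as.numeric(window_hu),
                 thickness_multiplier = thickness_multiplier,
                 extent = extent, edge_mm = edge_mm),
            class = "fai_config")
}

#' Build the peri-stent perivascular shell mask
#'
#' A voxel belongs to the shell iff (a) the arc position of its center's
#' orthogonal projection onto the centerline lies within the longitudinal
#' extent (the stented segment, optionally extended by the edge margin),
#' and (b) its radial distance r from the centerline satisfies
#' `R < r <= R + D`, with `R` = stent diameter / 2 (outer stent surface)
#' and `D` = `thickness_multiplier` x stent diameter.
#'
#' @param grid A [voxel_grid()] (only its geometry is used).
#' @param cl A [centerline()].
#' @param annotation A [stent_annotation()].
#' @param config A [fai_config()].
#' @return Logical 3D array, same dimensions as `grid`.
#' @export
build_pvat_shell <- function(grid, cl, annotation, config = fai_config()) {
  a <- annotation$start_mm
  b <- annotation$end_mm
  if (config$extent == "stent_edges") {
    a <- a - config$edge_mm
    b <- b + config$edge_mm
  }
  a <- max(a, 0)
  b <- min(b, arc_length(cl))
  if (b - a <= 1e-9)
    stopf("empty longitudinal extent for the perivascular shell")
  R <- annotation$diameter_mm / 2
  D <- config$thickness_multiplier * annotation$diameter_mm
  d <- dim(grid$data)

  # restrict to the bounding box of the relevant centerline span
  span <- cl$points[cl$arc >= a - grid$spacing[1] &
                      cl$arc <= b + grid$spacing[1], , drop = FALSE]
  if (nrow(span) == 0L) span <- cl$points
  margin <- R + D + max(grid$spacing)
  lo <- pmax(ceiling((apply(span, 2, min) - margin - grid$origin) /
                       grid$spacing) + 1, 1)
  hi <- pmin(floor((apply(span, 2, max) + margin - grid$origin) /
                     grid$spacing) + 1, d)
  if (any(lo > hi)) return(array(FALSE, d))
  sub_idx <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                   k = lo[3]:hi[3]))
  centers <- sweep(sweep(sub_idx - 1, 2, grid$spacing, "*"),
                   2, grid$origin, "+")
  pr <- project_to_polyline(centers, cl)
  inside <- pr$s >= a & pr$s <= b & pr$r > R & pr$r <= R + D
  mask <- array(FALSE, d)
  mask[sub_idx[inside, , drop = FALSE]] <- TRUE
  mask
}

#' Compute the fat attenuation index over a shell mask
#'
#' FAI = mean HU over shell voxels whose attenuation lies inside the
#' adipose window (both ends inclusive). Lumen, stent and wall voxels that
#' geometrically intrude on the shell are excluded automatically because
#' their attenuation falls outside the window.
#'
#' @param volume A [voxel_grid()].
#' @param shell_mask Logical array aligned to `volume` (e.g. from
#'   [build_pvat_shell()]).
#' @param config A [fai_config()].
#' @return Object of class `fai_measurement`: `fai_hu`, `n_shell`,
#'   `n_window`, `window_fraction`, `shell_volume_mm3`, `window_hu`.
#' @export
compute_fai <- function(volume, shell_mask, config = fai_config()) {
  if (!identical(dim(shell_mask), dim(volume$data)))
    stopf("shell mask dimensions do not match the volume")
  shell_mask <- as_mask(shell_mask)
  hu <- volume$data[shell_mask]
  n_shell <- length(hu)
  inw <- hu >= config$window_hu[1] & hu <= config$window_hu[2]
  n_window <- sum(inw)
  if (n_window == 0L)
    stopf("no adipose voxels: no shell attenuation inside [%g, %g] HU",
          config$window_hu[1], config$window_hu[2],
          class = "no_adipose_voxels")
  structure(list(fai_hu = mean(hu[inw]),
                 n_shell = n_shell,
                 n_window = n_window,
                 window_fraction = n_window / n_shell,
                 shell_volume_mm3 = n_shell * prod(volume$spacing),
                 window_hu = config$window_hu),
            class = "fai_measurement")
}

#' Measure the peri-stent FAI end to end
#'
#' Builds the peri-stent perivascular shell from the centerline and stent
#' annotation, then averages the in-window shell attenuation.
#'
#' @inheritParams build_pvat_shell
#' @param volume A [voxel_grid()].
#' @return A `fai_measurement` (see [compute_fai()]).
#' @export
measure_peristent_fai <- function(volume, cl, annotation,
                                  config = fai_config()) {
  shell <- build_pvat_shell(volume, cl, annotation, config)
  if (!any(shell))
    stopf("perivascular shell is empty on this grid")
  compute_fai(volume, shell, config)
}

#' @export
print.fai_measurement <- function(x, ...) {
  cat(sprintf("<fai_measurement> FAI %.1f HU (window [%g, %g] HU)\n",
              x$fai_hu, x$window_hu[1], x$window_hu[2]))
  cat(sprintf("  %d shell voxels (%.0f mm^3), %d in window (%.1f%%)\n",
              x$n_shell, x$shell_volume_mm3, x$n_window,
              100 * x$window_fraction))
  invisible(x)
}
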