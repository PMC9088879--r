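# Perpendicular cross-section resampling and lumen diameter measurement.

# Trilinear interpolation of grid HU at world points (n x 3 matrix).
# Points outside the voxel-center hull return NA.
trilinear_sample <- function(grid, points) {
  d <- dim(grid$data)
  f <- sweep(sweep(points, 2, grid$origin, "-"), 2, grid$spacing, "/")
  out <- rep(NA_real_, nrow(f))
  ok <- f[, 1] >= 0 & f[, 1] <= d[1] - 1 &
    f[, 2] >= 0 & f[, 2] <= d[2] - 1 &
    f[, 3] >= 0 & f[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  f <- f[ok, , drop = FALSE]
  i0 <- pmin(floor(f), rep(d, each = nrow(f)) - 2)
  i0 <- pmax(i0, 0)
  w <- f - i0
  g <- grid$data
  idx <- function(dx, dy, dz) {
    g[cbind(i0[, 1] + 1 + dx, i0[, 2] + 1 + dy, i0[, 3] + 1 + dz)]
  }
  val <-
    idx(0, 0, 0) * (1 - w[, 1]) * (1 - w[, 2]) * (1 - w[, 3]) +
    idx(1, 0, 0) * w[, 1] * (1 - w[, 2]) * (1 - w[, 3]) +
    idx(0, 1, 0) * (1 - w[, 1]) * w[, 2] * (1 - w[, 3]) +
    idx(1, 1, 0) * w[, 1] * w[, 2] * (1 - w[, 3]) +
    idx(0, 0, 1) * (1 - w[, 1]) * (1 - w[, 2]) * w[, 3] +
    idx(1, 0, 1) * w[, 1] * (1 - w[, 2]) * w[, 3] +
    idx(0, 1, 1) * (1 - w[, 1]) * w[, 2] * w[, 3] +
    idx(1, 1, 1) * w[, 1] * w[, 2] * w[, 3]
  out[ok] <- val
  out
}

#' Resample a cross-section perpendicular to the centerline
#'
#' Reconstructs the 2D attenuation slab in the plane orthogonal to the
#' centerline tangent at arc position `s`. In-plane axes are obtained by
#' parallel transport (double-reflection) of an initial frame from the
#' ostium, so consecutive slabs do not twist. HU values are trilinearly
#' interpolated; samples outside the volume are `NA`.
#'
#' @param volume A [voxel_grid()].
#' @param cl A [centerline()].
#' @param s Arc position, mm (must lie within the centerline's arc range).
#' @param half_width_mm Slab half-width, mm (slab spans ±`half_width_mm`
#'   around the centerline point; 0 gives a single sample).
#' @param pixel_mm In-plane pixel size, mm.
#' @return A square matrix of class `cross_section` (HU), with attributes
#'   `pixel_mm`, `center` (index of the centerline pixel), `point`,
#'   `axes` (in-plane unit vectors).
#' @export
resample_cross_section <- function(volume, cl, s, half_width_mm = 5,
                                   pixel_mm = 0.25) {
  if (!is_number(s) || s < -1e-9 || s > arc_length(cl) + 1e-9)
    stopf("arc position %.3f mm outside [0, %.3f] mm",
          s, arc_length(cl))
  at <- centerline_at(cl, s)
  frames <- centerline_frames(cl)
  j <- findInterval(min(max(s, 0), arc_length(cl)), cl$arc,
                    rightmost.closed = TRUE)
  j <- min(max(j, 1L), nrow(cl$points) - 1L)
  tfrac <- (s - cl$arc[j]) / (cl$arc[j + 1L] - cl$arc[j])
  u <- frames$u[j, ] * (1 - tfrac) + frames$u[j + 1L, ] * tfrac
  tn <- drop(at$tangent)
  u <- u - sum(u * tn) * tn
  u <- u / sqrt(sum(u^2))
  v <- c(tn[2] * u[3] - tn[3] * u[2],
         tn[3] * u[1] - tn[1] * u[3],
         tn[1] * u[2] - tn[2] * u[1])
  offs <- if (half_width_mm > 0) {
    seq(-half_width_mm, half_width_mm, by = pixel_mm)
  } else 0
  n <- length(offs)
  ab <- expand.grid(a = offs, b = offs)
  pts <- matrix(drop(at$point), nrow(ab), 3, byrow = TRUE) +
    outer(ab$a, u) + outer(ab$b, v)
  slab <- matrix(trilinear_sample(volume, pts), n, n)
  structure(slab, class = c("cross_section", "matrix", "array"),
            pixel_mm = pixel_mm, center = (n + 1L) %/% 2L,
            point = drop(at$point), axes = list(u = u, v = v, tangent = tn))
}

#' Measure the lumen diameter on a cross-sectional slab
#'
#' Thresholds the slab at the contrast attenuation, keeps the 4-connected
#' above-threshold component containing the centerline pixel, and reports
#' the equivalent-circle diameter `2 * sqrt(area / pi)`. A slab whose center
#' pixel is below threshold (occluded lumen) yields diameter 0.
#'
#' @param slab A `cross_section` from [resample_cross_section()].
#' @param contrast_threshold_hu Threshold separating contrast-filled lumen
#'   from wall/fat, HU.
#' @return Lumen diameter, mm.
#' @export
measure_lumen_diameter <- function(slab, contrast_threshold_hu = 180) {
  px <- attr(slab, "pixel_mm")
  ctr <- attr(slab, "center")
  bin <- !is.na(slab) & slab >= contrast_threshold_hu
  if (!bin[ctr, ctr]) return(0)
  comp <- matrix(FALSE, nrow(bin), ncol(bin))
  comp[ctr, ctr] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-nrow(comp), ]
    grown[-nrow(comp), ] <- grown[-nrow(comp), ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -ncol(comp)]
    grown[, -ncol(comp)] <- grown[, -ncol(comp)] | comp[, -1]
    grown <- grown & bin
    if (identical(grown, comp)) break
    comp <- grown
  }
  area <- sum(comp) * px^2
  2 * sqrt(area / pi)
}
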