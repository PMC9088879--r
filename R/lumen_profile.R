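#' Degree of in-stent restenosis from diameters
#'
#' Diameter-stenosis formula:
#' `100 * (reference - minimal) / reference` percent, where `reference` is
#' the normal proximal lumen diameter and `minimal` the smallest diameter
#' in the stented segment (a minimal diameter exceeding the reference is
#' clipped to 0 %).
#'
#' @param d_prox_mm Normal proximal reference lumen diameter, mm (> 0).
#' @param d_min_mm Minimal stent-segment lumen diameter, mm (>= 0).
#' @return Degree of stenosis, percent in \[0, 100\].
#' @export
degree_of_isr <- function(d_prox_mm, d_min_mm) {
  if (!is_number(d_prox_mm) || d_prox_mm <= 0)
    stopf("reference diameter must be > 0")
  if (!is_number(d_min_mm) || d_min_mm < 0)
    stopf("minimal diameter must be >= 0")
  if (d_min_mm >= d_prox_mm) return(0)
  100 * (d_prox_mm - d_min_mm) / d_prox_mm
}

#' Lumen diameter profile and restenosis call over a stented segment
#'
#' Samples the lumen diameter perpendicular to the centerline over the stent
#' and its 5 mm edge segments, takes the proximal reference diameter as the
#' median over the window 10–5 mm proximal to the stent, and computes the
#' degree of in-stent restenosis and the binary ISR call (recurrent diameter
#' stenosis in the stent segment or its 5 mm edges).
#'
#' Stents beginning within 10 mm of the ostium cannot supply a proximal
#' reference window and raise a `proximal_exclusion` error, mirroring the
#' usual exclusion of ostial stents.
#'
#' @param volume A [voxel_grid()].
#' @param cl A [centerline()].
#' @param annotation A [stent_annotation()].
#' @param step_mm Arc-length sampling step, mm.
#' @param edge_mm Edge-segment margin included in the minimal-diameter
#'   search, mm.
#' @param reference_window_mm Proximal window (distance before the stent
#'   start) over which the reference diameter is the median, mm
#'   (`c(far, near)`).
#' @param contrast_threshold_hu Lumen threshold passed to
#'   [measure_lumen_diameter()].
#' @param isr_threshold_pct Degree at or above which the ISR flag is set.
#' @param half_width_mm,pixel_mm Cross-section geometry (defaults sized from
#'   the annotated stent diameter).
#' @return Object of class `lumen_profile`: arc positions and diameters,
#'   reference and minimal diameters (mm), `degree_pct`, `isr` flag.
#' @export
compute_lumen_profile <- function(volume, cl, annotation, step_mm = 0.5,
                                  edge_mm = 5,
                                  reference_window_mm = c(10, 5),
                                  contrast_threshold_hu = 180,
                                  isr_threshold_pct = 50,
                                  half_width_mm = NULL, pixel_mm = 0.25) {
  a <- annotation$start_mm
  b <- annotation$end_mm
  L <- arc_length(cl)
  if (a - reference_window_mm[1] < -1e-9)
    stopf("stent starts %.1f mm from the ostium; the %.0f mm proximal reference window does not fit",
          a, reference_window_mm[1], class = "proximal_exclusion")
  if (a - edge_mm < -1e-9 || b + edge_mm > L + 1e-9)
    stopf("stent extent plus %.0f mm edges [%.1f, %.1f] mm exceeds arc range [0, %.2f] mm",
          edge_mm, a - edge_mm, b + edge_mm, L)
  if (is.null(half_width_mm))
    half_width_mm <- max(3, annotation$diameter_mm)
  diam_at <- function(s) {
    slab <- resample_cross_section(volume, cl, s, half_width_mm, pixel_mm)
    measure_lumen_diameter(slab, contrast_threshold_hu)
  }
  s_seek <- seq(a - edge_mm, b + edge_mm, by = step_mm)
  d_seek <- vapply(s_seek, diam_at, numeric(1))
  s_ref <- seq(a - reference_window_mm[1], a - reference_window_mm[2],
               by = step_mm)
  d_ref <- vapply(s_ref, diam_at, numeric(1))
  ref <- stats::median(d_ref)
  if (ref <= 0)
    stopf("no measurable lumen in the proximal reference window")
  dmin <- min(d_seek)
  deg <- degree_of_isr(ref, dmin)
  structure(list(arc_mm = s_seek, diameter_mm = d_seek,
                 reference_mm = ref, minimal_mm = dmin,
                 degree_pct = deg, isr = deg >= isr_threshold_pct,
                 isr_threshold_pct = isr_threshold_pct,
                 annotation = annotation),
            class = "lumen_profile")
}

#' @export
print.lumen_profile <- function(x, ...) {
  cat(sprintf("<lumen_profile> reference %.2f mm, minimal %.2f mm, degree %.1f%%, ISR: %s\n",
              x$reference_mm, x$minimal_mm, x$degree_pct,
              if (x$isr) "yes" else "no"))
  invisible(x)
}
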