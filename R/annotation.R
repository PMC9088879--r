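#' Stent annotation
#'
#' Records where a stent sits on a vessel centerline and its nominal
#' dimensions, as read by a radiologist: target vessel, vessel segment,
#' extent in arc length from the ostium, and nominal (outer) diameter.
#'
#' @param vessel One of `"LAD"`, `"LCx"`, `"RCA"`.
#' @param segment One of `"proximal"`, `"middle"`, `"distal"`.
#' @param start_mm,end_mm Stent extent in arc length from the ostium, mm.
#' @param diameter_mm Nominal stent diameter, mm.
#' @param stent_class `"DES"` (drug-eluting) or `"BMS"` (bare-metal).
#' @return Object of class `stent_annotation`.
#' @export
stent_annotation <- function(vessel, segment, start_mm, end_mm, diameter_mm,
                             stent_class = "DES") {
  vessel <- match.arg(vessel, c("LAD", "LCx", "RCA"))
  segment <- match.arg(segment, c("proximal", "middle", "distal"))
  stent_class <- match.arg(stent_class, c("DES", "BMS"))
  if (!is_number(start_mm) || !is_number(end_mm) || end_mm <= start_mm)
    stopf("stent extent must satisfy end > start")
  if (!is_number(diameter_mm) || diameter_mm <= 0)
    stopf("stent diameter must be > 0")
  structure(list(vessel = vessel, segment = segment,
                 start_mm = start_mm, end_mm = end_mm,
                 length_mm = end_mm - start_mm,
                 diameter_mm = diameter_mm, stent_class = stent_class),
            class = "stent_annotation")
}

#' @export
print.stent_annotation <- function(x, ...) {
  cat(sprintf("<stent_annotation> %s %s segment, [%.1f, %.1f] mm (length %.1f mm), diameter %.2f mm, %s\n",
              x$vessel, x$segment, x$start_mm, x$end_mm, x$length_mm,
              x$diameter_mm, x$stent_class))
  invisible(x)
}
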