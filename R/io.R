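# NIfTI / CSV serialization. Volumes are NIfTI-1 with affine
# diag(spacing) + origin (world mm); cohorts are plain CSV; centerlines are
# CSV with columns x, y, z, s, tx, ty, tz.

#' Write a voxel grid as NIfTI-1
#'
#' @param grid A [voxel_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  if (!inherits(grid, "voxel_grid")) stopf("`grid` must be a voxel_grid")
  im <- RNifti::asNifti(grid$data + 0)  # force numeric storage
  RNifti::pixdim(im) <- grid$spacing
  aff <- rbind(cbind(diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
  aff <- structure(aff, code = 2L)
  im <- RNifti::`sform<-`(im, aff)
  im <- RNifti::`qform<-`(im, aff)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a voxel grid
#'
#' @param path NIfTI file path.
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 3L)
    stopf("expected a 3D volume, got %d dimensions", length(d))
  x <- RNifti::xform(im)
  voxel_grid(array(as.numeric(im), d),
             spacing = RNifti::pixdim(im)[1:3],
             origin = x[1:3, 4])
}

#' Write / read a cohort table as CSV
#'
#' The CSV schema follows the cohort generator: mandatory columns `id`,
#' `isr`, `peri_stent_fai_hu`; any further columns round-trip untouched.
#'
#' @param cohort Cohort `data.frame`.
#' @param path CSV path.
#' @return `path` invisibly (write); the cohort `data.frame` (read).
#' @export
write_cohort <- function(cohort, path) {
  check_cohort_columns(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cohort_columns(df)
  df
}

check_cohort_columns <- function(df) {
  required <- c("id", "isr", "peri_stent_fai_hu")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stopf("cohort is missing mandatory column(s): %s",
          paste(miss, collapse = ", "))
  invisible(df)
}

#' Write / read a centerline as CSV
#'
#' Columns: `x`, `y`, `z` (mm), `s` (arc length, mm), `tx`, `ty`, `tz`
#' (unit tangent).
#'
#' @param cl A [centerline()].
#' @param path CSV path.
#' @return `path` invisibly (write); a [centerline()] (read).
#' @export
write_centerline <- function(cl, path) {
  df <- data.frame(x = cl$points[, 1], y = cl$points[, 2],
                   z = cl$points[, 3], s = cl$arc,
                   tx = cl$tangents[, 1], ty = cl$tangents[, 2],
                   tz = cl$tangents[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centerline
#' @export
read_centerline <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    stopf("centerline CSV needs columns x, y, z")
  centerline(as.matrix(df[, need]))
}

#' Read a pipeline configuration from YAML
#'
#' Values in the YAML file override the defaults of [pipeline_config()];
#' unknown top-level keys are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(unclass(defaults), raw)
  do.call(pipeline_config, merged)
}
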