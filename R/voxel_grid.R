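#' Voxel grid: a 3D attenuation (or mask) volume with geometry
#'
#' The basic image container used throughout the package: a 3D array of
#' Hounsfield units (or logical mask values) plus the voxel spacing and the
#' world-coordinate position of the center of voxel `[1, 1, 1]`. World
#' coordinates are in millimetres; voxel indices follow the voxel-center
#' convention, so voxel `[i, j, k]` is centred at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3D numeric or logical array.
#' @param spacing Voxel spacing in mm; length 1 (isotropic) or 3.
#' @param origin World coordinate (mm) of the center of the first voxel.
#' @return An object of class `voxel_grid` with elements `data`, `spacing`,
#'   `origin`.
#' @export
voxel_grid <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3D array, got %s dimensions",
          length(dim(data)))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("`spacing` must be 3 positive finite numbers")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stopf("`origin` must be 3 finite numbers")
  if (is.numeric(data) && any(!is.finite(data)))
    stopf("volume contains non-finite attenuation values")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  if (is.numeric(x$data))
    cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

# World coordinates (mm) of all voxel centers, as an n x 3 matrix ordered
# like `which(array)`.
voxel_centers <- function(grid, linear_idx = NULL) {
  d <- dim(grid$data)
  if (is.null(linear_idx)) linear_idx <- seq_len(prod(d))
  idx <- arrayInd(linear_idx, d)
  sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

as_mask <- function(grid) {
  if (inherits(grid, "voxel_grid")) {
    m <- grid$data
  } else m <- grid
  if (!is.logical(m)) m <- m != 0
  m
}
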