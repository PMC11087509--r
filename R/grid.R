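#' Regular 3-D grid specification
#'
#' A `grid_spec` describes a regular orthogonal voxel grid. The single
#' authoritative convention used throughout the package is that voxel
#' `(i, j, k)` (zero-based) has its *center* at
#' `origin + c(i, j, k) * spacing`, in Angstrom.
#'
#' @param origin numeric(3); world position (Angstrom) of the center of voxel
#'   (0, 0, 0).
#' @param spacing numeric(3) or scalar; voxel edge lengths in Angstrom, all
#'   strictly positive.
#' @param shape integer(3); number of voxels along x, y, z; all >= 1.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(origin = c(0, 0, 0), spacing = 1, shape = c(8, 8, 8))
#' voxel_centers(g, axis = 1)
#' @export
grid_spec <- function(origin = c(0, 0, 0), spacing = 1, shape) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(shape) == 3L)
  if (any(!is.finite(origin))) stop("grid origin must be finite")
  if (any(spacing <= 0)) stop("grid spacing must be > 0")
  if (any(shape < 1L)) stop("grid shape components must be >= 1")
  structure(list(origin = origin, spacing = spacing, shape = shape),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) A, origin (%.3g, %.3g, %.3g) A\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel center coordinates along one axis
#'
#' @param grid a [grid_spec()].
#' @param axis 1, 2 or 3 for x, y or z.
#' @return numeric vector of world coordinates (Angstrom) of voxel centers.
#' @export
voxel_centers <- function(grid, axis) {
  stopifnot(inherits(grid, "grid_spec"), axis %in% 1:3)
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' Test two grids for equality within tolerance
#' @param a,b [grid_spec()] objects.
#' @param tol numeric tolerance on origin and spacing, Angstrom.
#' @return logical.
#' @export
grids_identical <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' 3-D density map
#'
#' Couples a [grid_spec()] with a voxel value array and an optional logical
#' mask of the same shape. Both experimental (cryo-EM) and model-simulated
#' maps use this container.
#'
#' @param grid a [grid_spec()].
#' @param values numeric 3-D array with `dim(values) == grid$shape`; all
#'   values must be finite.
#' @param mask optional logical array of the same shape.
#' @return An object of class `density_map`.
#' @export
density_map <- function(grid, values, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("values array shape does not match grid shape")
  if (any(!is.finite(values))) stop("density map values must be finite")
  if (!is.null(mask)) {
    mask <- as.array(mask)
    if (!identical(as.integer(dim(mask)), grid$shape))
      stop("mask shape does not match grid shape")
    storage.mode(mask) <- "logical"
  }
  structure(list(grid = grid, values = values, mask = mask),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("density_map\n")
  print(x$grid)
  cat(sprintf("  values: [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  if (!is.null(x$mask))
    cat(sprintf("  mask: %d of %d voxels\n", sum(x$mask), length(x$mask)))
  invisible(x)
}
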