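#' Regular 3D voxel grid
#'
#' Describes the geometry of a regular voxel lattice: array dimensions,
#' isotropic or anisotropic voxel spacing in mm, the mm position of the first
#' voxel center, and which array axis carries the main static field B0.
#' Axis semantics follow the package convention x = right-left (RL),
#' y = anterior-posterior (AP), z = superior-inferior (SI); B0 is along +z
#' (axis 3) by default.
#'
#' @param shape integer vector of length 3, array dimensions (nx, ny, nz).
#' @param spacing numeric length 3 (or 1, recycled), voxel spacing in mm.
#' @param origin numeric length 3, mm coordinates of the center of voxel
#'   `[1,1,1]`. Default centers the volume on the coordinate origin.
#' @param b0_axis integer in 1..3, array axis of the B0 direction (default 3).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing = 1, origin = NULL, b0_axis = 3L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be three integers >= 1")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' entries must be positive")
  if (is.null(origin)) origin <- -(shape - 1) / 2 * spacing
  origin <- rep_len(as.numeric(origin), 3L)
  b0_axis <- as.integer(b0_axis)
  if (!b0_axis %in% 1:3) stop("'b0_axis' must be 1, 2 or 3")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 b0_axis = b0_axis),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d, spacing %.3g x %.3g x %.3g mm, B0 axis %d\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3], x$b0_axis))
  invisible(x)
}

#' Voxel-center coordinates along one grid axis
#'
#' @param grid a [voxel_grid()].
#' @param axis integer 1..3.
#' @return numeric vector of mm coordinates of voxel centers.
#' @export
grid_axis_coords <- function(grid, axis) {
  stopifnot(inherits(grid, "voxel_grid"), axis %in% 1:3)
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' Full per-voxel coordinate arrays
#'
#' mm coordinates of every voxel center, one array per axis (memory: three
#' doubles per voxel). Used by the geometric primitives, which need true
#' Euclidean distances per voxel center.
#'
#' @param grid a [voxel_grid()].
#' @return list of arrays `x`, `y`, `z`, each of dim `grid$shape`.
#' @export
grid_coord_arrays <- function(grid) {
  xs <- grid_axis_coords(grid, 1)
  ys <- grid_axis_coords(grid, 2)
  zs <- grid_axis_coords(grid, 3)
  n <- grid$shape
  list(
    x = array(rep(xs, times = n[2] * n[3]), dim = n),
    y = array(rep(rep(ys, each = n[1]), times = n[3]), dim = n),
    z = array(rep(zs, each = n[1] * n[2]), dim = n)
  )
}

grid_voxel_volume <- function(grid) prod(grid$spacing)

grids_equal <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol) &&
    a$b0_axis == b$b0_axis
}
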