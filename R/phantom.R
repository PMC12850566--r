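#' Labeled voxel volume
#'
#' An integer label per voxel on a [voxel_grid()], with label 0 conventionally
#' background/air. Labels index rows of a [material_table()].
#'
#' @param grid a [voxel_grid()].
#' @param labels integer array with dim equal to `grid$shape`.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(grid, labels) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!identical(dim(labels), as.integer(grid$shape)))
    stop("label array dimensions do not match the grid shape")
  storage.mode(labels) <- "integer"
  structure(list(grid = grid, labels = labels), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume on "); print(x$grid)
  print(table(x$labels))
  invisible(x)
}

#' Sphere mask on a voxel grid
#'
#' Voxel-center membership test: a voxel is inside iff its center lies within
#' `radius` mm of `center`. Sub-voxel accuracy comes from grid oversampling,
#' not partial-volume fractions.
#'
#' @param grid a [voxel_grid()].
#' @param center mm triple.
#' @param radius mm, >= 0.
#' @return logical array of dim `grid$shape`.
#' @export
make_sphere_mask <- function(grid, center, radius) {
  stopifnot(inherits(grid, "voxel_grid"), length(center) == 3)
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0) return(array(FALSE, dim = grid$shape))
  dx2 <- (grid_axis_coords(grid, 1) - center[1])^2
  dy2 <- (grid_axis_coords(grid, 2) - center[2])^2
  dz2 <- (grid_axis_coords(grid, 3) - center[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
}

#' Finite-cylinder mask on a voxel grid
#'
#' Voxel true iff its center is within `radius` mm of the closed segment
#' p0--p1 (a capsule-free right cylinder: axial extent clamped to the
#' segment, caps flat).
#'
#' @param grid a [voxel_grid()].
#' @param p0,p1 mm endpoints of the cylinder axis; must differ.
#' @param radius mm, >= 0.
#' @return logical array.
#' @export
make_cylinder_mask <- function(grid, p0, p1, radius) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (radius < 0) stop("radius must be >= 0")
  d <- as.numeric(p1) - as.numeric(p0)
  L <- sqrt(sum(d^2))
  if (L == 0) stop("degenerate cylinder axis: p0 == p1")
  if (radius == 0) return(array(FALSE, dim = grid$shape))
  u <- d / L
  cc <- grid_coord_arrays(grid)
  rx <- cc$x - p0[1]; ry <- cc$y - p0[2]; rz <- cc$z - p0[3]
  t <- rx * u[1] + ry * u[2] + rz * u[3]
  along <- t >= 0 & t <= L
  # squared radial distance from the axis line
  r2 <- (rx - t * u[1])^2 + (ry - t * u[2])^2 + (rz - t * u[3])^2
  along & r2 <= radius^2
}

#' Spherical-cap shell mask (acetabular cup / liner geometry)
#'
#' Voxel true iff r_inner <= |v - center| <= r_outer and the angle between
#' (v - center) and `cap_axis` is at most `cap_angle` degrees. With
#' `cap_angle = 180` this is a full spherical shell.
#'
#' @param grid a [voxel_grid()].
#' @param center mm triple.
#' @param r_outer,r_inner shell radii in mm, 0 <= r_inner < r_outer.
#' @param cap_axis direction of the cap pole (normalized internally).
#' @param cap_angle half-opening angle in degrees, in (0, 180].
#' @return logical array.
#' @export
make_cap_shell_mask <- function(grid, center, r_outer, r_inner,
                                cap_axis = c(0, 0, 1), cap_angle = 90) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (r_inner < 0 || r_inner >= r_outer)
    stop("require 0 <= r_inner < r_outer")
  if (cap_angle <= 0 || cap_angle > 180)
    stop("cap_angle must be in (0, 180]")
  a <- as.numeric(cap_axis); a <- a / sqrt(sum(a^2))
  cc <- grid_coord_arrays(grid)
  vx <- cc$x - center[1]; vy <- cc$y - center[2]; vz <- cc$z - center[3]
  r <- sqrt(vx^2 + vy^2 + vz^2)
  shell <- r >= r_inner & r <= r_outer
  dotp <- vx * a[1] + vy * a[2] + vz * a[3]
  # cos(angle) >= cos(cap_angle); guard r = 0 (center voxel: inside the cap)
  cosang <- ifelse(r > 0, dotp / pmax(r, .Machine$double.eps), 1)
  shell & cosang >= cos(cap_angle * pi / 180)
}

#' Merge implant masks into an anatomy label volume
#'
#' Implant materials override anatomy labels; when implant components
#' overlap, components later in the list take precedence. All masks must
#' share the anatomy grid. Materials are looked up by name in `table`.
#'
#' @param anatomy a [label_volume()].
#' @param implants list of `list(mask = <logical array>, material = <name>)`,
#'   applied in order.
#' @param table a [material_table()] containing every implant material.
#' @return a [label_volume()] on the same grid.
#' @export
merge_masks <- function(anatomy, implants, table) {
  stopifnot(inherits(anatomy, "label_volume"))
  labels <- anatomy$labels
  for (imp in implants) {
    if (!identical(dim(imp$mask), as.integer(anatomy$grid$shape)))
      stop("implant mask grid mismatch with anatomy grid")
    lab <- material_row(table, imp$material)$label
    labels[imp$mask] <- lab
  }
  label_volume(anatomy$grid, labels)
}

#' Assign per-voxel parameter maps from a material table
#'
#' Pure per-voxel lookup: proton density, T2 and chi come straight from the
#' table; T1 is evaluated at the requested field strength through the
#' dispersion model ([t1_at_field()]). No-signal (metal) materials get
#' rho = 0 while keeping their susceptibility.
#'
#' @param labels a [label_volume()].
#' @param table a [material_table()] covering every label present.
#' @param b0 field strength in Tesla, > 0.
#' @return object of class `parameter_maps`: list with arrays `rho`,
#'   `t1_ms`, `t2_ms`, `chi_ppm` and the `grid`.
#' @export
assign_parameters <- function(labels, table, b0) {
  stopifnot(inherits(labels, "label_volume"), b0 > 0)
  lab <- labels$labels
  present <- sort(unique(as.vector(lab)))
  unknown <- setdiff(present, table$label)
  if (length(unknown))
    stop("labels not present in material table: ",
         paste(unknown, collapse = ", "))
  # lookup vector indexed by label value + 1 (labels are small non-negatives)
  maxlab <- max(table$label)
  lut <- function(values) {
    v <- rep(NA_real_, maxlab + 1L)
    v[table$label + 1L] <- values
    array(v[lab + 1L], dim = dim(lab))
  }
  t1 <- vapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    if (r$t1_type == "power")
      t1_at_field(t1_dispersion_model(r$t1_a_ms, r$t1_b), b0)
    else r$t1_a_ms
  }, numeric(1))
  structure(list(
    rho     = lut(ifelse(table$is_metal, 0, table$pd)),
    t1_ms   = lut(t1),
    t2_ms   = lut(table$t2_ms),
    chi_ppm = lut(table$chi_ppm),
    grid    = labels$grid,
    b0      = b0
  ), class = "parameter_maps")
}
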