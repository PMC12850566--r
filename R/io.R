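#' NIfTI I/O for label volumes and scalar maps
#'
#' Volumes are written with a diagonal affine carrying the voxel spacing and
#' the mm position of the first voxel center; axes are stored in the
#' package convention x = RL, y = AP, z = SI (B0 axis metadata is not part
#' of NIfTI and defaults to z on read).
#'
#' @param vol a [label_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path` invisibly (writers); a [label_volume()] or list
#'   (`data`, `grid`) for the readers.
#' @export
write_labels_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  write_image_nifti(vol$labels, vol$grid$spacing, path,
                    origin = vol$grid$origin)
}

#' @rdname write_labels_nifti
#' @param b0_axis B0 axis to attach to the grid on read.
#' @export
read_labels_nifti <- function(path, b0_axis = 3L) {
  r <- read_image_nifti(path, b0_axis = b0_axis)
  label_volume(r$grid, array(as.integer(round(r$data)),
                             dim = r$grid$shape))
}

#' @rdname write_labels_nifti
#' @param data numeric 3D array.
#' @param spacing mm spacing triple.
#' @param origin mm coordinates of the first voxel center.
#' @export
write_image_nifti <- function(data, spacing, path, origin = NULL) {
  spacing <- rep_len(as.numeric(spacing), 3)
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * spacing
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_labels_nifti
#' @export
read_image_nifti <- function(path, b0_axis = 3L) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- abs(diag(aff)[1:3])
  origin <- aff[1:3, 4]
  data <- array(as.numeric(img), dim = dim(img))
  list(data = data,
       grid = voxel_grid(dim(data), spacing, origin, b0_axis = b0_axis))
}

#' Write / read a field-shift map as NIfTI (Hz) with a JSON sidecar
#'
#' The sidecar records the field strength so the map is self-describing.
#'
#' @param dfmap a `field_shift_map`.
#' @param path `.nii` / `.nii.gz` path; the sidecar is `path` with a
#'   `.json` extension appended.
#' @export
write_fieldmap_nifti <- function(dfmap, path) {
  stopifnot(inherits(dfmap, "field_shift_map"))
  write_image_nifti(dfmap$delta_f_hz, dfmap$grid$spacing, path,
                    origin = dfmap$grid$origin)
  jsonlite::write_json(list(b0_tesla = dfmap$b0, units = "Hz"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fieldmap_nifti
#' @export
read_fieldmap_nifti <- function(path) {
  r <- read_image_nifti(path)
  side <- paste0(path, ".json")
  b0 <- if (file.exists(side)) jsonlite::read_json(side)$b0_tesla else NA
  structure(list(grid = r$grid, delta_f_hz = r$data, b0 = b0),
            class = "field_shift_map")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips the nested configuration lists used by [run_pipeline()].
#'
#' @param config configuration list.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML scalars for length-2 numeric fields arrive as lists; flatten
  for (f in c("fov_mm", "matrix"))
    if (!is.null(cfg$sequence[[f]]))
      cfg$sequence[[f]] <- as.numeric(unlist(cfg$sequence[[f]]))
  cfg
}
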