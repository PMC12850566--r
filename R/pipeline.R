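#' Validate a pipeline configuration
#'
#' Schema check with field-path error messages. A configuration is a nested
#' list with components `phantom` (`type` one of "water_bath", "hip",
#' "nifti"; `args` passed to the generator or loader), `b0` (Tesla),
#' `fieldmap` (`pad_factor`), `sequence` (arguments of
#' [sequence_params()]), optional `noise` (arguments of [noise_model()];
#' NULL or `sigma_ref = 0` for noiseless) and optional `metrics`
#' (`threshold_fraction`).
#'
#' @param config nested list.
#' @return the config, invisibly, on success; otherwise an error naming the
#'   offending field path.
#' @export
validate_config <- function(config) {
  need <- function(cond, path, msg)
    if (!cond) stop("config$", path, ": ", msg, call. = FALSE)
  need(is.list(config$phantom), "phantom", "must be a list")
  need(isTRUE(config$phantom$type %in% c("water_bath", "hip", "nifti")),
       "phantom$type", "must be 'water_bath', 'hip' or 'nifti'")
  need(is.numeric(config$b0) && config$b0 > 0, "b0",
       "must be a positive field strength in Tesla")
  pad <- config$fieldmap$pad_factor
  need(is.null(pad) || (is.numeric(pad) && pad >= 1), "fieldmap$pad_factor",
       "must be >= 1")
  need(is.list(config$sequence), "sequence", "must be a list")
  sq <- try(do.call(sequence_params, config$sequence), silent = TRUE)
  if (inherits(sq, "try-error"))
    stop("config$sequence: ", attr(sq, "condition")$message, call. = FALSE)
  if (!is.null(config$noise)) {
    nm <- try(do.call(noise_model, config$noise), silent = TRUE)
    if (inherits(nm, "try-error"))
      stop("config$noise: ", attr(nm, "condition")$message, call. = FALSE)
  }
  invisible(config)
}

build_phantom <- function(config) {
  ph <- config$phantom
  args <- if (is.null(ph$args)) list() else ph$args
  fx <- switch(ph$type,
    water_bath = do.call(make_water_bath_phantom, args),
    hip = do.call(make_hip_phantom, args),
    nifti = {
      lv <- read_labels_nifti(args$path)
      tb <- if (!is.null(args$materials_yaml))
        read_materials_yaml(args$materials_yaml) else default_materials()
      list(labels = lv, materials = tb,
           implant_mask = array(lv$labels %in% tb$label[tb$is_metal],
                                dim = lv$grid$shape),
           head_mask = array(FALSE, dim = lv$grid$shape))
    })
  fx
}

#' Run the full simulation pipeline
#'
#' Executes phantom construction, parameter-map assignment, dipole field-map
#' computation, sequence simulation, optional noise addition, per-bin
#' reconstruction and root-sum-of-squares combination. Deterministic given
#' the configuration and seed. When `out_dir` is given, writes the final
#' image (NIfTI), the image-domain bin stack (RDS), and a JSON provenance
#' sidecar (configuration, seed, package version, stage timings).
#'
#' @param config configuration list (see [validate_config()]).
#' @param seed integer seed for the noise generator (unused in noiseless
#'   runs).
#' @param out_dir optional output directory.
#' @return list: `final` (magnitude array, freq x phase x slice), `stack`
#'   (image-domain [bin_stack()]), `kspace` (noisy k-space stack), `maps`,
#'   `dfmap`, `phantom` (fixture list), `timings` (seconds per stage).
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  validate_config(config)
  timings <- c()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    val <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    val
  }
  fx <- tick("phantom", build_phantom(config))
  table <- fx$materials
  if (!is.null(config$tissue_chi_override))
    table$chi_ppm[table$is_metal] <- config$tissue_chi_override
  maps <- tick("parameter_maps",
               assign_parameters(fx$labels, table, config$b0))
  pad <- config$fieldmap$pad_factor
  dfmap <- tick("fieldmap", susceptibility_to_fieldshift(
    maps, b0 = config$b0,
    pad_factor = if (is.null(pad)) 2L else as.integer(pad)))
  params <- do.call(sequence_params, config$sequence)
  kstack <- tick("sequence",
                 if (params$seq_type == "SEMAC")
                   simulate_semac_study(maps, dfmap, params)
                 else simulate_acquisition(maps, dfmap, params))
  if (!is.null(config$noise) &&
      (is.null(config$noise$sigma_ref) || config$noise$sigma_ref > 0)) {
    nm <- do.call(noise_model, config$noise)
    kstack <- tick("noise", add_noise(kstack, nm, config$b0, seed = seed))
  }
  stack <- tick("recon", reconstruct_bins(kstack))
  final <- tick("combine", combine_rsos(stack))
  res <- list(final = final, stack = stack, kspace = kstack, maps = maps,
              dfmap = dfmap, phantom = fx, config = config, seed = seed,
              timings = timings)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_image_nifti(final, c(kstack$meta$px_mm,
                               kstack$meta$slice_thickness_mm),
                      file.path(out_dir, "final.nii.gz"))
    saveRDS(stack, file.path(out_dir, "bin_stack.rds"))
    sidecar <- list(config = config, seed = seed,
                    package_version = as.character(utils::packageVersion("metalsim")),
                    timings = as.list(timings))
    jsonlite::write_json(sidecar, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

config_get <- function(config, path) {
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) config <- config[[k]]
  config
}

config_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(keys) == 1) config[[keys]] <- value
  else config[[keys[1]]] <- config_set(config[[keys[1]]],
                                       paste(keys[-1], collapse = "."), value)
  config
}

# recursively list paths at which two configs differ
config_diff <- function(a, b, prefix = "") {
  keys <- union(names(a), names(b))
  out <- character(0)
  for (k in keys) {
    pa <- a[[k]]; pb <- b[[k]]
    path <- if (prefix == "") k else paste0(prefix, ".", k)
    if (is.list(pa) && is.list(pb)) out <- c(out, config_diff(pa, pb, path))
    else if (!isTRUE(all.equal(pa, pb))) out <- c(out, path)
  }
  out
}

#' Run a single-parameter sweep and tabulate artifact and SNR metrics
#'
#' The configurations must be identical except at the sweep `axis` (a
#' dot-separated path, e.g. `"b0"` or `"sequence.readout_bw_hz_per_px"`).
#' For each configuration the pipeline is run twice (metal and
#' tissue-matched susceptibility, see [reference_pair()]); the signal-void
#' artifact is measured on the central slice of the difference image, and
#' SNR is measured when noise is configured (signal ROI: tissue in the
#' reference image away from the implant; background ROI: image corners).
#'
#' @param configs list of configuration lists.
#' @param axis dot-separated config path that varies across `configs`.
#' @param seed integer seed shared by all runs.
#' @return data.frame with columns `axis_value`, `area_mm2`,
#'   `extent_rl_mm`, `extent_si_mm`, `snr`.
#' @export
sweep_configs <- function(configs, axis, seed = NULL) {
  if (length(configs) > 1) {
    ref <- config_set(configs[[1]], axis, NULL)
    for (i in seq_along(configs)[-1]) {
      d <- setdiff(config_diff(config_set(configs[[i]], axis, NULL), ref), axis)
      if (length(d))
        stop("configs differ outside the sweep axis at: ",
             paste(d, collapse = ", "))
    }
  }
  rows <- lapply(configs, function(cfg) {
    pair <- reference_pair(cfg, seed = seed)
    mid <- ceiling(dim(pair$diff)[3] / 2)
    tf <- cfg$metrics$threshold_fraction
    imp2d <- implant_mask_on_image_grid(pair$metal)[, , mid]
    am <- measure_artifact(pair$diff[, , mid],
                           pair$reference$final[, , mid],
                           pair$metal$kspace$meta$px_mm,
                           threshold_fraction = if (is.null(tf)) 0.5 else tf,
                           implant_mask = imp2d)
    snr <- NA_real_
    if (!is.null(cfg$noise) && isTRUE(cfg$noise$sigma_ref > 0)) {
      rois <- default_rois(pair$reference$final, imp2d, mid)
      snr <- measure_snr(pair$metal$final[, , mid], rois$signal, rois$background)
    }
    data.frame(axis_value = as.numeric(config_get(cfg, axis)),
               area_mm2 = am$area_mm2, extent_rl_mm = am$extent_rl_mm,
               extent_si_mm = am$extent_si_mm, snr = snr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# box-average the fine-grid implant mask onto the image grid of a run
implant_mask_on_image_grid <- function(res) {
  meta <- res$kspace$meta
  p <- res$kspace$params
  grid <- res$maps$grid
  perm <- meta$axes
  m <- aperm(res$phantom$implant_mask, perm)
  fc <- grid_axis_coords(grid, p$freq_axis)
  pc <- grid_axis_coords(grid, p$phase_axis)
  sc <- grid_axis_coords(grid, p$slice_axis)
  d <- dim(res$final)
  out <- array(FALSE, dim = d)
  idx <- which(m)
  if (!length(idx)) return(out)
  ai <- arrayInd(idx, dim(m))
  fi <- round((fc[ai[, 1]] - meta$f_coord1) / meta$px_mm[1]) + 1
  pi_ <- round((pc[ai[, 2]] - meta$p_coord1) / meta$px_mm[2]) + 1
  si <- round((sc[ai[, 3]] - meta$z_slices[1]) / meta$slice_thickness_mm) + 1
  ok <- fi >= 1 & fi <= d[1] & pi_ >= 1 & pi_ <= d[2] &
    si >= 1 & si <= d[3]
  out[cbind(fi[ok], pi_[ok], si[ok])] <- TRUE
  out
}

# automatic signal/background ROIs on a central slice
default_rois <- function(reference_final, implant_2d, mid) {
  ref <- reference_final[, , mid]
  d <- dim(ref)
  away <- !dilate_mask_mm(implant_2d, c(1, 1), 25)
  signal <- ref > 0.5 * max(ref) & away
  background <- array(FALSE, dim = d)
  m <- max(4L, round(min(d) / 10))
  background[c(seq_len(m), d[1] - seq_len(m) + 1),
             c(seq_len(m), d[2] - seq_len(m) + 1)] <- TRUE
  background <- background & ref < 0.05 * max(ref)
  list(signal = signal, background = background)
}
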