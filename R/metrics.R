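#' Morphological dilation of a mask by a metric radius
#'
#' FFT ball-kernel dilation on a 2D or 3D lattice with per-axis spacing in
#' mm. Convolution is circular; masks within `radius_mm` of the array
#' boundary will wrap, so keep implants away from the volume edge (the
#' fixtures do).
#'
#' @param mask logical array (2D or 3D).
#' @param spacing_mm per-axis spacing, mm.
#' @param radius_mm dilation radius, mm.
#' @return logical array of the same shape.
#' @export
dilate_mask_mm <- function(mask, spacing_mm, radius_mm) {
  n <- dim(mask)
  spacing_mm <- rep_len(spacing_mm, length(n))
  offs <- lapply(seq_along(n), function(a) {
    i <- seq_len(n[a]) - 1
    (pmin(i, n[a] - i) * spacing_mm[a])^2
  })
  d2 <- offs[[1]]
  for (a in seq_along(n)[-1]) d2 <- outer(d2, offs[[a]], `+`)
  kern <- d2 <= radius_mm^2
  conv <- Re(stats::fft(stats::fft(array(as.numeric(mask), dim = n)) *
                          stats::fft(array(as.numeric(kern), dim = n)),
                        inverse = TRUE)) / prod(n)
  conv > 0.5
}

#' Run the pipeline with and without metal susceptibility
#'
#' Runs the simulation twice with identical parameters and seed, differing
#' only in the implant susceptibility: in the reference run every no-signal
#' (metal) material has its chi set to the tissue value (-9.05 ppm), so the
#' difference of the two final images isolates the susceptibility artifact.
#'
#' @param config a pipeline configuration (see [run_pipeline()]).
#' @param seed integer seed applied to both runs (common random numbers, so
#'   noise cancels in the difference away from the artifact).
#' @param tissue_chi_ppm reference susceptibility, default -9.05.
#' @return list with elements `metal` and `reference` (full [run_pipeline()]
#'   results) and `diff` (magnitude difference of the final images).
#' @export
reference_pair <- function(config, seed = NULL, tissue_chi_ppm = -9.05) {
  res_metal <- run_pipeline(config, seed = seed)
  cfg_ref <- config
  cfg_ref$tissue_chi_override <- tissue_chi_ppm
  res_ref <- run_pipeline(cfg_ref, seed = seed)
  list(metal = res_metal, reference = res_ref,
       diff = abs(res_metal$final - res_ref$final))
}

#' Measure the signal-void artifact from a difference image
#'
#' Automated surrogate for manual tracing of the signal void: the artifact
#' mask is the set of pixels where the absolute difference between the
#' metal and the tissue-matched simulation exceeds `threshold_fraction`
#' times the median reference signal over signal-bearing tissue, restricted
#' to the largest connected component intersecting the implant neighborhood
#' (the implant mask dilated by 10 mm) when an implant mask is supplied.
#' Extents are bounding-box extents of the mask along the declared
#' right-left and superior-inferior image axes.
#'
#' @param diff 2D magnitude difference image (central slice).
#' @param reference matching 2D reference image (tissue-matched run).
#' @param spacing_mm length-2 pixel spacing (mm) for the two image axes.
#' @param threshold_fraction in (0, 1), default 0.5.
#' @param implant_mask optional 2D logical mask of the implant on the image
#'   grid.
#' @param rl_axis,si_axis image-plane axes (1 or 2) used for the RL and SI
#'   extents.
#' @return list of class `artifact_measure`: `area_mm2`, `extent_rl_mm`,
#'   `extent_si_mm`, `mask`.
#' @export
measure_artifact <- function(diff, reference, spacing_mm,
                             threshold_fraction = 0.5, implant_mask = NULL,
                             rl_axis = 1, si_axis = 2) {
  if (!all(dim(diff) == dim(reference)))
    stop("diff and reference must have the same shape")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  if (all(reference == 0)) stop("reference image is identically zero")
  spacing_mm <- rep_len(spacing_mm, 2)
  signal <- reference > 0.1 * max(reference)
  thr <- threshold_fraction * stats::median(abs(reference[signal]))
  mask <- abs(diff) > thr
  if (any(mask)) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    if (!is.null(implant_mask)) {
      nbhd <- dilate_mask_mm(implant_mask, spacing_mm, 10)
      touching <- sort(unique(lab[nbhd & lab > 0]))
      keep <- if (length(touching)) touching[which.max(sizes[touching])]
              else integer(0)
    } else {
      keep <- which.max(sizes)
    }
    mask <- array(lab %in% keep, dim = dim(mask))
    # area inside the traced outline: fill enclosed holes (the implant's own
    # signal-free interior, where the difference image is near zero)
    mask <- EBImage::fillHull(mask) > 0
  }
  npix <- sum(mask)
  ext <- function(axis) {
    if (npix == 0) return(0)
    idx <- which(mask, arr.ind = TRUE)[, axis]
    (max(idx) - min(idx) + 1) * spacing_mm[axis]
  }
  structure(list(area_mm2 = npix * prod(spacing_mm),
                 extent_rl_mm = ext(rl_axis),
                 extent_si_mm = ext(si_axis),
                 mask = mask),
            class = "artifact_measure")
}

#' Rayleigh-corrected SNR from a magnitude image
#'
#' SNR = mean(signal ROI) / sigma_hat with sigma_hat the underlying complex
#' Gaussian noise sd recovered from the magnitude background:
#' sd(|background|) = sigma * sqrt(2 - pi/2) for Rayleigh-distributed
#' magnitude noise, so sigma_hat = sd(background) / sqrt(2 - pi/2).
#'
#' @param image magnitude image (any shape).
#' @param signal_roi,background_roi logical masks on `image`, non-empty and
#'   disjoint; the background must contain noise only.
#' @return scalar SNR.
#' @export
measure_snr <- function(image, signal_roi, background_roi) {
  if (!any(signal_roi) || !any(background_roi)) stop("empty ROI")
  if (any(signal_roi & background_roi)) stop("ROIs must be disjoint")
  s <- mean(image[signal_roi])
  sd_bg <- stats::sd(image[background_roi])
  if (sd_bg == 0) stop("background ROI has zero variance")
  s / (sd_bg / sqrt(2 - pi / 2))
}

#' Per-bin signal fraction near the implant
#'
#' Fraction (percent) of the total bin-stack magnitude, within a band of
#' `band_mm` around the implant boundary (morphological dilation of the
#' implant mask minus the implant), contributed by each spectral bin.
#' Fractions sum to 100.
#'
#' @param stack an image-domain [bin_stack()].
#' @param implant_mask logical array matching the stack's (freq, phase,
#'   slice) dimensions.
#' @param band_mm band width in mm, default 30.
#' @return numeric vector of percentages, one per bin.
#' @export
bin_signal_fraction <- function(stack, implant_mask, band_mm = 30) {
  stopifnot(inherits(stack, "bin_stack"))
  if (stack$domain != "image") stop("stack must be image-domain")
  if (band_mm <= 0) stop("band_mm must be > 0")
  d <- dim(stack$data)
  if (!all(dim(implant_mask) == d[1:3]))
    stop("implant mask does not match the image grid")
  sp <- c(stack$meta$px_mm, stack$meta$slice_thickness_mm)
  region <- dilate_mask_mm(implant_mask, sp, band_mm) & !implant_mask
  if (!any(region)) stop("empty band region around the implant")
  sums <- vapply(seq_len(d[4]), function(b) {
    m <- stack$data[, , , b, drop = FALSE]
    dim(m) <- d[1:3]
    sum(Mod(m)[region])
  }, numeric(1))
  if (sum(sums) == 0) stop("no signal in the band region")
  100 * sums / sum(sums)
}
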