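#' Reconstruct per-bin images from k-space
#'
#' Per-bin, per-slice 2D inverse Fourier transform with the unitary
#' normalization used throughout the package (Parseval-exact, so k-space and
#' image-domain noise sigmas coincide).
#'
#' @param kstack a k-space-domain [bin_stack()].
#' @return an image-domain [bin_stack()] of the same dimensions.
#' @export
reconstruct_bins <- function(kstack) {
  stopifnot(inherits(kstack, "bin_stack"))
  if (kstack$domain != "kspace")
    stop("reconstruct_bins expects a k-space-domain stack")
  d <- dim(kstack$data)
  img <- array(0i, dim = d)
  for (s in seq_len(d[3])) for (b in seq_len(d[4]))
    img[, , s, b] <- ifft2_unitary(kstack$data[, , s, b])
  out <- kstack
  out$data <- img
  out$domain <- "image"
  out
}

#' Root sum-of-squares combination over bins
#'
#' Per-pixel sqrt of the sum over bins of the squared magnitude; the final
#' image of a multi-spectral acquisition. Invariant under bin reordering and
#' per-bin global phase.
#'
#' @param stack an image-domain [bin_stack()] with at least one bin.
#' @return real non-negative array (freq, phase, slice).
#' @export
combine_rsos <- function(stack) {
  stopifnot(inherits(stack, "bin_stack"))
  if (stack$domain != "image")
    stop("combine_rsos expects an image-domain stack (reconstruct first)")
  d <- dim(stack$data)
  if (d[4] < 1) stop("empty bin stack")
  out <- array(0, dim = d[1:3])
  for (b in seq_len(d[4])) {
    m <- stack$data[, , , b, drop = FALSE]
    dim(m) <- d[1:3]
    out <- out + Mod(m)^2
  }
  sqrt(out)
}
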