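#' Physics constants
#'
#' @param gamma_bar proton gyromagnetic ratio / 2 pi, Hz per Tesla.
#' @return object of class `physics_constants`.
#' @export
physics_constants <- function(gamma_bar = 42.5775e6) {
  if (gamma_bar <= 0) stop("gamma_bar must be > 0")
  structure(list(gamma_bar = gamma_bar), class = "physics_constants")
}

# discrete sample frequencies (cycles/mm) for an n-point axis of spacing d
fft_freqs <- function(n, d) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-ceiling((n - 1) / 2), -1))
  k / (n * d)
}

#' k-space dipole kernel
#'
#' The unit-dipole field response in the Fourier domain,
#' D(k) = 1/3 - k_b^2 / |k|^2 with k_b the component along the B0 axis,
#' evaluated analytically at the discrete frequency samples. The DC sample
#' is set to 0 (demodulation at the bulk frequency), so D is bounded in
#' [-2/3, 1/3].
#'
#' @param shape integer triple.
#' @param spacing mm triple.
#' @param b0_axis axis (1..3) of the main field.
#' @return numeric array of dim `shape`.
#' @export
dipole_kernel <- function(shape, spacing, b0_axis = 3L) {
  shape <- as.integer(shape)
  if (any(shape < 1)) stop("shape entries must be >= 1")
  spacing <- rep_len(as.numeric(spacing), 3L)
  fx <- fft_freqs(shape[1], spacing[1])
  fy <- fft_freqs(shape[2], spacing[2])
  fz <- fft_freqs(shape[3], spacing[3])
  k2 <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  kb2 <- switch(b0_axis,
                outer(outer(fx^2, rep(0, shape[2]), `+`), rep(0, shape[3]), `+`),
                outer(outer(rep(0, shape[1]), fy^2, `+`), rep(0, shape[3]), `+`),
                outer(outer(rep(0, shape[1]), rep(0, shape[2]), `+`), fz^2, `+`))
  D <- 1 / 3 - kb2 / k2
  D[k2 == 0] <- 0
  D
}

#' Susceptibility-induced off-resonance map
#'
#' Computes the field shift Delta f (Hz) induced by a susceptibility
#' distribution by Fourier-domain convolution with the dipole kernel:
#' delta_f = gamma_bar * B0 * IFT( D(k) * FT(chi * 1e-6) ). The chi volume
#' is zero-padded by `pad_factor` per axis (padding filled with a reference
#' susceptibility, by default the dominant value on the volume boundary) to
#' suppress circular-convolution wrap-around, then cropped back. The
#' operator is linear in chi and in B0; a spatially uniform chi yields an
#' identically zero map (DC convention).
#'
#' @param chi_ppm susceptibility array in ppm (or a `parameter_maps` object,
#'   whose `chi_ppm` component is used).
#' @param grid the [voxel_grid()] of `chi_ppm`.
#' @param b0 field strength, Tesla.
#' @param constants a [physics_constants()].
#' @param pad_factor integer >= 1, per-axis zero-padding factor (default 2).
#' @param chi_ref ppm value filling the padding; default: most frequent chi
#'   value on the six boundary faces.
#' @return object of class `field_shift_map`: list(grid, delta_f_hz, b0).
#' @export
susceptibility_to_fieldshift <- function(chi_ppm, grid = NULL, b0,
                                         constants = physics_constants(),
                                         pad_factor = 2L, chi_ref = NULL) {
  if (inherits(chi_ppm, "parameter_maps")) {
    grid <- chi_ppm$grid
    chi_ppm <- chi_ppm$chi_ppm
  }
  stopifnot(inherits(grid, "voxel_grid"))
  if (!all(is.finite(chi_ppm))) stop("chi map contains non-finite values")
  pad_factor <- as.integer(pad_factor)
  if (pad_factor < 1) stop("pad_factor must be >= 1")
  n <- grid$shape
  if (is.null(chi_ref)) chi_ref <- boundary_mode(chi_ppm)
  np <- n * pad_factor
  chi_pad <- array(chi_ref, dim = np)
  off <- floor((np - n) / 2)
  chi_pad[off[1] + seq_len(n[1]), off[2] + seq_len(n[2]),
          off[3] + seq_len(n[3])] <- chi_ppm
  D <- dipole_kernel(np, grid$spacing, grid$b0_axis)
  F <- stats::fft(chi_pad * 1e-6)
  df_pad <- Re(stats::fft(D * F, inverse = TRUE)) / prod(np)
  df_pad <- constants$gamma_bar * b0 * df_pad
  delta_f <- df_pad[off[1] + seq_len(n[1]), off[2] + seq_len(n[2]),
                    off[3] + seq_len(n[3])]
  structure(list(grid = grid, delta_f_hz = delta_f, b0 = b0),
            class = "field_shift_map")
}

# most frequent value among the six boundary faces of a 3D array
boundary_mode <- function(a) {
  n <- dim(a)
  vals <- c(a[1, , ], a[n[1], , ], a[, 1, ], a[, n[2], ],
            a[, , 1], a[, , n[3]])
  tb <- table(vals)
  as.numeric(names(tb)[which.max(tb)])
}

#' Closed-form external field of a susceptibility sphere
#'
#' Reference solution for a sphere of susceptibility contrast `dchi_ppm`
#' and radius `a_mm` centered at `center`, in the Lorentz-sphere convention:
#' outside, delta_f = gamma_bar*B0*(dchi*1e-6/3)*(a/r)^3*(3 cos^2 theta - 1)
#' with theta measured from the B0 axis; inside, delta_f = 0. Used as an
#' independent oracle for the Fourier dipole computation.
#'
#' @param grid a [voxel_grid()].
#' @param center mm triple.
#' @param a_mm sphere radius, mm.
#' @param dchi_ppm susceptibility contrast (sphere minus background), ppm.
#' @param b0 Tesla.
#' @param constants a [physics_constants()].
#' @return numeric array of delta_f in Hz.
#' @export
sphere_field_analytic <- function(grid, center, a_mm, dchi_ppm, b0,
                                  constants = physics_constants()) {
  cc <- grid_coord_arrays(grid)
  vx <- cc$x - center[1]; vy <- cc$y - center[2]; vz <- cc$z - center[3]
  r2 <- vx^2 + vy^2 + vz^2
  vb <- switch(grid$b0_axis, vx, vy, vz)
  cos2 <- ifelse(r2 > 0, vb^2 / r2, 0)
  r3 <- pmax(r2, .Machine$double.eps)^(3 / 2)
  df <- constants$gamma_bar * b0 * (dchi_ppm * 1e-6 / 3) *
    (a_mm^3 / r3) * (3 * cos2 - 1)
  df[r2 <= a_mm^2] <- 0
  df
}
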