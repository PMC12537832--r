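#' Synthesize a multi-echo complex GRE signal from a phantom
#'
#' Per voxel and echo j the noiseless signal is
#' \deqn{S_j = m\,e^{-R_2^* TE_j}\, e^{i(\phi_0 + 2\pi \bar\gamma B_0
#'   f_{ppm} 10^{-6} TE_j)}}
#' where `f_ppm` is the forward dipole field of the phantom susceptibility
#' plus any background field, and `m`, `R2*` come from the phantom maps.
#' Independent complex Gaussian noise of standard deviation
#' `acq$noise_sigma * max(m)` per real/imaginary channel is added to every
#' echo (white-noise approximation of SENSE-reconstructed data).
#'
#' @param phantom a [make_dgm_phantom()] result (any list with `chi`,
#'   `r2star_map`, `magnitude_map`, `grid`).
#' @param acq an [acq_params()].
#' @param background optional 3-D array, background field in ppm added to
#'   the dipole field of `chi` (e.g. from [background_field()]).
#' @param phi0 scalar or 3-D array, receiver phase offset in rad.
#' @param seed integer seed for the noise draw.
#' @return object of class `multiecho_signal`: list with `signal` (4-D
#'   complex array, last dimension echo), `acq`, `grid`.
#' @export
synthesize_multiecho <- function(phantom, acq = acq_params(),
                                 background = NULL, phi0 = 0.3,
                                 seed = 1L) {
  stopifnot(inherits(acq, "acq_params"))
  grid <- phantom$grid
  D <- dipole_kernel(grid)
  f_ppm <- forward_field(phantom$chi, D)
  if (!is.null(background)) {
    if (!identical(dim(background), dim(f_ppm)))
      stop("shape mismatch between background field and phantom")
    f_ppm <- f_ppm + background
  }
  f_hz <- ppm_to_hz(f_ppm, acq$b0)
  te_s <- acq$echo_times / 1000
  ne <- length(te_s)
  s <- grid$shape
  sig <- array(0i, c(s, ne))
  if (length(phi0) == 1) phi0 <- array(phi0, s)
  for (j in seq_len(ne)) {
    sig[, , , j] <- phantom$magnitude_map *
      exp(-phantom$r2star_map * te_s[j]) *
      exp(1i * (phi0 + 2 * pi * f_hz * te_s[j]))
  }
  if (acq$noise_sigma > 0) {
    sd_abs <- acq$noise_sigma * max(phantom$magnitude_map)
    noise <- with_seed(seed, {
      complex(real = rnorm(length(sig), 0, sd_abs),
              imaginary = rnorm(length(sig), 0, sd_abs))
    })
    sig <- sig + array(noise, dim(sig))
  }
  structure(list(signal = sig, acq = acq, grid = grid,
                 field_ppm = f_ppm, seed = seed),
            class = "multiecho_signal")
}

#' Synthesize a background field from sources outside the brain
#'
#' Places uniform susceptibility in the region outside a brain mask (an
#' air/skull surrogate) and returns its forward dipole field, so that a
#' total-field method has a realistic slowly varying background to absorb.
#'
#' @param phantom a phantom with `brain_mask` and `grid`.
#' @param chi_background susceptibility of the exterior sources, ppm.
#' @return 3-D array, background field in ppm.
#' @export
background_field <- function(phantom, chi_background = 0.5) {
  chib <- array(0, phantom$grid$shape)
  chib[!phantom$brain_mask] <- chi_background
  forward_field(chib, dipole_kernel(phantom$grid))
}

#' @export
print.multiecho_signal <- function(x, ...) {
  d <- dim(x$signal)
  cat("multiecho_signal:", paste(d[1:3], collapse = "x"), "voxels,",
      d[4], "echoes, TE =", paste(x$acq$echo_times, collapse = ", "),
      "ms, noise_sigma =", x$acq$noise_sigma, "\n")
  invisible(x)
}
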