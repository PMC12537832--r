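#' Unit dipole kernel in k-space
#'
#' Builds the discrete frequency-domain dipole kernel
#' \deqn{D(k) = 1/3 - (k \cdot \hat b_0)^2 / |k|^2}
#' on the FFT frequency grid of the given voxel geometry. The k = 0 sample
#' is set to 0 by convention, which fixes the (otherwise arbitrary) spatial
#' mean of any forward field at zero.
#'
#' @param grid a [grid_spec()].
#' @return a 3-D numeric array of kernel values, same shape as the grid.
#' @examples
#' D <- dipole_kernel(grid_spec(c(8, 8, 8)))
#' D[1, 1, 2]  # k along +z (B0): 1/3 - 1 = -2/3
#' @export
dipole_kernel <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  s <- grid$shape; v <- grid$voxel_size; b0 <- grid$b0_direction
  freqs <- function(n, d) {
    k <- 0:(n - 1)
    k[k >= n / 2] <- k[k >= n / 2] - n
    k / (n * d)
  }
  kx <- freqs(s[1], v[1]); ky <- freqs(s[2], v[2]); kz <- freqs(s[3], v[3])
  KX <- array(rep(kx, times = s[2] * s[3]), dim = s)
  KY <- array(rep(rep(ky, each = s[1]), times = s[3]), dim = s)
  KZ <- array(rep(kz, each = s[1] * s[2]), dim = s)
  k2 <- KX^2 + KY^2 + KZ^2
  kb <- KX * b0[1] + KY * b0[2] + KZ * b0[3]
  D <- 1 / 3 - kb^2 / k2
  D[1, 1, 1] <- 0
  D
}

#' Forward dipole field of a susceptibility distribution
#'
#' Computes the Lorentz-corrected field perturbation (in ppm) induced by a
#' susceptibility volume (in ppm) by k-space multiplication with the dipole
#' kernel: `field = IFT(D * FT(chi))`. Linear in `chi`; the output has zero
#' spatial mean because `D(0) = 0`.
#'
#' @param chi 3-D numeric array, susceptibility in ppm.
#' @param kernel dipole kernel from [dipole_kernel()], same shape.
#' @return 3-D numeric array, field in ppm.
#' @export
forward_field <- function(chi, kernel) {
  if (!identical(dim(chi), dim(kernel)))
    stop("shape mismatch between chi and kernel")
  Re(stats::fft(kernel * stats::fft(chi), inverse = TRUE)) / length(chi)
}
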