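#' Define the voxel grid and B0 convention
#'
#' A grid specification carries the array shape, voxel size in mm, and the
#' unit vector of the static field direction in voxel coordinates. It is the
#' single place where the coordinate convention lives: axes are ordered
#' `[x, y, z]` RAS-like, voxel indices are 0-based in world-coordinate
#' formulas, and B0 defaults to +z.
#'
#' @param shape integer length-3, array dimensions (each >= 8).
#' @param voxel_size numeric length-3, voxel edge lengths in mm (> 0).
#' @param b0_direction numeric length-3 unit vector, direction of B0.
#' @return an object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(64, 64, 64), c(1, 1, 1))
#' @export
grid_spec <- function(shape = c(64L, 64L, 64L),
                      voxel_size = c(1, 1, 1),
                      b0_direction = c(0, 0, 1)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, length(voxel_size) == 3,
            length(b0_direction) == 3)
  if (any(shape < 8L)) stop("all grid dimensions must be >= 8")
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  nb <- sqrt(sum(b0_direction^2))
  if (abs(nb - 1) > 1e-9) stop("b0_direction must be a unit vector")
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 b0_direction = as.numeric(b0_direction)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("grid_spec:", paste(x$shape, collapse = " x "), "voxels,",
      paste(x$voxel_size, collapse = " x "), "mm, B0 = (",
      paste(signif(x$b0_direction, 3), collapse = ", "), ")\n")
  invisible(x)
}

#' Multi-echo GRE acquisition parameters
#'
#' Defaults follow a 3 T protocol with six monopolar echoes, first echo
#' 6 ms, echo spacing 6.4 ms, TR 41.75 ms, flip angle 20 degrees.
#'
#' @param echo_times numeric, echo times in ms, strictly increasing,
#'   length >= 2.
#' @param tr repetition time, ms.
#' @param flip_angle flip angle, degrees.
#' @param b0 field strength, Tesla.
#' @param noise_sigma complex Gaussian noise standard deviation per channel,
#'   as a fraction of the maximum signal magnitude (>= 0).
#' @return an object of class `acq_params`.
#' @export
acq_params <- function(echo_times = 6 + 6.4 * (0:5),
                       tr = 41.75, flip_angle = 20, b0 = 3,
                       noise_sigma = 0) {
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 2) stop("need at least 2 echo times")
  if (any(diff(echo_times) <= 0)) stop("echo_times must be strictly increasing")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(echo_times = echo_times, tr = tr, flip_angle = flip_angle,
                 b0 = b0, noise_sigma = noise_sigma),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("acq_params:", length(x$echo_times), "echoes, TE =",
      paste(x$echo_times, collapse = ", "), "ms, TR =", x$tr,
      "ms, FA =", x$flip_angle, "deg, B0 =", x$b0,
      "T, noise_sigma =", x$noise_sigma, "\n")
  invisible(x)
}

# voxel-center world coordinates (mm, origin at grid center) as three arrays
grid_coords <- function(grid) {
  s <- grid$shape; v <- grid$voxel_size
  cc <- (s + 1) / 2
  xs <- (seq_len(s[1]) - cc[1]) * v[1]
  ys <- (seq_len(s[2]) - cc[2]) * v[2]
  zs <- (seq_len(s[3]) - cc[3]) * v[3]
  list(x = array(rep(xs, times = s[2] * s[3]), dim = s),
       y = array(rep(rep(ys, each = s[1]), times = s[3]), dim = s),
       z = array(rep(zs, each = s[1] * s[2]), dim = s))
}
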