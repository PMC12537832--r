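#' Per-voxel signal-model fit of multi-echo complex data
#'
#' Estimates the four parameters of the mono-exponential complex signal
#' model per voxel: magnitude `m` and relaxation rate `R2*` by a log-linear
#' fit to the echo magnitudes, and field `f` (Hz) plus phase offset `phi0`
#' (rad) by a magnitude-squared-weighted linear fit to the temporally
#' unwrapped echo phases (greedy nearest-2*pi unwrapping from echo 1; no
#' spatial unwrapping).
#'
#' Voxels with any zero echo magnitude are flagged and excluded from the fit
#' mask (`fit_mask`); at least 3 echoes are required to identify the four
#' parameters.
#'
#' @param signal a [synthesize_multiecho()] object (or compatible list).
#' @param mask logical 3-D array of voxels to fit; defaults to all voxels.
#' @return object of class `field_model_fit`: volumes `m` (a.u.), `r2star`
#'   (1/s, clamped at 0), `phi0` (rad, wrapped to (-pi, pi]), `f_hz` (Hz),
#'   `residual` (RMS phase-fit residual, rad), logical `fit_mask`, plus the
#'   acquisition metadata.
#' @export
fit_signal_model <- function(signal, mask = NULL) {
  sig <- signal$signal
  d <- dim(sig)
  shape <- d[1:3]; ne <- d[4]
  if (ne < 3) stop("need at least 3 echoes to fit (m, R2*, phi0, f)")
  te_s <- signal$acq$echo_times / 1000
  if (is.null(mask)) mask <- array(TRUE, shape)

  Sm <- matrix(sig, ncol = ne)[which(mask), , drop = FALSE]
  A <- Mod(Sm)
  good <- rowSums(A <= 0) == 0

  m <- r2 <- fhz <- p0 <- resid <- rep(NA_real_, nrow(Sm))
  if (any(good)) {
    Ag <- A[good, , drop = FALSE]
    # magnitude: log|S_j| = log m - R2* TE_j
    L <- log(Ag)
    te_c <- te_s - mean(te_s)
    slope <- (L %*% te_c) / sum(te_c^2)
    m[good] <- exp(rowMeans(L) - slope * mean(te_s))
    r2[good] <- pmax(-slope, 0)
    # phase: temporal unwrap then weighted least squares, weights |S|^2
    P <- Arg(Sm[good, , drop = FALSE])
    dP <- P[, -1, drop = FALSE] - P[, -ne, drop = FALSE]
    dP <- dP - 2 * pi * round(dP / (2 * pi))
    Pu <- P
    for (j in 2:ne) Pu[, j] <- Pu[, j - 1] + dP[, j - 1]
    W <- Ag^2
    sw <- rowSums(W)
    tw <- (W %*% te_s) / sw
    pw <- rowSums(W * Pu) / sw
    ted <- matrix(te_s, nrow(W), ne, byrow = TRUE) - c(tw)
    b <- rowSums(W * ted * (Pu - c(pw))) / rowSums(W * ted^2)
    fhz[good] <- b / (2 * pi)
    ph <- c(pw) - b * c(tw)
    p0[good] <- atan2(sin(ph), cos(ph))
    pred <- ph + outer(b, te_s)
    resid[good] <- sqrt(rowMeans((Pu - pred)^2))
  }

  put <- function(vals, fill = 0) {
    out <- array(fill, shape)
    out[which(mask)] <- ifelse(is.na(vals), fill, vals)
    out
  }
  fm <- array(FALSE, shape)
  fm[which(mask)] <- good
  structure(list(m = put(m), r2star = put(r2), phi0 = put(p0),
                 f_hz = put(fhz), residual = put(resid),
                 fit_mask = fm, acq = signal$acq, grid = signal$grid),
            class = "field_model_fit")
}

#' Echo-time-weighted magnitude image
#'
#' Averages the echo magnitudes with weights proportional to the echo time:
#' `W(x) = sum_j TE_j |S_j(x)| / sum_j TE_j`. Late echoes, whose phase
#' carries most susceptibility contrast, dominate; the normalization by
#' `sum TE_j` keeps the image on the scale of the input magnitudes.
#'
#' @param signal a [synthesize_multiecho()] object.
#' @return 3-D numeric array.
#' @export
echo_time_weighted_magnitude <- function(signal) {
  sig <- signal$signal
  te <- signal$acq$echo_times
  d <- dim(sig)
  out <- array(0, d[1:3])
  for (j in seq_len(d[4])) out <- out + te[j] * Mod(sig[, , , j])
  out / sum(te)
}
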