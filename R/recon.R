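## Internal solver utilities -------------------------------------------------

# forward difference along one axis, Neumann boundary (last slice zero)
fdiff <- function(x, axis) {
  d <- dim(x); g <- array(0, d)
  if (axis == 1) g[-d[1], , ] <- x[-1, , ] - x[-d[1], , ]
  else if (axis == 2) g[, -d[2], ] <- x[, -1, ] - x[, -d[2], ]
  else g[, , -d[3]] <- x[, , -1] - x[, , -d[3]]
  g
}

# adjoint of fdiff (negative divergence with matching boundary handling)
fdiff_adj <- function(g, axis) {
  d <- dim(g); x <- array(0, d)
  if (axis == 1) { x[-1, , ] <- -g[-d[1], , ]; x[-d[1], , ] <- x[-d[1], , ] + g[-d[1], , ] }
  else if (axis == 2) { x[, -1, ] <- -g[, -d[2], ]; x[, -d[2], ] <- x[, -d[2], ] + g[, -d[2], ] }
  else { x[, , -1] <- -g[, , -d[3]]; x[, , -d[3]] <- x[, , -d[3]] + g[, , -d[3]] }
  -x
}

apply_kernel <- function(x, D) {
  Re(stats::fft(D * stats::fft(x), inverse = TRUE)) / length(x)
}

# symbol of the discrete Laplacian (sum over axes of 4 sin^2(pi k / n))
laplace_symbol <- function(shape) {
  f <- lapply(shape, function(n) 4 * sin(pi * (0:(n - 1)) / n)^2)
  array(outer(outer(f[[1]], f[[2]], "+"), f[[3]], "+"), shape)
}

# preconditioned conjugate gradient for SPD operator closures
pcg_solve <- function(Amul, b, x0, Minv = identity, iters = 60, tol = 1e-6) {
  x <- x0
  r <- b - Amul(x)
  z <- Minv(r)
  p <- z
  rz <- sum(r * z)
  b2 <- sum(b * b)
  if (b2 == 0) return(x)
  for (it in seq_len(iters)) {
    Ap <- Amul(p)
    den <- sum(p * Ap)
    if (den <= 0) break
    al <- rz / den
    x <- x + al * p
    r <- r - al * Ap
    if (sum(r * r) < tol^2 * b2) break
    z <- Minv(r)
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  x
}

## Edge weights ---------------------------------------------------------------

#' Binary TV edge weights from a magnitude image
#'
#' Per axis, voxels whose absolute forward-difference gradient of the
#' echo-time-weighted magnitude exceeds the `edge_percentile`-th percentile
#' (computed within the mask) get weight 0 — anatomical edges are exempted
#' from the total-variation penalty — and all others weight 1 (the MEDI
#' gradient-mask convention). A constant image yields all-ones weights.
#'
#' @param etw 3-D array, typically from [echo_time_weighted_magnitude()].
#' @param mask logical array over which the percentile is computed.
#' @param edge_percentile percentile in (0, 100); default 70 marks about
#'   30 percent of masked voxels as edges.
#' @return list of three binary arrays, one per axis.
#' @export
gradient_edge_weights <- function(etw, mask, edge_percentile = 70) {
  if (!any(mask)) stop("mask is empty")
  if (edge_percentile <= 0 || edge_percentile >= 100)
    stop("edge_percentile must be in (0, 100)")
  lapply(1:3, function(a) {
    g <- abs(fdiff(etw, a))
    thr <- stats::quantile(g[mask], edge_percentile / 100, names = FALSE)
    # guard band: exact ties at the threshold (common in piecewise-constant
    # synthetic images) must not flip with last-ulp perturbations
    tol <- 1e-9 * max(g[mask], 1e-300)
    w <- array(1, dim(etw))
    w[g > thr + tol] <- 0
    w
  })
}

## Parameters -----------------------------------------------------------------

#' Reconstruction parameters for TFI / mTFI
#'
#' @param lambda_tv total-variation weight of the mTFI stage (> 0). The
#'   default was fixed once by an L-curve sweep on the default phantom.
#' @param lambda_tv_init TV weight of the linear total-field-inversion
#'   initializer.
#' @param edge_percentile percentile for [gradient_edge_weights()].
#' @param max_outer_iters Gauss-Newton outer iterations of mTFI.
#' @param init_outer_iters outer iterations of the initializer.
#' @param cg_iters inner (preconditioned) conjugate-gradient iterations.
#' @param tol relative objective-change stopping tolerance (> 0).
#' @param cg_tol relative-residual stopping tolerance of the inner CG.
#' @param preconditioner_scale amplification of the susceptibility update
#'   outside the brain mask, where air/bone sources are orders of magnitude
#'   stronger than tissue.
#' @param eps_tv smoothing of the l1 TV term in the objective, ppm.
#' @param eps_irls floor for the IRLS reweighting denominators, ppm (a
#'   larger floor than `eps_tv` keeps the Gauss-Newton systems well
#'   conditioned; descent is still measured on the `eps_tv` objective).
#' @param seed integer seed (reconstruction is deterministic; kept for
#'   provenance).
#' @return object of class `recon_params`.
#' @export
recon_params <- function(lambda_tv = 2e-5, lambda_tv_init = 1e-4,
                         edge_percentile = 70, max_outer_iters = 10,
                         init_outer_iters = 5, cg_iters = 60,
                         tol = 1e-4, cg_tol = 1e-6,
                         preconditioner_scale = 30,
                         eps_tv = 1e-6, eps_irls = 1e-4, seed = 1L) {
  if (lambda_tv <= 0 || lambda_tv_init <= 0) stop("lambda_tv must be > 0")
  if (tol <= 0) stop("tol must be > 0")
  if (edge_percentile <= 0 || edge_percentile >= 100)
    stop("edge_percentile must be in (0, 100)")
  structure(as.list(environment()), class = "recon_params")
}

# shared machinery: one Gauss-Newton/IRLS step on chi = P * y.
# Returns the CG solution for  (H + lam * TVH) dy = -grad.
gn_step <- function(grad_y, Amul, Minv, cg_iters, cg_tol = 1e-6) {
  pcg_solve(Amul, -grad_y, array(0, dim(grad_y)), Minv, iters = cg_iters,
            tol = cg_tol)
}

tv_value <- function(chi, MG, eps) {
  s <- 0
  for (a in 1:3) s <- s + sum(MG[[a]] * sqrt(fdiff(chi, a)^2 + eps^2))
  s
}

## Total field inversion initializer -----------------------------------------

#' Preconditioned total field inversion of a fitted field map
#'
#' Solves the whole-field-of-view linear inverse problem
#' \deqn{\min_\chi \|w\,(f_{ppm} - D * \chi)\|_2^2 +
#'   \lambda \|M_G \nabla \chi\|_1}
#' with the substitution `chi = P y`, where the binary preconditioner `P`
#' boosts the expected strong sources outside the brain mask. No separate
#' background-field-removal step exists: background sources are absorbed by
#' the exterior part of `chi`. Used as the initializer of
#' [mtfi_reconstruct()].
#'
#' @param fit a [fit_signal_model()] result.
#' @param kernel dipole kernel of the grid.
#' @param params a [recon_params()].
#' @param brain_mask logical array.
#' @param weights optional reliability weights; default is the mean echo
#'   magnitude normalized to max 1.
#' @param edge_weights optional precomputed [gradient_edge_weights()].
#' @param signal optional `multiecho_signal` used to derive default weights.
#' @return list with `chi` (ppm, whole FOV), `objective` (per-iteration
#'   log), `converged` flag.
#' @export
total_field_inversion_init <- function(fit, kernel, params, brain_mask,
                                       weights = NULL, edge_weights = NULL,
                                       signal = NULL) {
  shape <- dim(fit$f_hz)
  if (is.null(weights)) {
    if (!is.null(signal)) {
      w <- array(0, shape)
      for (j in seq_len(dim(signal$signal)[4]))
        w <- w + Mod(signal$signal[, , , j])
      w <- w / max(w)
    } else {
      w <- fit$m / max(fit$m)
    }
    weights <- w * fit$fit_mask
  }
  if (is.null(edge_weights))
    edge_weights <- lapply(1:3, function(a) array(1, shape))
  MG <- edge_weights
  lam <- params$lambda_tv_init
  eps_o <- params$eps_tv; eps_w <- params$eps_irls
  fp <- hz_to_ppm(fit$f_hz, fit$acq$b0)
  w2 <- weights^2
  P <- array(1, shape); P[!brain_mask] <- params$preconditioner_scale
  L <- laplace_symbol(shape)
  obj <- function(y) {
    chi <- P * y
    sum((weights * (fp - apply_kernel(chi, kernel)))^2) +
      lam * tv_value(chi, MG, eps_o)
  }
  y <- array(0, shape)
  ob <- obj(y)
  olog <- ob
  converged <- FALSE
  for (k in seq_len(params$init_outer_iters)) {
    chi <- P * y
    R <- lapply(1:3, function(a)
      MG[[a]] / sqrt(fdiff(chi, a)^2 + eps_w^2))
    c1 <- 2 * mean(w2)
    c2 <- lam * mean(vapply(R, mean, 0))
    Msym <- c1 * kernel^2 + c2 * L + c1 * 1e-3
    Minv <- function(r) Re(stats::fft(stats::fft(r) / Msym, inverse = TRUE)) / length(r)
    Amul <- function(v) {
      Pv <- P * v
      out <- 2 * apply_kernel(w2 * apply_kernel(Pv, kernel), kernel)
      for (a in 1:3) out <- out + lam * fdiff_adj(R[[a]] * fdiff(Pv, a), a)
      P * out
    }
    g <- -2 * apply_kernel(w2 * (fp - apply_kernel(chi, kernel)), kernel)
    for (a in 1:3) g <- g + lam * fdiff_adj(R[[a]] * fdiff(chi, a), a)
    d <- gn_step(P * g, Amul, Minv, params$cg_iters, params$cg_tol)
    tstep <- 1
    repeat {
      on <- obj(y + tstep * d)
      if (on <= ob) { y <- y + tstep * d; ob <- on; break }
      tstep <- tstep / 2
      if (tstep < 1e-4) break
    }
    olog <- c(olog, ob)
    if (abs(diff(tail(olog, 2))) < params$tol * max(ob, 1e-12)) {
      converged <- TRUE
      break
    }
  }
  list(chi = P * y, objective = olog, converged = converged)
}

## mTFI -----------------------------------------------------------------------

#' Multi-echo complex total field inversion (mTFI)
#'
#' Reconstructs a susceptibility map directly from multi-echo complex data
#' over the whole field of view, with no separate background-field-removal
#' step. The objective is a magnitude-weighted complex-exponential misfit
#' summed over echoes,
#' \deqn{\sum_j \| m e^{-R_2^* TE_j}\,(e^{i\theta_j(\chi)} -
#'   e^{i\angle S_j})\,|S_j|/\max|S| \|_2^2 +
#'   \lambda_{tv}\, \| M_G \nabla \chi \|_1,}
#' \eqn{\theta_j(\chi) = \phi_0 + 2\pi\bar\gamma B_0 (D * \chi) 10^{-6}
#' TE_j}, minimized by block-alternating updates: the per-voxel nuisance
#' parameters (`m`, `R2*` once from the echo magnitudes; `phi0` each outer
#' iteration by its closed-form minimizer) and `chi` by Gauss-Newton steps
#' with IRLS-weighted TV and preconditioned conjugate-gradient inner
#' solves, initialized from [total_field_inversion_init()]. A backtracking
#' line search guarantees a non-increasing objective log. The result is
#' CSF-referenced via [csf_reference()].
#'
#' @param signal a [synthesize_multiecho()] object (>= 3 echoes).
#' @param brain_mask,csf_mask logical arrays. An empty CSF mask gives an
#'   unreferenced map with `referenced = FALSE`.
#' @param params a [recon_params()].
#' @return object of class `susceptibility_map`: `chi` (ppm, referenced),
#'   `chi_unreferenced`, `reference_region`, `reference_value`, `objective`
#'   (per outer iteration, non-increasing), `params`, `converged`,
#'   `diverged`, masks and grid metadata.
#' @export
mtfi_reconstruct <- function(signal, brain_mask, csf_mask,
                             params = recon_params()) {
  sig <- signal$signal
  d <- dim(sig)
  shape <- d[1:3]; ne <- d[4]
  if (ne < 3) stop("mTFI needs at least 3 echoes")
  stopifnot(identical(dim(brain_mask), shape),
            identical(dim(csf_mask), shape))
  te_s <- signal$acq$echo_times / 1000
  b0 <- signal$acq$b0
  kernel <- dipole_kernel(signal$grid)

  fit <- fit_signal_model(signal)
  etw <- echo_time_weighted_magnitude(signal)
  MG <- gradient_edge_weights(etw, brain_mask, params$edge_percentile)

  init <- total_field_inversion_init(fit, kernel, params, brain_mask,
                                     edge_weights = MG, signal = signal)

  maxS <- max(Mod(sig))
  cj <- 2 * pi * ppm_to_hz(1, b0) * te_s   # rad per ppm of chi, per echo
  phiS <- Arg(sig)
  W2 <- array(0, d)
  for (j in seq_len(ne)) {
    wj <- fit$m * exp(-fit$r2star * te_s[j]) * Mod(sig[, , , j]) / maxS
    wj[!fit$fit_mask] <- 0      # degenerate voxels excluded from fidelity
    W2[, , , j] <- wj^2
  }
  a2 <- array(0, shape)
  for (j in seq_len(ne)) a2 <- a2 + 2 * cj[j]^2 * W2[, , , j]

  lam <- params$lambda_tv
  eps_o <- params$eps_tv; eps_w <- params$eps_irls
  P <- array(1, shape); P[!brain_mask] <- params$preconditioner_scale
  L <- laplace_symbol(shape)

  obj <- function(chi, phi0) {
    fd <- apply_kernel(chi, kernel)
    s <- 0
    for (j in seq_len(ne))
      s <- s + sum(W2[, , , j] *
                     (2 - 2 * cos(phi0 + cj[j] * fd - phiS[, , , j])))
    s + lam * tv_value(chi, MG, eps_o)
  }

  chi <- init$chi
  phi0 <- fit$phi0
  olog <- numeric(0)
  diverged <- FALSE
  for (k in seq_len(params$max_outer_iters)) {
    # phi0 block: exact per-voxel minimizer given the current field
    fd <- apply_kernel(chi, kernel)
    zr <- array(0, shape); zi <- array(0, shape)
    for (j in seq_len(ne)) {
      dphi <- phiS[, , , j] - cj[j] * fd
      zr <- zr + W2[, , , j] * cos(dphi)
      zi <- zi + W2[, , , j] * sin(dphi)
    }
    phi0 <- atan2(zi, zr)
    ob <- obj(chi, phi0)
    if (!is.finite(ob)) { diverged <- TRUE; break }

    # chi block: Gauss-Newton with IRLS TV weights
    g_vox <- array(0, shape)
    for (j in seq_len(ne))
      g_vox <- g_vox + 2 * cj[j] * W2[, , , j] *
        sin(phi0 + cj[j] * fd - phiS[, , , j])
    R <- lapply(1:3, function(a)
      MG[[a]] / sqrt(fdiff(chi, a)^2 + eps_w^2))
    c1 <- mean(a2)
    c2 <- lam * mean(vapply(R, mean, 0))
    Msym <- c1 * kernel^2 + c2 * L + c1 * 1e-3
    Minv <- function(r) Re(stats::fft(stats::fft(r) / Msym, inverse = TRUE)) / length(r)
    g <- apply_kernel(g_vox, kernel)
    for (a in 1:3) g <- g + lam * fdiff_adj(R[[a]] * fdiff(chi, a), a)
    Amul <- function(v) {
      Pv <- P * v
      out <- apply_kernel(a2 * apply_kernel(Pv, kernel), kernel)
      for (a in 1:3) out <- out + lam * fdiff_adj(R[[a]] * fdiff(Pv, a), a)
      P * out
    }
    dy <- gn_step(P * g, Amul, Minv, params$cg_iters, params$cg_tol)
    dchi <- P * dy
    tstep <- 1
    repeat {
      on <- obj(chi + tstep * dchi, phi0)
      if (is.finite(on) && on <= ob) { chi <- chi + tstep * dchi; ob <- on; break }
      tstep <- tstep / 2
      if (tstep < 1e-4) break
    }
    olog <- c(olog, ob)
    if (length(olog) >= 2 &&
        abs(diff(tail(olog, 2))) < params$tol * max(ob, 1e-12)) break
  }

  out <- structure(
    list(chi = chi, chi_unreferenced = chi, reference_region = "none",
         reference_value = 0, referenced = FALSE,
         objective = olog, init_objective = init$objective,
         converged = !diverged, diverged = diverged,
         params = params, grid = signal$grid,
         brain_mask = brain_mask, csf_mask = csf_mask),
    class = "susceptibility_map")
  if (any(csf_mask)) out <- csf_reference(out, csf_mask) else
    warning("empty CSF mask: returning unreferenced susceptibility map")
  out
}

#' Reference a susceptibility map to the CSF mean
#'
#' QSM determines susceptibility only up to a constant; subtracting the
#' mean over a cerebrospinal-fluid mask fixes the offset so that values are
#' reported relative to CSF. ROI-to-ROI differences are unchanged.
#'
#' @param chi a `susceptibility_map` or a plain 3-D array, ppm.
#' @param csf_mask nonempty logical array.
#' @return same type as the input, with CSF mean exactly 0.
#' @export
csf_reference <- function(chi, csf_mask) {
  if (!any(csf_mask)) stop("CSF mask is empty")
  if (inherits(chi, "susceptibility_map")) {
    ref <- mean(chi$chi_unreferenced[csf_mask])
    chi$chi <- chi$chi_unreferenced - ref
    chi$reference_region <- "csf"
    chi$reference_value <- ref
    chi$referenced <- TRUE
    chi
  } else {
    chi - mean(chi[csf_mask])
  }
}

#' @export
print.susceptibility_map <- function(x, ...) {
  cat("susceptibility_map:", paste(dim(x$chi), collapse = "x"),
      "voxels,", if (x$referenced) "CSF-referenced" else "unreferenced", "\n")
  cat("  objective:", paste(signif(x$objective, 4), collapse = " "), "\n")
  cat("  chi in brain: [", signif(min(x$chi[x$brain_mask]), 3), ",",
      signif(max(x$chi[x$brain_mask]), 3), "] ppm\n")
  invisible(x)
}

#' @export
summary.susceptibility_map <- function(object, labels = NULL, ...) {
  out <- list(objective = object$objective,
              monotone = all(diff(object$objective) <= 1e-9),
              reference = object$reference_region)
  if (!is.null(labels)) {
    ids <- sort(unique(labels[labels > 0]))
    out$roi_means <- vapply(ids, function(i) mean(object$chi[labels == i]), 0)
    names(out$roi_means) <- paste0("label", ids)
  }
  class(out) <- "summary.susceptibility_map"
  out
}

#' @export
print.summary.susceptibility_map <- function(x, ...) {
  cat("mTFI objective:", paste(signif(x$objective, 4), collapse = " "),
      "\n  monotone descent:", x$monotone,
      "\n  reference:", x$reference, "\n")
  if (!is.null(x$roi_means)) {
    cat("  ROI means (ppm):\n")
    print(signif(x$roi_means, 4))
  }
  invisible(x)
}
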