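# Independent brute-force oracles used to cross-check the implementation.

# average ranks computed by first principles (sort + tie groups)
oracle_rank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Spearman correlation as Pearson on oracle ranks, Pearson by explicit sums
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  rx <- oracle_rank(x[ok]); ry <- oracle_rank(y[ok])
  n <- length(rx)
  sx <- rx - sum(rx) / n; sy <- ry - sum(ry) / n
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

# Benjamini-Hochberg step-up by the textbook recipe
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# 26-connected components by iterative minimum-label propagation,
# structurally different from the package's BFS flood fill
oracle_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  repeat {
    changed <- FALSE
    idx <- which(mask)
    pts <- arrayInd(idx, d)
    for (r in seq_len(nrow(nb))) {
      q <- cbind(pts[, 1] + nb[r, 1], pts[, 2] + nb[r, 2], pts[, 3] + nb[r, 3])
      ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
        q[, 3] >= 1 & q[, 3] <= d[3]
      qi <- idx[ok]
      ni <- q[ok, 1] + (q[ok, 2] - 1) * d[1] + (q[ok, 3] - 1) * d[1] * d[2]
      nm <- mask[ni]
      both <- which(nm)
      if (length(both)) {
        a <- lab[qi[both]]; b <- lab[ni[both]]
        newl <- pmin(a, b)
        if (any(newl < a)) { lab[qi[both]] <- newl; changed <- TRUE }
        if (any(newl < b)) { lab[ni[both]] <- newl; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  # relabel 1..k
  u <- sort(unique(lab[lab > 0]))
  out <- array(0L, d)
  for (i in seq_along(u)) out[lab == u[i]] <- i
  out
}

# small phantom + signal shared across recon tests (2 mm voxels keep it fast)
small_phantom <- function(noise = 0, seed = 7L) {
  g <- grid_spec(c(32L, 32L, 32L), c(2, 2, 2))
  ph <- make_dgm_phantom(g)
  sg <- synthesize_multiecho(ph, acq_params(noise_sigma = noise), seed = seed)
  list(grid = g, phantom = ph, signal = sg)
}

quick_recon_params <- function(...) {
  args <- modifyList(list(max_outer_iters = 8, init_outer_iters = 4,
                          cg_iters = 40), list(...))
  do.call(recon_params, args)
}

# all-zero effect maps for null-calibration cohorts
null_effects <- function() {
  em <- default_effect_map()
  for (o in names(em)) {
    em[[o]]$qsm[] <- 0; em[[o]]$volume[] <- 0
    em[[o]]$age <- 0; em[[o]]$sex <- 0; em[[o]]$dd <- 0
  }
  em
}
# effect map with exactly one injected susceptibility effect
single_qsm_effect <- function(region, outcome, value) {
  em <- null_effects()
  em[[outcome]]$qsm[region] <- value
  em
}

null_long_effects <- function() {
  le <- default_longitudinal_effects()
  for (o in names(le)) {
    le[[o]]$qsm[] <- 0; le[[o]]$volume[] <- 0
    le[[o]]$age <- 0; le[[o]]$sex <- 0; le[[o]]$dd <- 0
  }
  le
}
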