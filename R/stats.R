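#' Pairwise Spearman correlation matrix with FDR correction
#'
#' Rank correlation (average ranks for ties) over pairwise-complete
#' observations, two-sided p-values from the t approximation
#' `t = r sqrt((n-2)/(1-r^2))`, and Benjamini-Hochberg correction across
#' the upper triangle. Pairs involving a constant variable are reported as
#' missing.
#'
#' @param table data frame (e.g. a [generate_cohort()] table).
#' @param variables character vector of numeric columns; default is the
#'   full baseline variable set (covariates, regional susceptibility and
#'   volume, MRI surrogates, clinical scores).
#' @return object of class `spearman_matrix`: matrices `r`, `p`,
#'   `p_corrected`, `n`.
#' @export
spearman_matrix <- function(table, variables = NULL) {
  if (is.null(variables))
    variables <- c("age", "sex", "disease_duration",
                   paste0("qsm_", DGM_REGIONS), paste0("vol_", DGM_REGIONS),
                   "nbv", "log_tlv", CLINICAL_OUTCOMES)
  miss <- setdiff(variables, names(table))
  if (length(miss)) stop("variables not in table: ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(table)[variables])
  k <- ncol(X)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  nm <- matrix(0L, k, k, dimnames = list(variables, variables))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) diag(nm)[i] <- sum(!is.na(X[, i]))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(X[, c(i, j)])
    n <- sum(ok)
    nm[i, j] <- nm[j, i] <- n
    if (n < 3) next
    xi <- X[ok, i]; xj <- X[ok, j]
    if (sd(xi) == 0 || sd(xj) == 0) next  # r undefined for constant variable
    rs <- cor(xi, xj, method = "spearman")
    r[i, j] <- r[j, i] <- rs
    tt <- rs * sqrt((n - 2) / max(1 - rs^2, .Machine$double.eps))
    p[i, j] <- p[j, i] <- 2 * pt(-abs(tt), df = n - 2)
  }
  ut <- upper.tri(r)
  padj <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  padj[ut] <- p.adjust(p[ut], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  diag(padj) <- 0
  structure(list(r = r, p = p, p_corrected = padj, n = nm,
                 variables = variables),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 2, ...) {
  cat("spearman_matrix over", length(x$variables), "variables\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Z-score numeric columns of a table
#'
#' Centers and scales the given columns to mean 0, sd 1. Binary 0/1
#' columns such as sex are conventionally left unscaled so their
#' coefficients read as female-to-male contrasts; this function therefore
#' refuses zero-variance columns rather than silently producing NaN.
#'
#' @param table data frame.
#' @param columns character vector of columns to standardize.
#' @return the table with the columns replaced by their z-scores.
#' @export
standardize <- function(table, columns) {
  for (cl in columns) {
    x <- table[[cl]]
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop(sprintf("column '%s' has zero variance", cl))
    table[[cl]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}

#' Ordinary least squares fit of a design matrix
#'
#' Complete-case least squares with explicit rank checking; a rank
#' deficiency is an error naming the collinear columns rather than a
#' silent NA coefficient.
#'
#' @param design numeric matrix including an intercept column.
#' @param outcome numeric response.
#' @return list with `coefficients`, `residuals`, `fitted`, `r_squared`,
#'   `sigma2`, `se`, `t`, `n`, `df_residual`, `qr`.
#' @export
fit_ols <- function(design, outcome) {
  ok <- stats::complete.cases(design) & !is.na(outcome)
  X <- design[ok, , drop = FALSE]
  y <- outcome[ok]
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("too few complete cases for the design")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  dfres <- n - p
  sigma2 <- sum(res^2) / dfres
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  ybar <- mean(y)
  r2 <- 1 - sum(res^2) / sum((y - ybar)^2)
  list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
       residuals = as.numeric(res), fitted = as.numeric(X %*% beta),
       r_squared = r2, sigma2 = sigma2, se = se,
       t = as.numeric(beta) / se, n = n, df_residual = dfres,
       qr = qrX, X = X, y = y, complete = ok)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` from regressing predictor k on the other
#' predictors (intercept included). Perfectly collinear predictors are
#' reported as `Inf` with a flag rather than an error, so a screening loop
#' can report them.
#'
#' @param design numeric matrix of predictors (no intercept column; one is
#'   added internally).
#' @return named numeric vector of VIFs with attribute `collinear`
#'   (logical vector).
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  p <- ncol(X)
  if (p < 2) stop("need at least two predictors")
  out <- stats::setNames(numeric(p), colnames(X))
  coll <- logical(p)
  for (k in seq_len(p)) {
    Xo <- cbind(1, X[, -k, drop = FALSE])
    fit <- lm.fit(Xo, X[, k])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, k] - mean(X[, k]))^2)
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-12) { out[k] <- Inf; coll[k] <- TRUE }
    else out[k] <- 1 / (1 - r2)
  }
  attr(out, "collinear") <- coll
  out
}

#' Freedman-Lane permutation p-values for regression terms
#'
#' For each tested coefficient, residuals of the reduced model (the design
#' without that term) are permuted, added back to the reduced-model fit,
#' and the full model is refit to each permuted response; the two-sided
#' p-value is `(1 + #{|t*| >= |t|}) / (1 + B)`. This scheme keeps the
#' nuisance covariates' contribution intact under permutation, giving
#' close-to-exact control when residuals are exchangeable.
#'
#' @param design numeric matrix including an intercept column named
#'   `(intercept)` (or first column).
#' @param outcome numeric response.
#' @param terms character or integer indices of columns to test; default
#'   all non-intercept columns.
#' @param n_permutations number of permutations B (default 10000; a
#'   warning flag is set below 100).
#' @param seed integer seed for the permutation draws.
#' @return list with `p` (named per-term), `t_obs`, `fit` (the [fit_ols()]
#'   result), `n_permutations`, `low_b_warning`.
#' @export
permutation_pvalues <- function(design, outcome, terms = NULL,
                                n_permutations = 10000, seed = 1L) {
  fit <- fit_ols(design, outcome)
  X <- fit$X; y <- fit$y
  n <- nrow(X)
  cn <- colnames(X)
  if (is.null(terms)) terms <- setdiff(seq_along(cn), 1L)
  if (is.character(terms)) terms <- match(terms, cn)
  B <- as.integer(n_permutations)
  low_b <- B < 100
  if (low_b) warning("fewer than 100 permutations: p-values are coarse")
  XtXinv_diag <- diag(chol2inv(qr.R(fit$qr)))
  pvals <- stats::setNames(rep(NA_real_, length(terms)), cn[terms])
  with_seed(seed, {
    perms <- replicate(B, sample.int(n))
    for (ti in seq_along(terms)) {
      k <- terms[ti]
      t_obs <- fit$t[k]
      Xred <- X[, -k, drop = FALSE]
      fr <- lm.fit(Xred, y)
      e <- fr$residuals
      mu <- fr$fitted.values
      Ystar <- mu + matrix(e[perms], n, B)
      cf <- qr.coef(fit$qr, Ystar)           # p x B
      resid2 <- colSums(qr.resid(fit$qr, Ystar)^2)
      s2 <- resid2 / fit$df_residual
      tstar <- cf[k, ] / sqrt(s2 * XtXinv_diag[k])
      pvals[ti] <- (1 + sum(abs(tstar) >= abs(t_obs) - 1e-12)) / (1 + B)
    }
  })
  list(p = pvals, t_obs = fit$t[terms], fit = fit,
       n_permutations = B, low_b_warning = low_b)
}

#' Grouped Benjamini-Hochberg FDR correction
#'
#' Applies the BH step-up procedure independently within each group of
#' p-values (models sharing the same outcome variable form one group).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param group_labels vector of group identifiers, same length.
#' @param q nominal FDR level for the significance flags.
#' @return list with `q` (corrected values) and `significant` (logical).
#' @export
fdr_grouped <- function(pvals, group_labels, q = 0.05) {
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1]")
  stopifnot(length(pvals) == length(group_labels))
  adj <- rep(NA_real_, length(pvals))
  for (g in unique(group_labels)) {
    sel <- which(group_labels == g & !is.na(pvals))
    if (length(sel)) adj[sel] <- p.adjust(pvals[sel], method = "BH")
  }
  list(q = adj, significant = !is.na(adj) & adj < q)
}
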