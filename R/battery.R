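# shared worker for one model of the battery ("model 3": susceptibility and
# volume of one region enter together, plus covariates)
fit_battery_model <- function(table, region, outcome, family,
                              n_permutations, seed) {
  qcol <- paste0("qsm_", region); vcol <- paste0("vol_", region)
  ycol <- if (family == "longitudinal") paste0("fu_", outcome) else outcome
  need <- c(qcol, vcol, "age", "sex", "disease_duration", ycol)
  if (family == "longitudinal")
    need <- c(need, outcome, "followup_interval")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))

  df <- as.data.frame(table)[need]
  ok <- stats::complete.cases(df)
  df <- df[ok, , drop = FALSE]

  zcols <- c(qcol, vcol, "age", "disease_duration", ycol)
  if (family == "longitudinal") zcols <- c(zcols, outcome, "followup_interval")
  flags <- character(0)
  kept <- character(0)
  for (cl in zcols) {
    s <- sd(df[[cl]])
    if (!is.finite(s) || s == 0) {
      flags <- c(flags, sprintf("zero_variance:%s", cl))
      df[[cl]] <- df[[cl]] - mean(df[[cl]])   # centered, stays constant 0
    } else {
      df <- standardize(df, cl)
      kept <- c(kept, cl)
    }
  }

  terms <- c(qsm = qcol, volume = vcol, age = "age", sex = "sex",
             disease_duration = "disease_duration")
  if (family == "longitudinal")
    terms <- c(terms, baseline_outcome = outcome,
               followup_interval = "followup_interval")
  usable <- vapply(terms, function(cl)
    cl %in% kept || cl == "sex", TRUE)
  X <- cbind("(intercept)" = 1,
             as.matrix(df[unname(terms[usable])]))
  y <- df[[ycol]]

  pp <- permutation_pvalues(X, y, n_permutations = n_permutations,
                            seed = seed)
  beta <- pp$fit$coefficients
  allterms <- names(terms)
  cols <- unname(terms[allterms])
  out <- data.frame(
    family = family, region = region, outcome = outcome,
    term = allterms,
    beta = ifelse(usable[allterms], beta[match(cols, names(beta))], NA_real_),
    p = ifelse(usable[allterms], pp$p[match(cols, names(pp$p))], NA_real_),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(rows = out, r_squared = pp$fit$r_squared, n = pp$fit$n,
       flags = flags, vif = tryCatch(vif(X[, -1, drop = FALSE]),
                                     error = function(e) NULL))
}

run_battery <- function(table, family, regions, outcomes,
                        n_permutations, seed, q = 0.05) {
  rows <- list(); info <- list()
  i <- 0L
  for (o in outcomes) for (r in regions) {
    i <- i + 1L
    res <- fit_battery_model(table, r, o, family, n_permutations,
                             seed = seed + i)
    rows[[i]] <- res$rows
    info[[i]] <- data.frame(family = family, region = r, outcome = o,
                            r_squared = res$r_squared, n = res$n,
                            flags = paste(res$flags, collapse = ";"),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  # grouped FDR: one group per outcome, over the susceptibility and volume
  # terms of the regional models sharing that outcome
  exposure <- tab$term %in% c("qsm", "volume")
  tab$q <- NA_real_
  fg <- fdr_grouped(tab$p[exposure], tab$outcome[exposure], q = q)
  tab$q[exposure] <- fg$q
  tab$significant <- !is.na(tab$q) & tab$q < q
  structure(list(results = tab, models = do.call(rbind, info),
                 family = family, n_models = i,
                 n_permutations = n_permutations, q = q, seed = seed),
            class = "qsm_battery")
}

#' Cross-sectional regression battery
#'
#' Fits, for every deep grey matter region and every baseline outcome, the
#' multiple regression
#' `outcome ~ QSM + volume + age + sex + disease duration`
#' on z-scored continuous variables (sex kept 0/1), with Freedman-Lane
#' permutation p-values per term and Benjamini-Hochberg FDR applied within
#' each group of models sharing an outcome (over the susceptibility and
#' volume terms). With the default 4 regions and 7 outcomes (five clinical
#' scores plus normalized brain volume and log lesion volume) this yields
#' 28 models.
#'
#' @param table a [generate_cohort()] table (or compatible data frame).
#' @param regions character vector of regions.
#' @param outcomes character vector of outcome columns.
#' @param n_permutations permutations per term (study default 10000;
#'   smaller values give coarser p-values).
#' @param seed integer seed; model `i` uses `seed + i`.
#' @param q FDR level.
#' @return object of class `qsm_battery`; `$results` has one row per
#'   (region, outcome, term) with `beta` (standardized), `p` (permutation),
#'   `q` (grouped FDR, exposure terms), `significant`; `$models` has per-
#'   model R^2, n and diagnostic flags.
#' @export
run_cross_sectional_battery <- function(table, regions = DGM_REGIONS,
                                        outcomes = CS_OUTCOMES,
                                        n_permutations = 10000,
                                        seed = 1L, q = 0.05) {
  run_battery(table, "cross_sectional", regions, outcomes,
              n_permutations, seed, q)
}

#' Longitudinal regression battery
#'
#' Fits, for every region and clinical outcome, the follow-up model
#' `follow-up outcome ~ baseline QSM + baseline volume + age + sex +
#' disease duration + baseline outcome + follow-up interval`, restricted to
#' subjects with that follow-up score (complete cases per model, n
#' reported). With 4 regions and 5 clinical outcomes this yields 20
#' models.
#'
#' @inheritParams run_cross_sectional_battery
#' @return a `qsm_battery` object (see
#'   [run_cross_sectional_battery()]).
#' @export
run_longitudinal_battery <- function(table, regions = DGM_REGIONS,
                                     outcomes = CLINICAL_OUTCOMES,
                                     n_permutations = 10000,
                                     seed = 1L, q = 0.05) {
  run_battery(table, "longitudinal", regions, outcomes,
              n_permutations, seed, q)
}

#' @export
print.qsm_battery <- function(x, ...) {
  cat(sprintf("qsm_battery (%s): %d models, %d permutations per term\n",
              x$family, x$n_models, x$n_permutations))
  sig <- x$results[x$results$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("significant exposure terms (grouped FDR q <", x$q, "):\n")
    print(sig[c("region", "outcome", "term", "beta", "p", "q")],
          row.names = FALSE, digits = 3)
  } else cat("no significant exposure terms\n")
  invisible(x)
}

#' @export
summary.qsm_battery <- function(object, ...) {
  cat(sprintf("%s battery: %d models (n per model %d-%d), median R^2 %.3f\n",
              object$family, object$n_models, min(object$models$n),
              max(object$models$n), median(object$models$r_squared)))
  invisible(object)
}

#' @export
coef.qsm_battery <- function(object, ...) {
  object$results[c("region", "outcome", "term", "beta")]
}

#' @export
as.data.frame.qsm_battery <- function(x, ...) x$results

#' Heatmap of standardized battery coefficients
#'
#' Standardized beta of the susceptibility and volume terms per (region,
#' outcome) cell; non-significant cells (grouped FDR) are blanked, the
#' display convention of the association figures this battery emulates.
#'
#' @param x a `qsm_battery`.
#' @param only_significant blank cells that do not pass grouped FDR.
#' @param ... ignored.
#' @export
plot.qsm_battery <- function(x, only_significant = TRUE, ...) {
  tab <- x$results[x$results$term %in% c("qsm", "volume"), ]
  tab$rowlab <- paste(tab$region, tab$term)
  rl <- unique(tab$rowlab); ol <- unique(tab$outcome)
  M <- matrix(NA_real_, length(rl), length(ol), dimnames = list(rl, ol))
  for (i in seq_len(nrow(tab))) {
    v <- tab$beta[i]
    if (only_significant && !tab$significant[i]) v <- NA
    M[tab$rowlab[i], tab$outcome[i]] <- v
  }
  lim <- max(abs(M), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  old <- par(mar = c(5, 8, 3, 1)); on.exit(par(old))
  image(seq_along(ol), seq_along(rl), t(M)[, rev(seq_along(rl)), drop = FALSE],
        col = hcl.colors(51, "Blue-Red 3"), zlim = c(-lim, lim),
        axes = FALSE, xlab = "", ylab = "",
        main = paste(x$family, "standardized β"))
  axis(1, seq_along(ol), ol, las = 2)
  axis(2, seq_along(rl), rev(rl), las = 1)
  for (i in seq_along(rl)) for (j in seq_along(ol)) {
    v <- M[i, j]
    if (!is.na(v)) text(j, length(rl) + 1 - i, sprintf("%.2f", v), cex = 0.7)
  }
  invisible(M)
}

#' Heatmap of a Spearman correlation matrix
#'
#' @param x a [spearman_matrix()].
#' @param only_significant blank cells with corrected p >= 0.05.
#' @param ... ignored.
#' @export
plot.spearman_matrix <- function(x, only_significant = TRUE, ...) {
  M <- x$r
  if (only_significant) M[!is.na(x$p_corrected) & x$p_corrected >= 0.05] <- NA
  k <- ncol(M)
  old <- par(mar = c(7, 7, 2, 1)); on.exit(par(old))
  image(1:k, 1:k, t(M)[, rev(1:k), drop = FALSE],
        col = hcl.colors(51, "Blue-Red 3"), zlim = c(-1, 1),
        axes = FALSE, xlab = "", ylab = "", main = "Spearman r (FDR-masked)")
  axis(1, 1:k, colnames(M), las = 2, cex.axis = 0.7)
  axis(2, 1:k, rev(rownames(M)), las = 1, cex.axis = 0.7)
  invisible(M)
}
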