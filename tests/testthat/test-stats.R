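test_that("spearman matrix equals the brute-force rank oracle", {
  set.seed(8)
  for (rep in 1:5) {
    X <- as.data.frame(matrix(rnorm(20 * 6), 20, 6))
    names(X) <- paste0("v", 1:6)
    X$v3 <- round(X$v3 * 2) / 2          # force ties
    sm <- spearman_matrix(X, names(X))
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(sm$r[i, j], oracle_spearman(X[[i]], X[[j]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("spearman correlation is monotone-invariant and sign-correct", {
  x <- c(0.3, 1.2, 2.1, 3.9, 5.5, 7.1)
  df <- data.frame(x = x, ye = exp(x), yn = -x)
  sm <- spearman_matrix(df, c("x", "ye", "yn"))
  expect_equal(sm$r["x", "ye"], 1)
  expect_equal(sm$r["x", "yn"], -1)
  df2 <- data.frame(x = 1:5, y = c(2, 1, 4, 3, 5))
  expect_equal(spearman_matrix(df2, c("x", "y"))$r[1, 2], 0.8)
  expect_equal(oracle_spearman(df2$x, df2$y), 0.8)
  # constant variable: undefined, reported missing
  df3 <- data.frame(x = 1:6, k = rep(2, 6))
  expect_true(is.na(spearman_matrix(df3, c("x", "k"))$r[1, 2]))
})

test_that("standardization z-scores columns and refuses constants", {
  df <- data.frame(a = c(1, 2, 3, 4), b = rep(1, 4))
  out <- standardize(df, "a")
  expect_equal(mean(out$a), 0, tolerance = 1e-12)
  expect_equal(sd(out$a), 1, tolerance = 1e-12)
  expect_equal(standardize(out, "a")$a, out$a, tolerance = 1e-12)
  expect_error(standardize(df, "b"), "zero variance")
})

test_that("least squares matches the normal-equations oracle", {
  set.seed(3)
  n <- 40
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(intercept)", "x1", "x2")
  y <- 0.5 + 1.5 * X[, 2] - 0.7 * X[, 3] + rnorm(n, 0, 0.3)
  fit <- fit_ols(X, y)
  beta_or <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients), c(beta_or), tolerance = 1e-10)
  # intercept-only model returns the mean
  X0 <- matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))
  expect_equal(unname(fit_ols(X0, y)$coefficients), mean(y))
  # single standardized predictor: beta equals the Pearson correlation
  xs <- (X[, 2] - mean(X[, 2])) / sd(X[, 2])
  ys <- (y - mean(y)) / sd(y)
  f1 <- fit_ols(cbind("(intercept)" = 1, x = xs), ys)
  expect_equal(unname(f1$coefficients[2]), cor(X[, 2], y), tolerance = 1e-10)
  # rank deficiency errors with the column named
  Xd <- cbind(X, x2b = X[, 3])
  expect_error(fit_ols(Xd, y), "x2b")
})

test_that("variance inflation factors follow the closed form", {
  set.seed(5)
  n <- 5000
  # two predictors with correlation 0.6: VIF = 1/(1-0.36) = 1.5625
  z <- matrix(rnorm(n * 2), n, 2) %*% chol(matrix(c(1, 0.6, 0.6, 1), 2))
  colnames(z) <- c("a", "b")
  v <- vif(z)
  r <- cor(z[, 1], z[, 2])
  expect_equal(unname(v["a"]), 1 / (1 - r^2), tolerance = 1e-9)
  expect_equal(unname(v["a"]), 1.5625, tolerance = 0.05)
  # exactly orthogonal (and mean-zero) predictors: VIF 1
  q <- unclass(stats::poly(1:50, 3))
  colnames(q) <- c("q1", "q2", "q3")
  expect_equal(unname(vif(q)), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # duplicated column: flagged infinite
  dup <- cbind(a = z[, 1], b = z[, 1])
  vd <- vif(dup)
  expect_true(all(is.infinite(vd)))
  expect_true(all(attr(vd, "collinear")))
})

test_that("grouped BH correction matches the hand recipe", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  g <- rep("o1", 4)
  out <- fdr_grouped(p, g)
  expect_equal(out$q, rep(0.04, 4))
  expect_equal(out$q, oracle_bh(p))
  # single p per group unchanged; equal p unchanged
  expect_equal(fdr_grouped(c(0.03, 0.2), c("a", "b"))$q, c(0.03, 0.2))
  expect_equal(fdr_grouped(rep(0.07, 5), rep("a", 5))$q, rep(0.07, 5))
  # grouping matters: within-group correction ignores other groups
  p2 <- c(0.01, 0.04, 0.001, 0.5)
  g2 <- c("a", "a", "b", "b")
  out2 <- fdr_grouped(p2, g2)
  expect_equal(out2$q[1:2], oracle_bh(p2[1:2]))
  expect_equal(out2$q[3:4], oracle_bh(p2[3:4]))
  expect_error(fdr_grouped(c(0.5, 1.2), c("a", "a")), "\\[0, 1\\]")
  # q >= p always (step-up property)
  set.seed(13)
  pr <- runif(30)
  gr <- sample(letters[1:3], 30, replace = TRUE)
  o3 <- fdr_grouped(pr, gr)
  expect_true(all(o3$q >= pr - 1e-12))
})

test_that("permutation p-values are seeded, bounded below and catch strong effects", {
  set.seed(7)
  n <- 400
  X <- cbind("(intercept)" = 1, x = rnorm(n), z = rnorm(n))
  y <- 0.5 * X[, "x"] + rnorm(n)
  r1 <- permutation_pvalues(X, y, terms = "x", n_permutations = 500, seed = 3)
  r2 <- permutation_pvalues(X, y, terms = "x", n_permutations = 500, seed = 3)
  expect_identical(r1$p, r2$p)
  expect_equal(unname(r1$p["x"]), 1 / 501)   # minimum attainable
  expect_warning(permutation_pvalues(X, y, terms = "x", n_permutations = 50,
                                     seed = 1),
                 "coarse")
})

test_that("permutation p-values are uniform on the attainable grid under the null", {
  set.seed(19)
  n <- 60
  B <- 199
  reps <- 300
  ps <- vapply(seq_len(reps), function(i) {
    X <- cbind("(intercept)" = 1, x = rnorm(n), z = rnorm(n))
    y <- 0.4 * X[, "z"] + rnorm(n)   # x is null, z is a real nuisance
    permutation_pvalues(X, y, terms = "x", n_permutations = B,
                        seed = 1000 + i)$p["x"]
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(min(ps), 0)
  expect_lte(max(ps), 1)
})
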