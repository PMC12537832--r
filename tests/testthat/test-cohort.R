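test_that("cohort table has the requested size, schema and invariants", {
  tab <- generate_cohort(cohort_spec(n_subjects = 771, seed = 2))
  expect_equal(nrow(tab), 771)
  expect_false(anyDuplicated(tab$subject_id) > 0)
  expect_true(all(tab$sex %in% c(0L, 1L)))
  expect_true(all(tab$tlv >= 0))
  expect_true(all(tab$disease_duration > 0))
  has_fu <- !is.na(tab$followup_interval)
  expect_true(all(tab$followup_interval[has_fu] >= 1))
  expect_true(all(tab$followup_interval[has_fu] <= 4.7))
  # follow-up availability differs by outcome, SDMT being the scarcest
  n_fu <- colSums(!is.na(tab[paste0("fu_", c("edss", "t25fw", "sdmt"))]))
  expect_lt(n_fu[3], n_fu[1])
  expect_equal(unname(n_fu[1] / 771), 396 / 771, tolerance = 0.1)
  expect_equal(tab$log_tlv, log(tab$tlv + 0.01))
})

test_that("same seed reproduces the cohort bit-identically", {
  a <- generate_cohort(cohort_spec(n_subjects = 100, seed = 9))
  b <- generate_cohort(cohort_spec(n_subjects = 100, seed = 9))
  d <- generate_cohort(cohort_spec(n_subjects = 100, seed = 10))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(d)))
})

test_that("null effects leave susceptibility and outcomes uncorrelated", {
  spec <- cohort_spec(n_subjects = 2000, effect_map = null_effects(),
                      longitudinal_effects = null_long_effects(), seed = 5)
  tab <- generate_cohort(spec)
  r <- cor(tab$qsm_caudate, tab$edss, method = "spearman")
  expect_lt(abs(r), 0.05)
})

test_that("the latent correlation structure is realized in large samples", {
  spec <- cohort_spec(n_subjects = 20000, seed = 11)
  tab <- generate_cohort(spec)
  R <- spec$latent_correlation
  # untransformed Gaussian columns: age, susceptibilities, volumes, tiv
  cols <- c("age", paste0("qsm_", c("thalamus", "caudate", "putamen",
                                    "pallidum")),
            paste0("vol_", c("thalamus", "caudate", "putamen", "pallidum")),
            "tiv")
  emp <- cor(as.data.frame(tab)[cols])
  expect_lt(max(abs(emp - R[cols, cols])), 0.03)
})

test_that("injected standardized effects are recovered by refitting", {
  # caudate susceptibility effect on disability, beta = 0.19, as the only
  # injected effect; the model-3 regression on z-scored variables should
  # average back to it over seeds
  em <- single_qsm_effect("caudate", "edss", 0.19)
  est <- vapply(1:25, function(s) {
    tab <- generate_cohort(cohort_spec(n_subjects = 771, effect_map = em,
                                       seed = 100 + s))
    df <- standardize(as.data.frame(tab),
                      c("qsm_caudate", "vol_caudate", "age",
                        "disease_duration", "edss"))
    X <- cbind(1, as.matrix(df[c("qsm_caudate", "vol_caudate", "age", "sex",
                                 "disease_duration")]))
    fit_ols(X, df$edss)$coefficients[2]
  }, 0)
  expect_lt(abs(mean(est) - 0.19), 0.03)
})

test_that("overloaded effects that exhaust the outcome variance are refused", {
  em <- default_effect_map()
  em$edss$qsm[] <- c(0.6, 0.6, 0.6, 0.6)
  expect_error(generate_cohort(cohort_spec(n_subjects = 100, effect_map = em,
                                           seed = 1)),
               "residual variance")
  expect_error(cohort_spec(n_subjects = 5), "n_subjects")
  expect_error(cohort_spec(autocorrelation = 1.5), "autocorrelation")
  em2 <- default_effect_map()
  em2$edss$qsm["caudate"] <- 1.2
  expect_error(cohort_spec(effect_map = em2), "beta")
})

test_that("full autocorrelation makes baseline dominate follow-up", {
  spec <- cohort_spec(n_subjects = 1500, effect_map = null_effects(),
                      longitudinal_effects = null_long_effects(),
                      autocorrelation = 1, seed = 21,
                      followup_fraction = c(edss = 1, t25fw = 1, nhpt = 1,
                                            sdmt = 1, fsmc = 1))
  tab <- generate_cohort(spec)
  expect_gt(cor(tab$edss, tab$fu_edss), 0.95)
})
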