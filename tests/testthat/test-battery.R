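cohort_for_battery <- generate_cohort(cohort_spec(n_subjects = 300, seed = 31))

test_that("battery sizes are pure functions of the region-outcome grid", {
  b <- run_cross_sectional_battery(cohort_for_battery, n_permutations = 100,
                                   seed = 1)
  expect_equal(b$n_models, 28L)
  expect_equal(nrow(b$models), 28L)
  expect_equal(nrow(b$results), 28L * 5L)
  b6 <- run_cross_sectional_battery(
    cohort_for_battery, outcomes = setdiff(c("edss", "t25fw", "nhpt", "sdmt",
                                             "fsmc", "nbv", "log_tlv"), "fsmc"),
    n_permutations = 100, seed = 1)
  expect_equal(b6$n_models, 24L)
  bl <- run_longitudinal_battery(cohort_for_battery, n_permutations = 100,
                                 seed = 1)
  expect_equal(bl$n_models, 20L)
  expect_equal(nrow(bl$results), 20L * 7L)
})

test_that("battery results are reproducible under a fixed seed", {
  b1 <- run_cross_sectional_battery(cohort_for_battery, outcomes = "edss",
                                    n_permutations = 200, seed = 7)
  b2 <- run_cross_sectional_battery(cohort_for_battery, outcomes = "edss",
                                    n_permutations = 200, seed = 7)
  expect_identical(b1$results, b2$results)
})

test_that("grouped FDR in the battery acts within outcome groups on exposures", {
  b <- run_cross_sectional_battery(cohort_for_battery, n_permutations = 200,
                                   seed = 2)
  tab <- b$results
  expo <- tab[tab$term %in% c("qsm", "volume"), ]
  for (o in unique(expo$outcome)) {
    grp <- expo[expo$outcome == o, ]
    expect_equal(grp$q, oracle_bh(grp$p), tolerance = 1e-12)
  }
  # nuisance terms carry no q
  expect_true(all(is.na(tab$q[!tab$term %in% c("qsm", "volume")])))
  expect_true(all(tab$q >= tab$p - 1e-12, na.rm = TRUE))
})

test_that("longitudinal models keep complete cases and report n per model", {
  bl <- run_longitudinal_battery(cohort_for_battery, n_permutations = 100,
                                 seed = 3)
  tab <- cohort_for_battery
  for (o in c("edss", "sdmt")) {
    n_expected <- sum(stats::complete.cases(
      data.frame(tab[[paste0("fu_", o)]], tab[[o]], tab$followup_interval)))
    expect_equal(unique(bl$models$n[bl$models$outcome == o]), n_expected)
  }
  expect_true(all(bl$models$n < nrow(tab)))
})

test_that("a constant follow-up interval is flagged, not fatal", {
  tab <- cohort_for_battery
  tab$followup_interval[!is.na(tab$followup_interval)] <- 2.5
  bl <- run_longitudinal_battery(tab, outcomes = "edss",
                                 n_permutations = 100, seed = 4)
  expect_equal(bl$n_models, 4L)
  expect_true(all(grepl("zero_variance:followup_interval", bl$models$flags)))
  fi <- bl$results[bl$results$term == "followup_interval", ]
  expect_true(all(is.na(fi$beta)))
  expect_error(run_cross_sectional_battery(tab[, setdiff(names(tab), "nbv")],
                                           n_permutations = 120, seed = 1),
               "nbv")
})

test_that("dominant baseline autocorrelation leaves susceptibility null-calibrated", {
  spec <- cohort_spec(n_subjects = 600, effect_map = null_effects(),
                      longitudinal_effects = null_long_effects(),
                      autocorrelation = 1, seed = 17,
                      followup_fraction = c(edss = 1, t25fw = 1, nhpt = 1,
                                            sdmt = 1, fsmc = 1))
  tab <- generate_cohort(spec)
  bl <- run_longitudinal_battery(tab, outcomes = "edss",
                                 n_permutations = 300, seed = 5)
  res <- bl$results
  base <- res[res$term == "baseline_outcome", ]
  qsm <- res[res$term == "qsm", ]
  expect_true(all(abs(base$beta) > 0.9))
  expect_true(all(base$p <= 1 / 301 + 1e-12))
  expect_true(all(abs(qsm$beta) < 0.05))
})
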