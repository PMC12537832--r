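DGM_REGIONS <- c("thalamus", "caudate", "putamen", "pallidum")
CLINICAL_OUTCOMES <- c("edss", "t25fw", "nhpt", "sdmt", "fsmc")
CS_OUTCOMES <- c(CLINICAL_OUTCOMES, "nbv", "log_tlv")

#' Default latent correlation structure of the simulated cohort
#'
#' Correlations among the Gaussian latents behind age, sex, disease
#' duration, the four regional susceptibilities, the four normalized
#' regional volumes and TIV. Values emulate the qualitative structure seen
#' in MS cohorts: basal-ganglia susceptibility rises strongly with age,
#' regional volumes shrink with age and inter-correlate, susceptibility and
#' volume of a region are mildly negatively related, TIV tracks sex. The
#' matrix is symmetrized and eigenvalue-clipped to the nearest positive
#' definite correlation matrix, which is returned (and is what the
#' generator actually uses).
#'
#' @return a 12 x 12 positive-definite correlation matrix with dimnames.
#' @export
default_latent_correlation <- function() {
  vars <- c("age", "sexl", "disease_duration",
            paste0("qsm_", DGM_REGIONS), paste0("vol_", DGM_REGIONS), "tiv")
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set2 <- function(R, a, b, v) { R[a, b] <- v; R[b, a] <- v; R }
  # age with regional susceptibility (strong in basal ganglia)
  R <- set2(R, "age", "qsm_thalamus", 0.10)
  R <- set2(R, "age", "qsm_caudate", 0.50)
  R <- set2(R, "age", "qsm_putamen", 0.63)
  R <- set2(R, "age", "qsm_pallidum", 0.53)
  for (r in DGM_REGIONS) R <- set2(R, "age", paste0("vol_", r), -0.30)
  R <- set2(R, "age", "disease_duration", 0.25)
  # susceptibility inter-correlations
  bg <- c("caudate", "putamen", "pallidum")
  for (i in 1:2) for (j in (i + 1):3)
    R <- set2(R, paste0("qsm_", bg[i]), paste0("qsm_", bg[j]), 0.50)
  for (r in bg) R <- set2(R, "qsm_thalamus", paste0("qsm_", r), 0.15)
  # volume inter-correlations
  for (i in 1:3) for (j in (i + 1):4)
    R <- set2(R, paste0("vol_", DGM_REGIONS[i]),
              paste0("vol_", DGM_REGIONS[j]), 0.45)
  # same-region susceptibility/volume coupling; weak cross-region coupling
  for (r in DGM_REGIONS) R <- set2(R, paste0("qsm_", r), paste0("vol_", r), -0.20)
  for (r in DGM_REGIONS) for (s in setdiff(DGM_REGIONS, r))
    R <- set2(R, paste0("qsm_", r), paste0("vol_", s), -0.10)
  # disease duration
  for (r in bg) R <- set2(R, "disease_duration", paste0("qsm_", r), 0.15)
  for (r in DGM_REGIONS) R <- set2(R, "disease_duration", paste0("vol_", r), -0.15)
  # head size and sex
  for (r in DGM_REGIONS) R <- set2(R, "tiv", paste0("vol_", r), 0.40)
  R <- set2(R, "sexl", "tiv", 0.45)
  for (r in DGM_REGIONS) R <- set2(R, "sexl", paste0("vol_", r), 0.20)
  # nearest PD correlation matrix (eigenvalue clip + rescale)
  e <- eigen(R, symmetric = TRUE)
  v <- pmax(e$values, 1e-3)
  R2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / outer(d, d)
  dimnames(R2) <- dimnames(R)
  (R2 + t(R2)) / 2
}

#' Default standardized effects of the simulated cohort
#'
#' Standardized regression effects injected when generating baseline
#' outcomes: per outcome, per-region susceptibility and volume effects plus
#' age, sex and disease-duration effects. The susceptibility entries follow
#' the significant cross-sectional associations reported for a large MS
#' cohort (e.g. caudate-EDSS 0.19); volume and covariate effects are
#' moderate values in the reported ranges.
#'
#' @return nested list: `effects[[outcome]]` has numeric vectors `qsm`,
#'   `volume` (named by region) and scalars `age`, `sex`, `dd`.
#' @export
default_effect_map <- function() {
  eff <- function(qsm = NULL, volume = NULL, age = 0, sex = 0, dd = 0) {
    q <- stats::setNames(numeric(4), DGM_REGIONS)
    v <- stats::setNames(numeric(4), DGM_REGIONS)
    q[names(qsm)] <- qsm; v[names(volume)] <- volume
    list(qsm = q, volume = v, age = age, sex = sex, dd = dd)
  }
  list(
    edss = eff(qsm = c(caudate = 0.19, putamen = 0.15, pallidum = 0.13),
               volume = c(thalamus = -0.20, caudate = -0.10),
               age = 0.10, dd = 0.15),
    t25fw = eff(volume = c(thalamus = -0.15), age = 0.10),
    nhpt = eff(qsm = c(caudate = 0.14, putamen = 0.16, pallidum = 0.13),
               volume = c(caudate = -0.14), age = 0.10),
    sdmt = eff(qsm = c(caudate = -0.14, putamen = -0.15, pallidum = -0.13),
               volume = c(thalamus = 0.25), age = -0.20),
    fsmc = eff(qsm = c(thalamus = -0.11), dd = 0.10),
    nbv = eff(volume = c(thalamus = 0.35, caudate = 0.15, putamen = 0.15,
                         pallidum = 0.10),
              age = -0.30, dd = -0.10),
    log_tlv = eff(qsm = c(thalamus = -0.07, caudate = 0.17,
                          putamen = 0.14, pallidum = 0.14),
                  volume = c(thalamus = -0.30), age = 0.10, dd = 0.20)
  )
}

#' Default longitudinal effects (baseline predictors of follow-up outcomes)
#'
#' Susceptibility carries no prognostic effect by default; thalamic and
#' caudate volumes predict disability and dexterity, mirroring the signals
#' reported for early MS.
#'
#' @return nested list shaped like [default_effect_map()], for the five
#'   clinical outcomes.
#' @export
default_longitudinal_effects <- function() {
  eff <- function(qsm = NULL, volume = NULL, age = 0, sex = 0, dd = 0) {
    q <- stats::setNames(numeric(4), DGM_REGIONS)
    v <- stats::setNames(numeric(4), DGM_REGIONS)
    q[names(qsm)] <- qsm; v[names(volume)] <- volume
    list(qsm = q, volume = v, age = age, sex = sex, dd = dd)
  }
  list(
    edss = eff(volume = c(thalamus = -0.11, caudate = -0.10)),
    t25fw = eff(),
    nhpt = eff(volume = c(caudate = -0.14)),
    sdmt = eff(),
    fsmc = eff()
  )
}

#' Specify a synthetic cohort
#'
#' @param n_subjects number of subjects (>= 10).
#' @param effect_map baseline standardized effects, see
#'   [default_effect_map()]; `NULL` keeps the defaults. Every |effect| must
#'   be < 1.
#' @param longitudinal_effects baseline-predictor effects on follow-up
#'   outcomes, see [default_longitudinal_effects()].
#' @param covariate_params list of marginal distribution parameters:
#'   `age = c(mean, sd)` years, `sex_male_frac`, `disease_duration =
#'   c(mean, sd)` years, `tiv = c(mean, sd)` mL, `qsm` and `volume` (named
#'   region -> c(mean, sd), ppm and mL), `outcome_scale` (named outcome ->
#'   c(mean, sd)).
#' @param latent_correlation correlation matrix of the Gaussian latents
#'   (see [default_latent_correlation()]).
#' @param followup_interval length-2 range in years (first element >= 1).
#' @param autocorrelation baseline-to-follow-up outcome dependence, in
#'   \[0, 1\].
#' @param noise_sd residual scale multiplier; 1 gives outcomes of unit
#'   latent variance.
#' @param followup_fraction named fractions of subjects with a follow-up
#'   score per clinical outcome; defaults emulate the differential
#'   availability of clinical scores (EDSS 0.51 ... SDMT 0.21).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 771,
                        effect_map = NULL,
                        longitudinal_effects = NULL,
                        covariate_params = NULL,
                        latent_correlation = NULL,
                        followup_interval = c(1, 4.7),
                        autocorrelation = 0.6,
                        noise_sd = 1,
                        followup_fraction = NULL,
                        seed = 1L) {
  if (n_subjects < 10) stop("n_subjects must be >= 10")
  if (autocorrelation < 0 || autocorrelation > 1)
    stop("autocorrelation must be in [0, 1]")
  if (followup_interval[1] < 1)
    stop("followup interval must start at >= 1 year")
  em <- if (is.null(effect_map)) default_effect_map() else effect_map
  le <- if (is.null(longitudinal_effects)) default_longitudinal_effects()
        else longitudinal_effects
  allb <- unlist(lapply(c(em, le), function(e)
    c(e$qsm, e$volume, e$age, e$sex, e$dd)))
  if (any(abs(allb) >= 1)) stop("every standardized effect must satisfy |beta| < 1")
  cp <- list(
    age = c(40.0, 11.0), sex_male_frac = 0.357,
    disease_duration = c(7.4, 6.3), tiv = c(1540, 140),
    qsm = list(thalamus = c(-0.008, 0.010), caudate = c(0.042, 0.018),
               putamen = c(0.050, 0.028), pallidum = c(0.099, 0.028)),
    volume = list(thalamus = c(13.0, 1.3), caudate = c(6.6, 0.8),
                  putamen = c(8.6, 0.9), pallidum = c(2.9, 0.5)),
    outcome_scale = list(edss = c(1.6, 1.2), t25fw = c(4.3, 1.0),
                         nhpt = c(18.5, 3.0), sdmt = c(60, 12),
                         fsmc = c(42, 18), nbv = c(1418.2, 56.8),
                         log_tlv = c(1.0, 1.2))
  )
  if (!is.null(covariate_params)) cp <- modifyList(cp, covariate_params)
  ff <- c(edss = 396, t25fw = 284, nhpt = 284, sdmt = 165, fsmc = 288) / 771
  if (!is.null(followup_fraction)) ff[names(followup_fraction)] <- followup_fraction
  R <- if (is.null(latent_correlation)) default_latent_correlation()
       else latent_correlation
  structure(list(n_subjects = as.integer(n_subjects), effect_map = em,
                 longitudinal_effects = le, covariate_params = cp,
                 latent_correlation = R,
                 followup_interval = followup_interval,
                 autocorrelation = autocorrelation, noise_sd = noise_sd,
                 followup_fraction = ff, seed = as.integer(seed)),
            class = "cohort_spec")
}

# population variance of  signal = bz' Z + b_sex * sex01  where Z are the
# standard-normal latents with correlation R and sex01 = 1{Z_sexl > c}
signal_variance <- function(bz, b_sex, R, c_sex) {
  p <- 1 - stats::pnorm(c_sex)
  v <- as.numeric(t(bz) %*% R %*% bz) + b_sex^2 * p * (1 - p)
  # Cov(1{Z > c}, X) = dnorm(c) * rho for jointly standard normal (Z, X)
  v + 2 * b_sex * stats::dnorm(c_sex) * sum(bz * R[, "sexl"])
}

effect_to_bz <- function(e, vars) {
  bz <- stats::setNames(numeric(length(vars)), vars)
  bz[paste0("qsm_", DGM_REGIONS)] <- e$qsm[DGM_REGIONS]
  bz[paste0("vol_", DGM_REGIONS)] <- e$volume[DGM_REGIONS]
  bz["age"] <- e$age
  bz["disease_duration"] <- e$dd
  bz
}

#' Generate a synthetic cohort table
#'
#' Draws correlated Gaussian latents for the covariates, susceptibilities,
#' volumes and TIV; forms each baseline outcome as the injected standardized
#' linear combination of latents plus Gaussian residual scaled so the
#' outcome has unit latent variance; forms follow-up clinical outcomes as
#' `autocorrelation * baseline + injected longitudinal effects + noise`;
#' then maps everything to natural units. Deterministic given the spec
#' seed.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` of class `cohort_table`, one row per subject:
#'   `subject_id`, `age` (years), `sex` (0 female / 1 male),
#'   `disease_duration` (years), `qsm_<region>` (ppm), `vol_<region>`
#'   (normalized, mL), `tiv` (mL), `nbv` (mL), `tlv` (mL), `log_tlv`,
#'   baseline outcomes `edss`, `t25fw`, `nhpt`, `sdmt`, `fsmc`, follow-up
#'   outcomes `fu_*` (NA when unavailable), `followup_interval` (years).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  cp <- spec$covariate_params
  R <- spec$latent_correlation
  vars <- colnames(R)
  with_seed(spec$seed, {
    Z <- matrix(rnorm(n * ncol(R)), n) %*% chol(R)
    colnames(Z) <- vars
    c_sex <- qnorm(1 - cp$sex_male_frac)
    sex01 <- as.integer(Z[, "sexl"] > c_sex)

    age <- cp$age[1] + cp$age[2] * Z[, "age"]
    dd <- pmax(cp$disease_duration[1] + cp$disease_duration[2] *
                 Z[, "disease_duration"], 0.1)
    tiv <- cp$tiv[1] + cp$tiv[2] * Z[, "tiv"]
    qsm <- sapply(DGM_REGIONS, function(r)
      cp$qsm[[r]][1] + cp$qsm[[r]][2] * Z[, paste0("qsm_", r)])
    vol <- sapply(DGM_REGIONS, function(r)
      cp$volume[[r]][1] + cp$volume[[r]][2] * Z[, paste0("vol_", r)])

    # baseline outcomes on the latent (z) scale
    yz <- list()
    for (o in CS_OUTCOMES) {
      e <- spec$effect_map[[o]]
      bz <- effect_to_bz(e, vars)
      sig <- as.numeric(Z %*% bz) + e$sex * sex01
      v <- signal_variance(bz, e$sex, R, c_sex)
      if (v >= 1)
        stop(sprintf("effects for outcome '%s' leave residual variance <= 0", o))
      yz[[o]] <- sig + rnorm(n, 0, spec$noise_sd * sqrt(1 - v))
    }

    # follow-up clinical outcomes on the latent scale
    interval <- runif(n, spec$followup_interval[1], spec$followup_interval[2])
    fuz <- list()
    for (o in CLINICAL_OUTCOMES) {
      e <- spec$longitudinal_effects[[o]]
      bz <- effect_to_bz(e, vars)
      sig <- spec$autocorrelation * yz[[o]] +
        as.numeric(Z %*% bz) + e$sex * sex01
      # empirical variance; floored so autocorrelation = 1 stays valid
      v <- min(var(sig), 1 - 1e-4)
      fuz[[o]] <- sig + rnorm(n, 0, spec$noise_sd * sqrt(1 - v))
    }

    # natural units
    os <- cp$outcome_scale
    nat <- function(o, z) os[[o]][1] + os[[o]][2] * z
    tlv <- pmax(exp(nat("log_tlv", yz$log_tlv)) - 0.01, 0)

    tab <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = age, sex = sex01, disease_duration = dd,
      stringsAsFactors = FALSE)
    for (r in DGM_REGIONS) tab[[paste0("qsm_", r)]] <- qsm[, r]
    for (r in DGM_REGIONS) tab[[paste0("vol_", r)]] <- vol[, r]
    tab$tiv <- tiv
    tab$nbv <- nat("nbv", yz$nbv)
    tab$tlv <- tlv
    tab$log_tlv <- log_tlv(tlv)
    for (o in CLINICAL_OUTCOMES) tab[[o]] <- nat(o, yz[[o]])
    for (o in CLINICAL_OUTCOMES) {
      fu <- nat(o, fuz[[o]])
      keep <- runif(n) < spec$followup_fraction[[o]]
      fu[!keep] <- NA_real_
      tab[[paste0("fu_", o)]] <- fu
    }
    has_fu <- rowSums(!is.na(tab[paste0("fu_", CLINICAL_OUTCOMES)])) > 0
    interval[!has_fu] <- NA_real_
    tab$followup_interval <- interval

    attr(tab, "spec") <- spec
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x), "subjects,",
      sum(!is.na(x$followup_interval)), "with follow-up;",
      ncol(x), "columns\n")
  print(utils::head(as.data.frame(x)[, 1:8]), row.names = FALSE)
  invisible(x)
}
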