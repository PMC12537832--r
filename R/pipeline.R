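#' Pipeline configuration
#'
#' One nested list holding the parameter blocks of every stage; each
#' stochastic stage derives its own seed from the single global seed, so a
#' full run is reproducible from `global_seed` alone. Round-trips
#' losslessly through YAML ([write_config()] / [read_config()]).
#'
#' @param global_seed integer master seed.
#' @param grid,acq,recon parameter lists accepted by [grid_spec()],
#'   [acq_params()], [recon_params()].
#' @param cohort parameter list accepted by [cohort_spec()] (seed is
#'   derived).
#' @param stats list with `n_permutations` and FDR level `q`.
#' @param output_dir where pipeline artifacts are written.
#' @param verbose print stage progress.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(global_seed = 1L,
                            grid = list(shape = c(64L, 64L, 64L),
                                        voxel_size = c(1, 1, 1)),
                            acq = list(noise_sigma = 0.02),
                            recon = list(),
                            cohort = list(n_subjects = 771L),
                            stats = list(n_permutations = 1000L, q = 0.05),
                            output_dir = "qsmdgm_run",
                            verbose = TRUE) {
  structure(list(global_seed = as.integer(global_seed), grid = grid,
                 acq = acq, recon = recon, cohort = cohort, stats = stats,
                 output_dir = output_dir, verbose = verbose),
            class = "pipeline_config")
}

# fixed offsets keep stage seeds distinct yet derived from one master seed
stage_seed <- function(config, stage) {
  offsets <- c(phantom = 101L, signal = 211L, cohort = 307L,
               battery_cs = 401L, battery_long = 503L, recon = 601L)
  (config$global_seed * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw)
  cfg
}

# config hash for the run manifest (md5 of the canonical JSON serialization)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(config, path, artifacts) {
  jsonlite::write_json(
    list(config_hash = config_hash(config),
         global_seed = config$global_seed,
         artifacts = artifacts,
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("qsmdgm")),
         timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Chains every stage: phantom construction, multi-echo signal synthesis,
#' mTFI reconstruction, region metric extraction, cohort simulation, and
#' the cross-sectional plus longitudinal regression batteries. All outputs
#' (NIfTI volumes, CSV tables, JSON manifest) land in
#' `config$output_dir`.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with `phantom`, `signal`, `map`, `metrics`,
#'   `cohort`, `battery_cs`, `battery_long`, `manifest` (path).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  od <- function(f) file.path(config$output_dir, f)
  artifacts <- character(0)

  say("phantom ...")
  grid <- do.call(grid_spec, config$grid)
  phantom <- make_dgm_phantom(grid, seed = stage_seed(config, "phantom"))
  write_volume(phantom$chi, od("chi_truth.nii.gz"), grid)
  write_volume(phantom$labels + 0, od("labels.nii.gz"), grid)
  write_volume(phantom$brain_mask + 0, od("brain_mask.nii.gz"), grid)
  write_volume(phantom$csf_mask + 0, od("csf_mask.nii.gz"), grid)
  artifacts <- c(artifacts, "chi_truth.nii.gz", "labels.nii.gz",
                 "brain_mask.nii.gz", "csf_mask.nii.gz")

  say("multi-echo signal ...")
  acq <- do.call(acq_params, config$acq)
  signal <- synthesize_multiecho(phantom, acq,
                                 seed = stage_seed(config, "signal"))
  write_signal(signal, od("signal"))
  artifacts <- c(artifacts, "signal_mag.nii.gz", "signal_phase.nii.gz",
                 "signal_acq.json")

  say("mTFI reconstruction ...")
  rp <- do.call(recon_params, config$recon)
  map <- mtfi_reconstruct(signal, phantom$brain_mask, phantom$csf_mask, rp)
  write_volume(map$chi, od("qsm.nii.gz"), grid)
  artifacts <- c(artifacts, "qsm.nii.gz")

  say("region metrics ...")
  metrics <- region_metrics(map, phantom)
  write.csv(metrics$regions, od("region_metrics.csv"), row.names = FALSE)
  artifacts <- c(artifacts, "region_metrics.csv")

  say("cohort ...")
  cargs <- config$cohort
  cargs$seed <- stage_seed(config, "cohort")
  cspec <- do.call(cohort_spec, cargs)
  cohort <- generate_cohort(cspec)
  write_cohort(cohort, od("cohort.csv"))
  artifacts <- c(artifacts, "cohort.csv")

  say("regression batteries ...")
  nb <- config$stats$n_permutations
  qq <- config$stats$q
  bcs <- run_cross_sectional_battery(cohort, n_permutations = nb,
                                     seed = stage_seed(config, "battery_cs"),
                                     q = qq)
  blong <- run_longitudinal_battery(cohort, n_permutations = nb,
                                    seed = stage_seed(config, "battery_long"),
                                    q = qq)
  write.csv(bcs$results, od("cross_sectional_results.csv"), row.names = FALSE)
  write.csv(blong$results, od("longitudinal_results.csv"), row.names = FALSE)
  artifacts <- c(artifacts, "cross_sectional_results.csv",
                 "longitudinal_results.csv")

  write_config(config, od("config.yaml"))
  manifest <- write_manifest(config, od("manifest.json"),
                             c(artifacts, "config.yaml"))
  say("done: ", config$output_dir)
  invisible(list(phantom = phantom, signal = signal, map = map,
                 metrics = metrics, cohort = cohort, battery_cs = bcs,
                 battery_long = blong, manifest = manifest))
}
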