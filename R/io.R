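#' Write / read a volume as NIfTI-1
#'
#' Volumes are written with an RAS+ diagonal affine built from the grid's
#' voxel sizes; reading returns the data array plus the recovered voxel
#' sizes. Pairing functions refuse shape mismatches rather than resampling.
#'
#' @param volume 3-D (or 4-D) numeric array.
#' @param path file path (`.nii` / `.nii.gz`).
#' @param grid a [grid_spec()] supplying voxel sizes.
#' @return `write_volume` returns the path invisibly; `read_volume`
#'   returns a list with `data` (plain array) and `voxel_size`.
#' @export
write_volume <- function(volume, path, grid = NULL) {
  vs <- if (is.null(grid)) c(1, 1, 1) else grid$voxel_size
  attr(volume, "pixdim") <- rep(vs, length.out = length(dim(volume)))
  RNifti::writeNifti(volume, path, datatype = "double")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       voxel_size = RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))])
}

#' Write / read a multi-echo complex signal as a magnitude/phase NIfTI pair
#'
#' The complex 4-D signal is stored as two 4-D NIfTI files,
#' `<stem>_mag.nii.gz` and `<stem>_phase.nii.gz` (phase in rad), the usual
#' scanner-export dialect; echo times and acquisition metadata travel in a
#' JSON sidecar `<stem>_acq.json`.
#'
#' @param signal a [synthesize_multiecho()] object.
#' @param stem path stem (no extension).
#' @return `write_signal` the stem invisibly; `read_signal` a
#'   `multiecho_signal`.
#' @export
write_signal <- function(signal, stem) {
  write_volume(Mod(signal$signal), paste0(stem, "_mag.nii.gz"), signal$grid)
  write_volume(Arg(signal$signal), paste0(stem, "_phase.nii.gz"), signal$grid)
  acq <- signal$acq
  jsonlite::write_json(
    list(echo_times = acq$echo_times, tr = acq$tr,
         flip_angle = acq$flip_angle, b0 = acq$b0,
         noise_sigma = acq$noise_sigma,
         shape = signal$grid$shape, voxel_size = signal$grid$voxel_size,
         b0_direction = signal$grid$b0_direction),
    paste0(stem, "_acq.json"), digits = NA, auto_unbox = FALSE)
  invisible(stem)
}

#' @rdname write_signal
#' @export
read_signal <- function(stem) {
  mag <- read_volume(paste0(stem, "_mag.nii.gz"))
  ph <- read_volume(paste0(stem, "_phase.nii.gz"))
  if (!identical(dim(mag$data), dim(ph$data)))
    stop("magnitude and phase volumes have mismatched shapes")
  meta <- jsonlite::read_json(paste0(stem, "_acq.json"), simplifyVector = TRUE)
  grid <- grid_spec(meta$shape, meta$voxel_size, meta$b0_direction)
  acq <- acq_params(meta$echo_times, meta$tr, meta$flip_angle, meta$b0,
                    meta$noise_sigma)
  structure(list(signal = mag$data * exp(1i * ph$data), acq = acq,
                 grid = grid),
            class = "multiecho_signal")
}

#' Write / read a cohort table as CSV
#'
#' UTF-8 CSV with the frozen column dictionary of [generate_cohort()].
#'
#' @param table a `cohort_table` data frame.
#' @param path CSV path.
#' @return `write_cohort` the path invisibly; `read_cohort` a
#'   `cohort_table`.
#' @export
write_cohort <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Check that two volumes share a grid
#'
#' @param a,b arrays (or lists with `data`).
#' @return invisibly TRUE; error on mismatch.
#' @export
check_same_grid <- function(a, b) {
  da <- if (is.list(a)) dim(a$data) else dim(a)
  db <- if (is.list(b)) dim(b$data) else dim(b)
  if (!identical(da, db))
    stop(sprintf("volume shape mismatch: %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}
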