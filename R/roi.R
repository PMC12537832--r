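#' Mean susceptibility over a labelled region
#'
#' @param chi a `susceptibility_map` or plain 3-D array, ppm.
#' @param labels integer 3-D array of region labels.
#' @param label_id label value (integer) or, if `labels` carries structure
#'   names via `region_names`, a region name.
#' @param region_names optional character vector mapping label values
#'   (1-based) to names.
#' @return scalar mean susceptibility, ppm.
#' @export
roi_mean <- function(chi, labels, label_id, region_names = NULL) {
  vol <- if (inherits(chi, "susceptibility_map")) chi$chi else chi
  if (!identical(dim(vol), dim(labels))) stop("shape mismatch")
  if (is.character(label_id)) {
    if (is.null(region_names)) stop("region_names needed for name lookup")
    idx <- match(label_id, region_names)
    if (is.na(idx)) stop(sprintf("label '%s' not found", label_id))
    label_id <- idx
  }
  sel <- labels == label_id
  if (!any(sel)) stop(sprintf("label '%s' absent from the label volume",
                              as.character(label_id)))
  mean(vol[sel])
}

#' Head-size normalization of a regional volume
#'
#' Divides by the individual total intracranial volume (TIV) and multiplies
#' by the cohort mean TIV, so values stay on an intuitive mL scale.
#'
#' @param raw_ml raw regional volume, mL.
#' @param tiv_ml individual TIV, mL (> 0).
#' @param mean_tiv_ml cohort mean TIV, mL.
#' @return normalized volume, mL.
#' @export
normalize_volume <- function(raw_ml, tiv_ml, mean_tiv_ml) {
  if (any(tiv_ml <= 0)) stop("tiv must be > 0")
  raw_ml / tiv_ml * mean_tiv_ml
}

# 26-connected component labelling of a logical 3-D mask.
# Breadth-first flood fill over the voxel index list.
label_components_26 <- function(mask) {
  d <- dim(mask)
  comp <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0) return(comp)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  ar <- arrayInd(idx, d)
  key <- function(m) (m[, 3] - 1L) * (d[1] * d[2]) + (m[, 2] - 1L) * d[1] + m[, 1]
  inmask <- logical(prod(d)); inmask[idx] <- TRUE
  visited <- logical(prod(d))
  cur <- 0L
  for (s in idx) {
    if (visited[s]) next
    cur <- cur + 1L
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      comp[queue] <- cur
      pts <- arrayInd(queue, d)
      cand <- do.call(rbind, lapply(seq_len(nrow(nb)), function(i)
        cbind(pts[, 1] + nb[i, 1], pts[, 2] + nb[i, 2], pts[, 3] + nb[i, 3])))
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      k <- unique(key(cand))
      k <- k[inmask[k] & !visited[k]]
      visited[k] <- TRUE
      queue <- k
    }
  }
  comp
}

#' Filter small lesions and compute total lesion volume
#'
#' Removes connected components (26-connectivity) of the lesion mask whose
#' volume is below `min_volume_mm3` (components exactly at the threshold
#' are retained) and sums the surviving volumes into the total lesion
#' volume (TLV), reported in mL. The 15 mm^3 default corresponds to a
#' 3 mm-diameter sphere, the usual minimum size of a reportable lesion.
#'
#' @param lesion_mask logical 3-D array.
#' @param voxel_volume_mm3 volume of one voxel, mm^3.
#' @param min_volume_mm3 survival threshold, mm^3 (inclusive).
#' @return list with `mask` (filtered logical array), `tlv_ml`,
#'   `n_components` (surviving), `component_volumes_mm3`.
#' @export
lesion_filter_tlv <- function(lesion_mask, voxel_volume_mm3,
                              min_volume_mm3 = 15) {
  stopifnot(is.logical(lesion_mask))
  comp <- label_components_26(lesion_mask)
  if (max(comp) == 0L)
    return(list(mask = lesion_mask & FALSE, tlv_ml = 0,
                n_components = 0L, component_volumes_mm3 = numeric(0)))
  sizes <- tabulate(comp[comp > 0L])
  vols <- sizes * voxel_volume_mm3
  keep <- which(vols >= min_volume_mm3)
  out <- array(FALSE, dim(lesion_mask))
  out[comp %in% keep] <- TRUE
  list(mask = out, tlv_ml = sum(vols[keep]) / 1000,
       n_components = length(keep), component_volumes_mm3 = vols[keep])
}

#' Logarithmic transform of the total lesion volume
#'
#' Natural log of TLV plus a small offset so that lesion-free subjects
#' (TLV = 0) remain defined; the 0.01 mL default offset is exposed because
#' the choice is a convention, not a measurement.
#'
#' @param tlv_ml total lesion volume, mL (>= 0).
#' @param offset additive offset, mL.
#' @return log-transformed TLV.
#' @export
log_tlv <- function(tlv_ml, offset = 0.01) {
  if (any(tlv_ml < 0)) stop("tlv must be >= 0")
  log(tlv_ml + offset)
}

#' Extract all region metrics from a reconstructed map and phantom masks
#'
#' Computes per-region mean susceptibility, voxel counts and raw volumes,
#' the lesion-filtered TLV and its log transform. Head-size-normalized
#' volumes need a cohort context (individual and mean TIV) and use
#' [normalize_volume()].
#'
#' @param map a `susceptibility_map` (or plain chi array).
#' @param phantom a `qsm_phantom` providing labels, masks and grid.
#' @param tiv_ml,mean_tiv_ml optional TIV context for normalized volumes.
#' @param min_lesion_mm3 lesion survival threshold, mm^3.
#' @return object of class `region_metrics`: data frame `regions` (name,
#'   mean qsm ppm, voxel count, raw and normalized volume mL) plus fields
#'   `tlv_ml`, `log_tlv`, `tiv_ml`.
#' @export
region_metrics <- function(map, phantom, tiv_ml = NULL, mean_tiv_ml = NULL,
                           min_lesion_mm3 = 15) {
  vox_mm3 <- prod(phantom$grid$voxel_size)
  nms <- vapply(phantom$structures, `[[`, "", "label")
  rows <- lapply(seq_along(nms), function(i) {
    n <- sum(phantom$labels == i)
    raw_ml <- n * vox_mm3 / 1000
    data.frame(region = nms[i],
               qsm_ppm = roi_mean(map, phantom$labels, i),
               voxels = n, volume_ml = raw_ml,
               norm_volume_ml = if (is.null(tiv_ml)) NA_real_ else
                 normalize_volume(raw_ml, tiv_ml, mean_tiv_ml),
               stringsAsFactors = FALSE)
  })
  les <- lesion_filter_tlv(phantom$lesion_mask, vox_mm3, min_lesion_mm3)
  structure(list(regions = do.call(rbind, rows),
                 tlv_ml = les$tlv_ml, log_tlv = log_tlv(les$tlv_ml),
                 n_lesions = les$n_components, tiv_ml = tiv_ml),
            class = "region_metrics")
}

#' @export
print.region_metrics <- function(x, ...) {
  cat("region_metrics:\n")
  print(x$regions, row.names = FALSE)
  cat(sprintf("  TLV %.3f mL (%d lesions), log-TLV %.3f\n",
              x$tlv_ml, x$n_lesions, x$log_tlv))
  invisible(x)
}
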