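#' Whole-brain mean perfusion
#'
#' Unweighted mean of the uncorrected CBF map over every voxel classified
#' as brain tissue, CSF included — the conventional "whole brain CBF" of
#' clinical ASL reports (hence lower than cortical values).
#'
#' @param cbf A [cbf_map()] or numeric 3-D array.
#' @param brain_mask Logical array of brain voxels; defaults to the map's
#'   own mask.
#' @return Scalar mean (mL/100 g/min).
#' @export
whole_brain_mean <- function(cbf, brain_mask = NULL) {
  if (inherits(cbf, "cbf_map")) {
    values <- cbf$values
    if (is.null(brain_mask)) brain_mask <- cbf$mask
  } else {
    values <- cbf
    if (is.null(brain_mask))
      stop("brain_mask is required when `cbf` is a plain array")
  }
  stopifnot(identical(dim(values), dim(brain_mask)))
  if (sum(brain_mask) == 0) stop("empty brain mask")
  mean(values[brain_mask])
}

#' Regional mean perfusion
#'
#' Per-region unweighted means of the uncorrected CBF map over a label
#' map, optionally augmented with PVE-weighted PVC cortical means from a
#' [pvc_regress()] result. Regions absent from the label map are reported
#' as missing (`NA` with zero voxel count), never as zero.
#'
#' @param cbf A [cbf_map()] (uncorrected).
#' @param labels Integer 3-D label map congruent with `cbf`.
#' @param region_ids Integer labels to summarize (default 1..5).
#' @param region_names Names for those labels (default the five cortical
#'   regions in [asl_regions]).
#' @param pvc Optional [pvc_regress()] result for PVC cortical means.
#' @param pve_gm GM PVE map, required when `pvc` is given.
#' @return A `data.frame` with columns `region`, `n_voxels`, `mean_cbf`
#'   and (when `pvc` is supplied) `pvc_cbf`.
#' @export
regional_means <- function(cbf, labels, region_ids = 1:5,
                           region_names = asl_regions,
                           pvc = NULL, pve_gm = NULL) {
  stopifnot(inherits(cbf, "cbf_map"))
  if (!identical(dim(labels), dim(cbf$values)))
    stop("label map must be congruent with the CBF map")
  if (length(region_ids) != length(region_names))
    stop("region_ids and region_names must have equal length")
  if (!is.null(pvc) && is.null(pve_gm))
    stop("pve_gm is required for PVC regional means")
  out <- data.frame(region = region_names,
                    n_voxels = NA_integer_,
                    mean_cbf = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(pvc)) out$pvc_cbf <- NA_real_
  for (k in seq_along(region_ids)) {
    sel <- labels == region_ids[k] & cbf$mask
    out$n_voxels[k] <- sum(sel)
    if (out$n_voxels[k] > 0) {
      out$mean_cbf[k] <- mean(cbf$values[sel])
      if (!is.null(pvc)) {
        out$pvc_cbf[k] <- tryCatch(
          weighted_cortical_mean(pvc, pve_gm, roi_mask = sel),
          error = function(e) NA_real_)
      }
    }
  }
  out
}

#' Full regional and global perfusion summary
#'
#' Combines [whole_brain_mean()], [regional_means()] and the global
#' PVE-weighted PVC cortical mean into one summary, matching the usual
#' reporting layout of clinical ASL studies (whole brain including CSF,
#' PVC cortical, then the five cortical regions uncorrected and PVC).
#'
#' @param cbf A [cbf_map()] (uncorrected).
#' @param labels Integer region label map.
#' @param pvc A [pvc_regress()] result.
#' @param pve_gm GM PVE map.
#' @param brain_mask Optional brain mask for the whole-brain mean.
#' @return A list with `whole_brain_cbf`, `pvc_cortical_cbf`, and the
#'   `regional` data.frame from [regional_means()].
#' @export
region_summary <- function(cbf, labels, pvc, pve_gm, brain_mask = NULL) {
  list(whole_brain_cbf = whole_brain_mean(cbf, brain_mask),
       pvc_cortical_cbf = weighted_cortical_mean(pvc, pve_gm),
       regional = regional_means(cbf, labels, pvc = pvc, pve_gm = pve_gm))
}
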