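#' Intensity-scale a template-space scan to a DVR image
#'
#' Divides the image by the 75th percentile of its intensities in the
#' reference region (whole brain without striata, thalamus/brainstem,
#' cerebellum and ventricles), yielding the distribution volume ratio
#' (DVR). The output is invariant to any positive global intensity scale
#' of the input.
#'
#' @param img template-space `vol3d`.
#' @param reference_mask binary `vol3d` reference region.
#' @param q reference quantile (0.75).
#' @return DVR `vol3d`.
#' @export
to_dvr <- function(img, reference_mask, q = 0.75) {
  ref <- masked_percentile(img, reference_mask, q)
  if (ref <= 0) stop("degenerate scan: nonpositive reference percentile")
  out <- img
  out$data <- img$data / ref
  out
}

#' Hottest-voxels putamen SBR
#'
#' Averages the `n` largest DVR values inside a large unilateral putamen
#' mask, where `n` corresponds to a fixed total volume (default 10 ml; at
#' 2 mm isotropic voxels n = 1250), and returns SBR = mean DVR - 1. Ties
#' at the n-th value are resolved by descending value with deterministic
#' index order.
#'
#' @param dvr DVR `vol3d`.
#' @param mask binary unilateral putamen mask (`vol3d`), much larger than
#'   the putamen itself.
#' @param volume_ml total volume of the averaged hottest voxels, ml.
#' @return Scalar SBR.
#' @export
hottest_voxels_sbr <- function(dvr, mask, volume_ml = 10) {
  stopifnot_same_grid(dvr, mask)
  n <- round(volume_ml * 1000 / voxel_volume(dvr))
  vals <- dvr$data[mask$data > 0]
  if (length(vals) < n)
    stop("mask holds fewer voxels (", length(vals), ") than the ",
         volume_ml, " ml hottest-voxels volume (", n, ")")
  mean(sort(vals, decreasing = TRUE, method = "radix")[seq_len(n)]) - 1
}

#' Anatomical-ROI mean putamen SBR
#'
#' Mean DVR over a tight anatomical unilateral putamen mask, minus 1.
#'
#' @param dvr DVR `vol3d`.
#' @param mask binary anatomical putamen mask.
#' @return Scalar SBR.
#' @export
roi_mean_sbr <- function(dvr, mask) {
  stopifnot_same_grid(dvr, mask)
  sel <- mask$data > 0
  if (!any(sel)) stop("empty mask")
  mean(dvr$data[sel]) - 1
}

#' Quantify one native scan end to end
#'
#' Runs stereotactical normalization (single or multiple templates),
#' intensity scaling to DVR, and both ROI methods (hottest voxels and
#' anatomical mean) on both hemispheres. Returns one row per ROI method
#' with left/right/min/mean SBR and the DET of the normalization
#' transform.
#'
#' @param scan native `vol3d`.
#' @param templates a [template_set]; for `template_mode = "single"` only
#'   the first template is used.
#' @param masks an [roi_mask_set].
#' @param template_mode `"single"` or `"multiple"`.
#' @param scan_id identifier recorded in the output.
#' @param volume_ml hottest-voxels volume, ml.
#' @param opts registration options ([normalize_opts()]).
#' @param transform optional fixed [affine12] (or 4x4 matrix) mapping the
#'   scan to template space; when supplied, registration is skipped and
#'   the scan is resampled through it (used for ground-truth evaluation).
#' @return A data.frame of class `sbr_record` with one row per ROI method
#'   (`HV`, `AAL`): columns scan_id, template_mode, roi_method, sbr_left,
#'   sbr_right, sbr_min, sbr_mean, det.
#' @export
quantify_scan <- function(scan, templates, masks,
                          template_mode = c("single", "multiple"),
                          scan_id = "scan", volume_ml = 10,
                          opts = normalize_opts(), transform = NULL) {
  template_mode <- match.arg(template_mode)
  if (is.null(transform)) {
    tset <- if (template_mode == "single")
      template_set(templates$templates[1], templates$labels[1]) else templates
    res <- normalize_scan(scan, tset, masks$head_mask, opts = opts)
    normalized <- res$normalized
    det <- res$det
  } else {
    normalized <- resample(scan, xf = as_matrix4(transform),
                           target = masks$head_mask, space = "template")
    det <- det_of(transform)
  }
  dvr <- to_dvr(normalized, masks$reference_mask)
  row <- function(method, l, r) {
    data.frame(scan_id = scan_id, template_mode = template_mode,
               roi_method = method, sbr_left = l, sbr_right = r,
               sbr_min = min(l, r), sbr_mean = (l + r) / 2, det = det,
               row.names = NULL)
  }
  hv <- row("HV",
            hottest_voxels_sbr(dvr, masks$hv_putamen_left, volume_ml),
            hottest_voxels_sbr(dvr, masks$hv_putamen_right, volume_ml))
  an <- row("AAL",
            roi_mean_sbr(dvr, masks$anat_putamen_left),
            roi_mean_sbr(dvr, masks$anat_putamen_right))
  out <- rbind(hv, an)
  class(out) <- c("sbr_record", class(out))
  out
}
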