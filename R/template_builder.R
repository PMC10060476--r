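#' Template set
#'
#' An ordered collection of DVR templates on one template grid, used as the
#' registration target. A single-template set drives classic
#' single-template normalization; the full set of eight (normal symmetric,
#' moderate deficit right, moderate deficit left, strong; each with and
#' without scalp signal from omitted attenuation/scatter correction) drives
#' multi-template normalization, where the best-matching linear combination
#' is fitted.
#'
#' @param templates list of `vol3d` on identical grids.
#' @param labels optional list of label vectors (category, scalp status).
#' @return An object of class `template_set`.
#' @export
template_set <- function(templates, labels = NULL) {
  if (!length(templates)) stop("empty template set")
  for (t in templates[-1]) stopifnot_same_grid(templates[[1]], t)
  if (is.null(labels))
    labels <- rep(list(c(category = "unlabelled", scalp = "unknown")),
                  length(templates))
  structure(list(templates = templates, labels = labels),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d template(s)\n", length(x$templates)))
  for (i in seq_along(x$templates))
    cat(sprintf("  [%d] %s\n", i,
                paste(names(x$labels[[i]]), x$labels[[i]], sep = "=",
                      collapse = ", ")))
  invisible(x)
}

#' @export
length.template_set <- function(x) length(x$templates)

#' Symmetrize an image at the midsagittal plane
#'
#' Returns `0.5 * (img + flip_lr(img))`; the output is an exact fixed
#' point of [flip_lr()].
#'
#' @param img template-space `vol3d`.
#' @return Symmetric `vol3d`.
#' @export
symmetrize <- function(img) {
  out <- img
  out$data <- 0.5 * (img$data + flip_lr(img)$data)
  out
}

#' Flip scans so the striatal deficit is right-lateralized
#'
#' Each template-space DVR scan whose right hottest-voxels putamen SBR
#' exceeds its left is left-right flipped, so that after the call the
#' deficit (lower SBR) is in the right hemisphere for every scan. Ties are
#' left unflipped.
#'
#' @param dvr_scans list of template-space DVR `vol3d`.
#' @param masks an [roi_mask_set] providing the HV putamen masks.
#' @param volume_ml hottest-voxels volume, ml.
#' @return List of `vol3d` with right HV SBR <= left HV SBR throughout.
#' @export
orient_deficit_right <- function(dvr_scans, masks, volume_ml = 10) {
  lapply(dvr_scans, function(s) {
    l <- hottest_voxels_sbr(s, masks$hv_putamen_left, volume_ml)
    r <- hottest_voxels_sbr(s, masks$hv_putamen_right, volume_ml)
    if (r > l) flip_lr(s) else s
  })
}

#' Left-deficit template from the right-deficit template
#'
#' @param template_right template-space `vol3d` with right-hemisphere
#'   deficit.
#' @return Its left-right mirror.
#' @export
make_left_variant <- function(template_right) flip_lr(template_right)

#' Iterative template construction from native scans
#'
#' Builds a category template by the iterative normalize-average scheme:
#' in each of `iterations` passes, every scan is stereotactically
#' normalized (single-template mode) to the current target (initially
#' `target0`, afterwards the previous pass's output), intensity-scaled to
#' DVR, for the moderate category flipped so the deficit is
#' right-lateralized, averaged voxelwise (soft mean), and for the normal
#' category symmetrized at the midsagittal plane.
#'
#' @param scans list of native `vol3d` (>= 2).
#' @param target0 initial target template (template-space `vol3d`).
#' @param masks [roi_mask_set] with head, reference and HV masks.
#' @param category `"normal"` (symmetrized), `"moderate"` (deficit
#'   right-oriented) or `"strong"` (averaged as-is).
#' @param iterations number of normalize-average passes (default 3: the
#'   initial pass plus two repeats).
#' @param opts registration options, see [normalize_opts()].
#' @return The built template as a template-space `vol3d`.
#' @export
build_template <- function(scans, target0, masks,
                           category = c("normal", "moderate", "strong"),
                           iterations = 3, opts = normalize_opts()) {
  category <- match.arg(category)
  if (length(scans) < 2) stop("need at least 2 scans")
  target <- target0
  for (it in seq_len(iterations)) {
    dvrs <- vector("list", length(scans))
    for (i in seq_along(scans)) {
      res <- normalize_scan(scans[[i]], target, masks$head_mask, opts = opts)
      if (!res$converged)
        stop("normalization did not converge for scan ", i,
             " in iteration ", it)
      dvrs[[i]] <- to_dvr(res$normalized, masks$reference_mask)
    }
    if (category == "moderate")
      dvrs <- orient_deficit_right(dvrs, masks)
    target <- soft_mean(dvrs)
    if (category == "normal") target <- symmetrize(target)
  }
  target
}
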