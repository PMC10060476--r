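#' Volumetric image
#'
#' A `vol3d` is a 3D scalar grid together with its voxel size (mm), a 4x4
#' homogeneous voxel-to-world affine `v2w` (0-based voxel index -> mm) and a
#' space tag (`"native"` or `"template"`). All images handled by the package
#' (scans, templates, DVR images, binary masks) are `vol3d` objects.
#'
#' When `v2w` is not supplied, a centered mapping is used: world coordinate
#' `voxel_size * (i - (dim - 1)/2)` per axis, so the world origin sits at the
#' grid center and the midsagittal plane is the central plane of the first
#' (left-right) axis.
#'
#' @param data 3D numeric array of finite intensities.
#' @param voxel_size length-3 positive numeric, mm.
#' @param v2w 4x4 voxel-to-world matrix, or `NULL` for the centered default.
#' @param space `"native"` or `"template"`.
#' @return An object of class `vol3d`.
#' @export
vol3d <- function(data, voxel_size = c(2, 2, 2), v2w = NULL,
                  space = c("native", "template")) {
  space <- match.arg(space)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (any(dim(data) < 1L)) stop("grid dimensions must be >= 1")
  if (!all(is.finite(data))) stop("all intensities must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive numbers (mm)")
  if (is.null(v2w)) {
    d <- dim(data)
    v2w <- diag(c(voxel_size, 1))
    v2w[1:3, 4] <- -voxel_size * (d - 1) / 2
  }
  v2w <- as.matrix(v2w)
  if (!all(dim(v2w) == c(4L, 4L))) stop("'v2w' must be a 4x4 matrix")
  if (abs(det(v2w[1:3, 1:3])) < .Machine$double.eps)
    stop("the 3x3 part of 'v2w' must be non-singular")
  structure(list(data = data, voxel_size = voxel_size, v2w = v2w,
                 space = space),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol3d> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, space: %s\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$space))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.vol3d <- function(x) dim(x$data)

#' Test that two volumes share one grid (dims, voxel size and affine).
#' @param a,b `vol3d` objects.
#' @param tol numeric tolerance on voxel size and affine entries.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$voxel_size - b$voxel_size)) < tol &&
    max(abs(a$v2w - b$v2w)) < tol
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("volumes are not on the same grid")
  invisible(TRUE)
}

#' Voxel volume in mm^3
#' @param img a `vol3d`.
#' @return Scalar, mm^3.
#' @export
voxel_volume <- function(img) prod(img$voxel_size)

# homogeneous 0-based index grid of a volume, 4 x N
index_grid_hom <- function(d) {
  g <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                             z = 0:(d[3] - 1)))
  rbind(t(g), 1)
}

#' Resample a volume through an affine transform onto a target grid
#'
#' Samples `img` trilinearly on the grid of `target`, through the world-space
#' affine `xf` (an [affine12] or plain 4x4 matrix mapping source world
#' coordinates to target world coordinates). Voxels mapping outside the
#' source field of view are set to zero (no wrapping). Intensities are
#' interpolated as stored; they are not rescaled by the local volume change
#' of the transform ("preserve concentrations").
#'
#' @param img source `vol3d`.
#' @param xf [affine12], 4x4 matrix, or `NULL` for identity.
#' @param target `vol3d` (only its geometry is used); `NULL` keeps the
#'   source grid.
#' @param space space tag for the output; default keeps the target's tag.
#' @return A `vol3d` on the target grid.
#' @export
resample <- function(img, xf = NULL, target = NULL, space = NULL) {
  if (is.null(target)) target <- img
  M <- if (is.null(xf)) diag(4) else as_matrix4(xf)
  if (abs(det(M[1:3, 1:3])) < 1e-12) stop("non-invertible transform")
  # target voxel -> target world -> source world -> source voxel
  S <- solve(img$v2w) %*% solve(M) %*% target$v2w
  d <- dim(target$data)
  pts <- (S %*% index_grid_hom(d))[1:3, , drop = FALSE]
  v <- cpp_trilinear(as.numeric(img$data), dim(img$data), pts)
  vol3d(array(v, d), target$voxel_size, target$v2w,
        if (is.null(space)) target$space else space)
}

#' Mirror a volume at the midsagittal plane
#'
#' Reverses the grid along the left-right axis, mirroring the image at the
#' grid's central sagittal plane. The operation is an exact involution:
#' `flip_lr(flip_lr(x))` equals `x` bitwise.
#'
#' @param img a `vol3d`.
#' @param axis left-right grid axis (default 1, the package convention).
#' @return The mirrored `vol3d` on the same grid.
#' @export
flip_lr <- function(img, axis = 1L) {
  d <- dim(img$data)
  if (!(axis %in% 1:3)) stop("'axis' must be 1, 2 or 3")
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- d[axis]:1
  out <- img
  out$data <- do.call(`[`, c(list(img$data), idx, list(drop = FALSE)))
  out
}

gauss_kernel_1d <- function(fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(1)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm  # in voxels
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian smoothing
#'
#' Convolves the image with a separable Gaussian of the given full width at
#' half maximum per axis (mm), `sigma = fwhm / (2 sqrt(2 log 2))`. Kernels
#' are normalized to unit sum and boundaries are handled by reflection, so
#' constant images are preserved exactly. `fwhm = 0` on an axis leaves that
#' axis untouched.
#'
#' @param img a `vol3d`.
#' @param fwhm_mm scalar or length-3 FWHM in mm, `>= 0`.
#' @return Smoothed `vol3d` on the same grid.
#' @export
gaussian_smooth <- function(img, fwhm_mm) {
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3)
  if (any(fwhm_mm < 0)) stop("'fwhm_mm' must be >= 0")
  if (all(fwhm_mm == 0)) return(img)
  d <- dim(img$data)
  x <- as.numeric(img$data)
  for (ax in 1:3) {
    k <- gauss_kernel_1d(fwhm_mm[ax], img$voxel_size[ax])
    if (length(k) > 1) x <- cpp_conv_axis(x, d, k, ax - 1L)
  }
  out <- img
  out$data <- array(x, d)
  out
}

#' Quantile of in-mask voxel intensities
#'
#' Returns the `q`-quantile of the intensities under a binary mask, using
#' linear interpolation between closest order statistics (R's default
#' quantile type 7).
#'
#' @param img a `vol3d`.
#' @param mask binary `vol3d` on the same grid.
#' @param q quantile in `[0, 1]`.
#' @return Scalar intensity.
#' @export
masked_percentile <- function(img, mask, q) {
  stopifnot_same_grid(img, mask)
  if (q < 0 || q > 1) stop("'q' must be in [0, 1]")
  sel <- mask$data > 0
  if (!any(sel)) stop("empty mask")
  unname(stats::quantile(img$data[sel], probs = q, type = 7))
}

#' Voxelwise mean of several volumes ("soft mean")
#'
#' @param imgs list of `vol3d` on identical grids.
#' @return The voxelwise arithmetic mean as a `vol3d`.
#' @export
soft_mean <- function(imgs) {
  if (!length(imgs)) stop("need at least one image")
  for (im in imgs[-1]) stopifnot_same_grid(imgs[[1]], im)
  out <- imgs[[1]]
  acc <- imgs[[1]]$data
  for (im in imgs[-1]) acc <- acc + im$data
  out$data <- acc / length(imgs)
  out
}

#' Region mask set in template space
#'
#' Bundles the binary masks used throughout the pipeline, all on one
#' template grid: the head weighting mask (brain plus scalp, cerebellum
#' excluded), the reference region for intensity scaling (brain without
#' striata, thalamus/brainstem, cerebellum and ventricles), the large
#' "hottest voxels" unilateral putamen masks and the tight anatomical
#' unilateral putamen masks.
#'
#' @param head_mask,reference_mask,hv_putamen_left,hv_putamen_right,anat_putamen_left,anat_putamen_right
#'   binary `vol3d` masks on a common template grid.
#' @param hv_volume_ml minimum volume each HV mask must hold (ml).
#' @return An object of class `roi_mask_set`.
#' @export
roi_mask_set <- function(head_mask, reference_mask, hv_putamen_left,
                         hv_putamen_right, anat_putamen_left,
                         anat_putamen_right, hv_volume_ml = 10) {
  masks <- list(head_mask = head_mask, reference_mask = reference_mask,
                hv_putamen_left = hv_putamen_left,
                hv_putamen_right = hv_putamen_right,
                anat_putamen_left = anat_putamen_left,
                anat_putamen_right = anat_putamen_right)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    stopifnot_same_grid(head_mask, m)
    if (!all(m$data %in% c(0, 1)))
      stop("mask '", nm, "' is not strictly binary")
  }
  if (any(hv_putamen_left$data * hv_putamen_right$data > 0))
    stop("left and right putamen masks must be disjoint")
  if (any(anat_putamen_left$data * anat_putamen_right$data > 0))
    stop("left and right putamen masks must be disjoint")
  if (any(reference_mask$data * (anat_putamen_left$data +
                                 anat_putamen_right$data) > 0))
    stop("reference mask must be disjoint from the putamen masks")
  vv <- voxel_volume(head_mask)
  need <- hv_volume_ml * 1000 / vv
  if (sum(hv_putamen_left$data) < need || sum(hv_putamen_right$data) < need)
    stop("each HV putamen mask must hold at least ", hv_volume_ml, " ml")
  structure(masks, class = "roi_mask_set")
}

#' @export
print.roi_mask_set <- function(x, ...) {
  vv <- voxel_volume(x$head_mask) / 1000
  cat("<roi_mask_set> volumes (ml):\n")
  for (nm in names(x))
    cat(sprintf("  %-20s %8.2f\n", nm, sum(x[[nm]]$data) * vv))
  invisible(x)
}
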