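#' Digital DAT-SPECT phantom specification
#'
#' Describes the synthetic world from which cohorts are simulated: a 2 mm
#' isotropic template grid holding ellipsoidal anatomy (brain, scalp shell,
#' bilateral putamen and caudate, cerebellum, ventricles, a
#' thalamus/brainstem placeholder), the point-spread blurring and noise of
#' reconstructed scans, and the ranges of the random affine misalignment
#' from template space.
#'
#' All structure geometry is given as ellipsoid centers and semi-axes in
#' world mm (world origin at the grid center, left-right along the first
#' axis). Left structures are exact mirrors of right ones. The defaults are
#' free modelling choices of the package (real clinical anatomy is both
#' larger and more complex); the putamen is deliberately sized so that the
#' 10 ml hottest-voxels volume nests inside its signal, and `striatum_atrophy`
#' shrinks the striatal structures of subjects with reduced uptake so that a
#' normal-uptake template is a geometric mismatch for them.
#'
#' @param shape template grid dimensions (voxels).
#' @param voxel_size_mm isotropic template voxel size, mm.
#' @param native_shape,native_voxel_mm geometry of simulated native scans
#'   (larger field of view so misaligned heads are not clipped).
#' @param brain,scalp_outer,putamen,caudate,cerebellum,ventricle,thalamus
#'   lists with `center` (right-hemisphere copy where lateral) and `semi`
#'   axes, mm.
#' @param hv_scale semi-axis inflation of the putamen ellipsoid giving the
#'   large hottest-voxels masks ("much bigger than the actual putamen").
#' @param anat_scale semi-axis shrinkage giving the tight anatomical masks.
#' @param background_dvr brain background DVR (1 by definition of DVR).
#' @param ventricle_dvr DVR painted in the ventricles.
#' @param scalp_dvr range of the scalp-shell DVR when the scalp is painted
#'   (mimicking omission of attenuation/scatter correction).
#' @param psf_fwhm_mm effective point-spread FWHM of reconstructed scans
#'   (mm); default matches a typical Gaussian post-filter.
#' @param noise_sd additive Gaussian noise SD as a fraction of background.
#' @param striatum_atrophy semi-axis scale of striatal structures in
#'   reduced subjects (and reduced templates).
#' @param translation_mm,rotation_deg,zoom_range,shear_max ranges of the
#'   uniform random misalignment from template space.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(54, 64, 50), voxel_size_mm = 2,
                         native_shape = c(60, 68, 56), native_voxel_mm = 2.5,
                         brain = list(center = c(0, 0, 0), semi = c(44, 54, 40)),
                         scalp_outer = list(center = c(0, 0, 0), semi = c(50, 60, 46)),
                         putamen = list(center = c(24, 6, 0), semi = c(11, 25, 13)),
                         caudate = list(center = c(14, 32, 10), semi = c(5, 12, 7)),
                         cerebellum = list(center = c(0, -38, -24), semi = c(26, 16, 13)),
                         ventricle = list(center = c(8, 4, 10), semi = c(4, 16, 7)),
                         thalamus = list(center = c(0, -6, -6), semi = c(12, 14, 16)),
                         hv_scale = 1.5, anat_scale = 0.85,
                         background_dvr = 1, ventricle_dvr = 0.5,
                         scalp_dvr = c(1.2, 2.0),
                         psf_fwhm_mm = 7, noise_sd = 0.05,
                         striatum_atrophy = 0.9,
                         translation_mm = 10, rotation_deg = 10,
                         zoom_range = c(0.9, 1.1), shear_max = 0.05) {
  if (zoom_range[1] <= 0) stop("zoom range must exclude 0")
  spec <- list(shape = shape, voxel_size_mm = voxel_size_mm,
               native_shape = native_shape, native_voxel_mm = native_voxel_mm,
               brain = brain, scalp_outer = scalp_outer, putamen = putamen,
               caudate = caudate, cerebellum = cerebellum,
               ventricle = ventricle, thalamus = thalamus,
               hv_scale = hv_scale, anat_scale = anat_scale,
               background_dvr = background_dvr, ventricle_dvr = ventricle_dvr,
               scalp_dvr = scalp_dvr, psf_fwhm_mm = psf_fwhm_mm,
               noise_sd = noise_sd, striatum_atrophy = striatum_atrophy,
               translation_mm = translation_mm, rotation_deg = rotation_deg,
               zoom_range = zoom_range, shear_max = shear_max)
  class(spec) <- "phantom_spec"
  spec
}

# empty template-space volume for a spec
template_grid <- function(spec, space = "template") {
  vol3d(array(0, spec$shape), voxel_size = rep(spec$voxel_size_mm, 3),
        space = space)
}

native_grid <- function(spec) {
  vol3d(array(0, spec$native_shape),
        voxel_size = rep(spec$native_voxel_mm, 3), space = "native")
}

# world coordinates (3 x N) of a template grid, cached per call site
grid_world <- function(grid) {
  d <- dim(grid$data)
  (grid$v2w %*% index_grid_hom(d))[1:3, , drop = FALSE]
}

# logical membership of an ellipsoid; side = +1 right, -1 left (mirrors
# the center's first coordinate), scale multiplies the semi-axes
ellipsoid_mask <- function(world, center, semi, side = NULL, scale = 1) {
  center <- as.numeric(center)
  if (!is.null(side)) center[1] <- side * center[1]
  semi <- as.numeric(semi) * scale
  ((world[1, ] - center[1]) / semi[1])^2 +
    ((world[2, ] - center[2]) / semi[2])^2 +
    ((world[3, ] - center[3]) / semi[3])^2 < 1
}

as_mask_vol <- function(sel, grid) {
  out <- grid
  out$data <- array(as.numeric(sel), dim(grid$data))
  out
}

#' Build the template-space anatomy masks of the phantom
#'
#' Returns the [roi_mask_set] of the phantom world (head weighting mask,
#' reference region, large hottest-voxels putamen masks, tight anatomical
#' putamen masks) plus an integer label image coding the painted
#' structures (0 background/air, 1 brain, 2 scalp shell, 3 cerebellum,
#' 4 ventricles, 5 thalamus placeholder, 6 caudate, 7 putamen).
#'
#' @param spec a [phantom_spec].
#' @return List with elements `masks` ([roi_mask_set]) and `labels`
#'   (`vol3d`).
#' @export
make_anatomy <- function(spec) {
  grid <- template_grid(spec)
  w <- grid_world(grid)
  brain <- ellipsoid_mask(w, spec$brain$center, spec$brain$semi)
  scalp <- ellipsoid_mask(w, spec$scalp_outer$center, spec$scalp_outer$semi) & !brain
  cere <- ellipsoid_mask(w, spec$cerebellum$center, spec$cerebellum$semi)
  thal <- ellipsoid_mask(w, spec$thalamus$center, spec$thalamus$semi)
  put_r <- ellipsoid_mask(w, spec$putamen$center, spec$putamen$semi, side = +1)
  put_l <- ellipsoid_mask(w, spec$putamen$center, spec$putamen$semi, side = -1)
  cau_r <- ellipsoid_mask(w, spec$caudate$center, spec$caudate$semi, side = +1)
  cau_l <- ellipsoid_mask(w, spec$caudate$center, spec$caudate$semi, side = -1)
  ven_r <- ellipsoid_mask(w, spec$ventricle$center, spec$ventricle$semi, side = +1)
  ven_l <- ellipsoid_mask(w, spec$ventricle$center, spec$ventricle$semi, side = -1)
  striat <- list(put_r, put_l, cau_r, cau_l)
  for (i in 1:3) for (j in (i + 1):4)
    if (any(striat[[i]] & striat[[j]])) stop("overlapping striatal structures")
  # large HV masks: inflated putamen, caudate carved out so putaminal
  # hottest voxels are not contaminated by the (hotter) caudate
  hv_r <- ellipsoid_mask(w, spec$putamen$center, spec$putamen$semi,
                         side = +1, scale = spec$hv_scale) & !cau_r & !cau_l
  hv_l <- ellipsoid_mask(w, spec$putamen$center, spec$putamen$semi,
                         side = -1, scale = spec$hv_scale) & !cau_r & !cau_l
  an_r <- ellipsoid_mask(w, spec$putamen$center, spec$putamen$semi,
                         side = +1, scale = spec$anat_scale)
  an_l <- ellipsoid_mask(w, spec$putamen$center, spec$putamen$semi,
                         side = -1, scale = spec$anat_scale)
  head <- (brain | scalp) & !cere
  ref <- brain & !(put_r | put_l | cau_r | cau_l | ven_r | ven_l | thal | cere)
  labels <- numeric(length(brain))
  labels[brain] <- 1; labels[scalp] <- 2; labels[cere] <- 3
  labels[ven_r | ven_l] <- 4; labels[thal] <- 5
  labels[cau_r | cau_l] <- 6; labels[put_r | put_l] <- 7
  masks <- roi_mask_set(
    head_mask = as_mask_vol(head, grid),
    reference_mask = as_mask_vol(ref, grid),
    hv_putamen_left = as_mask_vol(hv_l, grid),
    hv_putamen_right = as_mask_vol(hv_r, grid),
    anat_putamen_left = as_mask_vol(an_l, grid),
    anat_putamen_right = as_mask_vol(an_r, grid))
  list(masks = masks, labels = as_mask_vol(FALSE, grid) |>
         (\(v) { v$data <- array(labels, dim(grid$data)); v })())
}

#' Cohort mixture parameters
#'
#' The generating distribution of the simulated cohort's minimum putamen
#' SBR: a two-component Gaussian mixture (reduced / normal uptake), plus
#' the left-right asymmetry and caudate excess that complete a subject's
#' striatal profile. Defaults follow the fitted minimum hottest-voxels SBR
#' components under multi-template normalization (reduced: mean 0.58, SD
#' 0.15; normal: mean 1.57, SD 0.32) with the reduced fraction taken from
#' the corresponding classification marginals (764/1702).
#'
#' @param p_reduced probability of the reduced category.
#' @param m_reduced,sd_reduced mean and SD of the minimum putamen SBR in
#'   reduced subjects.
#' @param m_normal,sd_normal same for normal subjects.
#' @param asym_reduced,asym_normal SBR difference between the better and
#'   worse hemisphere by category.
#' @param caud_excess_reduced,caud_excess_normal caudate SBR excess over
#'   the same-side putamen SBR (Parkinson-typical rostrocaudal gradient).
#' @return An object of class `cohort_mixture`.
#' @export
cohort_mixture <- function(p_reduced = 0.449,
                           m_reduced = 0.58, sd_reduced = 0.15,
                           m_normal = 1.57, sd_normal = 0.32,
                           asym_reduced = 0.2, asym_normal = 0.05,
                           caud_excess_reduced = 0.5,
                           caud_excess_normal = 0.1) {
  if (p_reduced < 0 || p_reduced > 1) stop("'p_reduced' must be in [0, 1]")
  if (sd_reduced <= 0 || sd_normal <= 0) stop("component SDs must be > 0")
  structure(list(p_reduced = p_reduced, m_reduced = m_reduced,
                 sd_reduced = sd_reduced, m_normal = m_normal,
                 sd_normal = sd_normal, asym_reduced = asym_reduced,
                 asym_normal = asym_normal,
                 caud_excess_reduced = caud_excess_reduced,
                 caud_excess_normal = caud_excess_normal),
            class = "cohort_mixture")
}

# Gaussian truncated below at `lower` (keeps DVR = SBR + 1 positive)
rnorm_trunc <- function(n, mean, sd, lower = -0.5) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    out[need] <- stats::rnorm(length(need), mean, sd)
    need <- need[out[need] <= lower]
  }
  out
}

#' Draw one subject's ground truth from the cohort mixture
#'
#' Draws the category, the worse hemisphere (uniform left/right), the
#' minimum putamen SBR from the category's Gaussian truncated at
#' SBR > -0.5, sets the better hemisphere higher by the category's
#' asymmetry, and the caudate SBR above the same-side putamen SBR. Uses
#' the R session RNG (seed with [set.seed()] for reproducibility).
#'
#' @param mixture a [cohort_mixture].
#' @return An object of class `subject_truth`: category, worse side,
#'   per-structure true SBR and DVR (= SBR + 1); the true misalignment is
#'   attached later by [simulate_scan()] / [simulate_cohort()].
#' @export
sample_subject <- function(mixture) {
  stopifnot(inherits(mixture, "cohort_mixture"))
  reduced <- stats::runif(1) < mixture$p_reduced
  if (reduced) {
    m <- mixture$m_reduced; s <- mixture$sd_reduced
    asym <- mixture$asym_reduced; cexc <- mixture$caud_excess_reduced
  } else {
    m <- mixture$m_normal; s <- mixture$sd_normal
    asym <- mixture$asym_normal; cexc <- mixture$caud_excess_normal
  }
  worse <- if (stats::runif(1) < 0.5) "left" else "right"
  sbr_min <- rnorm_trunc(1, m, s)
  sbr <- c(left = sbr_min, right = sbr_min)
  better <- if (worse == "left") "right" else "left"
  sbr[better] <- sbr[worse] + asym
  caud <- sbr + cexc
  structure(list(category = if (reduced) "reduced" else "normal",
                 worse_side = worse,
                 sbr_putamen = sbr, sbr_caudate = caud,
                 dvr_putamen = sbr + 1, dvr_caudate = caud + 1,
                 true_affine = NULL),
            class = "subject_truth")
}

#' Draw a random misalignment from template space
#'
#' Uniform draws within the spec's ranges: translations, rotations, zooms
#' and shears. The returned [affine12] maps native world coordinates to
#' template world coordinates (it is the transform stereotactical
#' normalization must recover).
#'
#' @param spec a [phantom_spec].
#' @return An [affine12].
#' @export
sample_misalignment <- function(spec) {
  affine12(
    translation = stats::runif(3, -spec$translation_mm, spec$translation_mm),
    rotation = stats::runif(3, -spec$rotation_deg, spec$rotation_deg) * pi / 180,
    zoom = stats::runif(3, spec$zoom_range[1], spec$zoom_range[2]),
    shear = stats::runif(3, -spec$shear_max, spec$shear_max))
}

#' Paint a subject's noise-free DVR image in template space
#'
#' Background brain at DVR 1, putamen and caudate at the subject's true
#' DVR, ventricles at the spec's ventricular DVR, optional scalp shell.
#' Striatal ellipsoids of reduced subjects are shrunk by
#' `spec$striatum_atrophy`.
#'
#' @param spec a [phantom_spec].
#' @param truth a `subject_truth` (see [sample_subject()]).
#' @param scalp_on paint the scalp shell (omitted attenuation/scatter
#'   correction)?
#' @param scalp_dvr scalp DVR; default is the midpoint of the spec range.
#' @return Template-space `vol3d` DVR image.
#' @export
paint_subject <- function(spec, truth, scalp_on = FALSE, scalp_dvr = NULL) {
  grid <- template_grid(spec)
  w <- grid_world(grid)
  atro <- if (truth$category == "reduced") spec$striatum_atrophy else 1
  brain <- ellipsoid_mask(w, spec$brain$center, spec$brain$semi)
  img <- numeric(ncol(w))
  img[brain] <- spec$background_dvr
  ven <- ellipsoid_mask(w, spec$ventricle$center, spec$ventricle$semi, side = +1) |
    ellipsoid_mask(w, spec$ventricle$center, spec$ventricle$semi, side = -1)
  img[ven] <- spec$ventricle_dvr
  for (side in c(-1, 1)) {
    nm <- if (side < 0) "left" else "right"
    cau <- ellipsoid_mask(w, spec$caudate$center, spec$caudate$semi,
                          side = side, scale = atro)
    put <- ellipsoid_mask(w, spec$putamen$center, spec$putamen$semi,
                          side = side, scale = atro)
    img[cau] <- truth$dvr_caudate[nm]
    img[put] <- truth$dvr_putamen[nm]
  }
  if (scalp_on) {
    if (is.null(scalp_dvr)) scalp_dvr <- mean(spec$scalp_dvr)
    scalp <- ellipsoid_mask(w, spec$scalp_outer$center, spec$scalp_outer$semi) & !brain
    img[scalp] <- scalp_dvr
  }
  out <- grid
  out$data <- array(img, dim(grid$data))
  out
}

#' Simulate one native-space DAT-SPECT-like scan
#'
#' Forward model: paint the subject's DVR in template space, blur by the
#' point-spread FWHM, add Gaussian noise truncated at zero, resample into
#' native space through the inverse of the true misalignment, and apply an
#' arbitrary global intensity scale. The truth returned carries
#' `true_affine`, the transform mapping the native scan back to template
#' space.
#'
#' @param spec a [phantom_spec].
#' @param truth a `subject_truth`; if its `true_affine` is `NULL` a random
#'   misalignment is drawn.
#' @param scalp_on paint the scalp shell?
#' @param native target native grid (`vol3d` geometry); default from spec.
#' @param noise_sd,psf_fwhm_mm,intensity_scale overrides of the spec/noise
#'   defaults; `intensity_scale = NULL` draws uniformly from `[0.5, 2]`.
#' @param scalp_dvr scalp DVR passed to [paint_subject()].
#' @return List with `scan` (native `vol3d`) and `truth` (completed
#'   `subject_truth`).
#' @export
simulate_scan <- function(spec, truth, scalp_on = FALSE, native = NULL,
                          noise_sd = spec$noise_sd,
                          psf_fwhm_mm = spec$psf_fwhm_mm,
                          intensity_scale = NULL, scalp_dvr = NULL) {
  if (is.null(truth$true_affine)) truth$true_affine <- sample_misalignment(spec)
  if (is.null(native)) native <- native_grid(spec)
  if (is.null(intensity_scale)) intensity_scale <- stats::runif(1, 0.5, 2)
  img <- paint_subject(spec, truth, scalp_on = scalp_on, scalp_dvr = scalp_dvr)
  if (psf_fwhm_mm > 0) img <- gaussian_smooth(img, psf_fwhm_mm)
  if (noise_sd > 0) {
    img$data <- img$data +
      stats::rnorm(length(img$data), 0, noise_sd * spec$background_dvr)
    img$data[img$data < 0] <- 0
  }
  # native(x) = template_image(A x): resample through the inverse of the
  # native -> template transform
  A <- as_matrix4(truth$true_affine)
  scan <- resample(img, xf = solve(A), target = native, space = "native")
  scan$data <- scan$data * intensity_scale
  list(scan = scan, truth = truth)
}

#' Simulate a reproducible cohort of native scans with ground truth
#'
#' @param spec a [phantom_spec].
#' @param n number of subjects (>= 1).
#' @param mixture a [cohort_mixture].
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param scalp_frac fraction of scans simulated with scalp signal
#'   (mimicking reconstructions without attenuation/scatter correction).
#' @return List with `scans` (list of native `vol3d`), `truths` (list of
#'   `subject_truth`) and `manifest` (one data.frame row per scan: id,
#'   category, worse side, true putamen SBR left/right/min, scalp flag,
#'   intensity scale, affine parameters and true DET).
#' @export
simulate_cohort <- function(spec, n, mixture = cohort_mixture(), seed = 1,
                            scalp_frac = 0.3) {
  if (n < 1) stop("'n' must be >= 1")
  set.seed(seed)
  scans <- vector("list", n)
  truths <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    truth <- sample_subject(mixture)
    truth$true_affine <- sample_misalignment(spec)
    scalp_on <- stats::runif(1) < scalp_frac
    scalp_dvr <- stats::runif(1, spec$scalp_dvr[1], spec$scalp_dvr[2])
    scale <- stats::runif(1, 0.5, 2)
    sim <- simulate_scan(spec, truth, scalp_on = scalp_on,
                         intensity_scale = scale, scalp_dvr = scalp_dvr)
    scans[[i]] <- sim$scan
    truths[[i]] <- sim$truth
    a <- sim$truth$true_affine
    rows[[i]] <- data.frame(
      scan_id = sprintf("scan%04d", i), category = truth$category,
      worse_side = truth$worse_side,
      true_sbr_left = truth$sbr_putamen["left"],
      true_sbr_right = truth$sbr_putamen["right"],
      true_sbr_min = min(truth$sbr_putamen),
      scalp = scalp_on, intensity_scale = scale,
      tx = a$translation[1], ty = a$translation[2], tz = a$translation[3],
      rx = a$rotation[1], ry = a$rotation[2], rz = a$rotation[3],
      zx = a$zoom[1], zy = a$zoom[2], zz = a$zoom[3],
      sxy = a$shear[1], sxz = a$shear[2], syz = a$shear[3],
      true_det = det_of(a), row.names = NULL)
  }
  list(scans = scans, truths = truths, manifest = do.call(rbind, rows),
       seed = seed)
}

#' Paint the eight-template set directly from the phantom anatomy
#'
#' Builds the full template set (normal symmetric, moderate deficit right,
#' moderate deficit left, strong; each with and without scalp signal) by
#' painting noise-free category prototypes and blurring them with the
#' point-spread FWHM. This bypasses the iterative build from scans (see
#' [build_template()]) and is the fast route used for simulated
#' experiments. Category SBR levels follow the reported minimum putamen
#' SBR of the template source scans (normal about 1.9, moderate about
#' 0.66, strong about 0.28).
#'
#' @param spec a [phantom_spec].
#' @param sbr_normal,sbr_moderate,sbr_strong worse-side putamen SBR of the
#'   category prototypes.
#' @param asym_moderate better-side excess of the moderate prototype.
#' @return A [template_set] of eight templates.
#' @export
paint_template_set <- function(spec, sbr_normal = 1.9, sbr_moderate = 0.66,
                               sbr_strong = 0.28, asym_moderate = 0.3) {
  proto <- function(category, sbr_worse, asym, worse = "right") {
    mix <- cohort_mixture()
    cexc <- if (category == "reduced") mix$caud_excess_reduced else
      mix$caud_excess_normal
    sbr <- c(left = sbr_worse, right = sbr_worse)
    better <- if (worse == "left") "right" else "left"
    sbr[better] <- sbr[worse] + asym
    structure(list(category = category, worse_side = worse,
                   sbr_putamen = sbr, sbr_caudate = sbr + cexc,
                   dvr_putamen = sbr + 1, dvr_caudate = sbr + cexc + 1,
                   true_affine = NULL),
              class = "subject_truth")
  }
  truth_n <- proto("normal", sbr_normal, 0)
  truth_m <- proto("reduced", sbr_moderate, asym_moderate, worse = "right")
  truth_s <- proto("reduced", sbr_strong, 0)
  mk <- function(truth, scalp_on) {
    img <- paint_subject(spec, truth, scalp_on = scalp_on)
    if (spec$psf_fwhm_mm > 0) img <- gaussian_smooth(img, spec$psf_fwhm_mm)
    img
  }
  templates <- list()
  labels <- list()
  for (scalp in c(FALSE, TRUE)) {
    t_norm <- symmetrize(mk(truth_n, scalp))
    t_modr <- mk(truth_m, scalp)
    t_modl <- flip_lr(t_modr)
    t_str <- mk(truth_s, scalp)
    templates <- c(templates, list(t_norm, t_modr, t_modl, t_str))
    sc <- if (scalp) "without_acsc" else "with_acsc"
    labels <- c(labels, list(
      c(category = "normal", scalp = sc),
      c(category = "moderate_right", scalp = sc),
      c(category = "moderate_left", scalp = sc),
      c(category = "strong", scalp = sc)))
  }
  template_set(templates, labels)
}
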