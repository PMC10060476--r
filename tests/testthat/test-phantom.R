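test_that("make_anatomy produces the documented mask geometry", {
  masks <- fix$masks
  vv <- voxel_volume(masks$head_mask) / 1000  # ml per voxel
  expect_gte(sum(masks$hv_putamen_left$data) * vv, 30)
  expect_gte(sum(masks$hv_putamen_right$data) * vv, 30)
  anat_ml <- sum(masks$anat_putamen_left$data) * vv
  expect_gte(anat_ml, 4)
  expect_lte(anat_ml, 12)

  # disjointness constraints
  expect_equal(sum(masks$reference_mask$data * masks$anat_putamen_left$data), 0)
  expect_equal(sum(masks$reference_mask$data * masks$anat_putamen_right$data), 0)
  expect_equal(sum(masks$hv_putamen_left$data * masks$hv_putamen_right$data), 0)

  # mirror symmetry by construction
  expect_identical(flip_lr(masks$hv_putamen_left)$data,
                   masks$hv_putamen_right$data)
  expect_identical(flip_lr(masks$anat_putamen_left)$data,
                   masks$anat_putamen_right$data)
  expect_identical(flip_lr(masks$head_mask)$data, masks$head_mask$data)

  # anatomical masks nest inside the HV masks
  expect_equal(sum(masks$anat_putamen_left$data *
                     (1 - masks$hv_putamen_left$data)), 0)
})

test_that("sample_subject draws the stated mixture", {
  set.seed(21)
  all_norm <- replicate(20, sample_subject(cohort_mixture(p_reduced = 0))$category)
  expect_true(all(all_norm == "normal"))

  mix <- cohort_mixture()
  set.seed(22)
  n <- 1e5
  truths <- replicate(n, {
    s <- sample_subject(mix)
    c(red = s$category == "reduced", minsbr = min(s$sbr_putamen))
  })
  red <- truths["red", ] == 1
  # category-wise means within 3 SE of the generating Gaussians
  expect_lt(abs(mean(truths["minsbr", red]) - mix$m_reduced),
            3 * mix$sd_reduced / sqrt(sum(red)))
  expect_lt(abs(mean(truths["minsbr", !red]) - mix$m_normal),
            3 * mix$sd_normal / sqrt(sum(!red)))
  # reduced fraction within 3 binomial SE at the cohort scale
  n2 <- 1702
  frac <- mean(red[seq_len(n2)])
  expect_lt(abs(frac - mix$p_reduced),
            3 * sqrt(mix$p_reduced * (1 - mix$p_reduced) / n2))

  # zero asymmetry: equal hemispheres
  set.seed(23)
  s <- sample_subject(cohort_mixture(asym_reduced = 0, asym_normal = 0))
  expect_equal(unname(diff(s$sbr_putamen)), 0)
  # worse side is the minimum; caudate never below putamen
  set.seed(24)
  for (i in 1:20) {
    s <- sample_subject(mix)
    expect_equal(unname(s$sbr_putamen[s$worse_side]), min(s$sbr_putamen))
    expect_true(all(s$sbr_caudate >= s$sbr_putamen))
    expect_true(all(s$dvr_putamen > 0))
  }
  expect_error(cohort_mixture(p_reduced = 1.4), "p_reduced")
})

test_that("degenerate forward model reproduces the painted image and truth exactly", {
  spec <- fix$spec
  tr <- proto_truth(0.62, asym = 0.2, category = "reduced", worse = "left")
  tr$true_affine <- affine12()
  sim <- simulate_scan(spec, tr, native = datspect:::template_grid(spec),
                       noise_sd = 0, psf_fwhm_mm = 0, intensity_scale = 1)
  painted <- paint_subject(spec, tr)
  expect_equal(sim$scan$data, painted$data, tolerance = 1e-12)

  # full pipeline at a known transform recovers the painted SBR exactly
  rec <- quantify_scan(sim$scan, fix$templates, fix$masks, "single",
                       transform = affine12())
  hv <- rec[rec$roi_method == "HV", ]
  expect_equal(hv$sbr_left, unname(tr$sbr_putamen["left"]), tolerance = 1e-9)
  expect_equal(hv$sbr_min, min(tr$sbr_putamen), tolerance = 1e-9)
  expect_equal(hv$sbr_min, hv$sbr_left)  # worse side left by construction
})

test_that("PSF-blurred hottest-voxels SBR stays within 15% of painted truth", {
  spec <- fix$spec
  tr <- proto_truth(1.7)
  tr$true_affine <- affine12()
  sim <- simulate_scan(spec, tr, native = datspect:::template_grid(spec),
                       noise_sd = 0, intensity_scale = 1)  # PSF on (7 mm)
  rec <- quantify_scan(sim$scan, fix$templates, fix$masks, "single",
                       transform = affine12())
  hv <- rec[rec$roi_method == "HV", ]
  expect_lt(abs(hv$sbr_min - 1.7) / 1.7, 0.15)
  expect_equal(hv$sbr_left, hv$sbr_right, tolerance = 0.02)
})

test_that("global intensity scale does not change the quantification", {
  spec <- fix$spec
  tr <- proto_truth(1.2)
  tr$true_affine <- affine12()
  set.seed(31)
  s1 <- simulate_scan(spec, tr, noise_sd = 0, intensity_scale = 1)
  scan2 <- s1$scan
  scan2$data <- scan2$data * 3
  r1 <- quantify_scan(s1$scan, fix$templates, fix$masks, "single",
                      transform = affine12())
  r2 <- quantify_scan(scan2, fix$templates, fix$masks, "single",
                      transform = affine12())
  expect_equal(r1$sbr_min, r2$sbr_min, tolerance = 1e-12)
  expect_equal(r1$sbr_mean, r2$sbr_mean, tolerance = 1e-12)
})

test_that("simulate_cohort is reproducible and validates n", {
  spec <- fix$spec
  a <- simulate_cohort(spec, 2, seed = 77)
  b <- simulate_cohort(spec, 2, seed = 77)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$scans[[1]]$data, b$scans[[1]]$data)
  expect_identical(a$scans[[2]]$data, b$scans[[2]]$data)
  expect_equal(det_of(a$truths[[1]]$true_affine), a$manifest$true_det[1],
               tolerance = 1e-12)
  expect_error(simulate_cohort(spec, 0), "n")
})

test_that("painted template set has the stated structure", {
  tset <- fix$templates
  expect_length(tset, 8)
  # normal templates are exactly symmetric
  expect_identical(flip_lr(tset$templates[[1]])$data, tset$templates[[1]]$data)
  expect_identical(flip_lr(tset$templates[[5]])$data, tset$templates[[5]]$data)
  # moderate left is the exact mirror of moderate right
  expect_identical(tset$templates[[3]]$data, flip_lr(tset$templates[[2]])$data)
  # putamen SBR ordering: normal > moderate > strong (via HV on each template)
  sbr_of <- function(i) hottest_voxels_sbr(tset$templates[[i]],
                                           fix$masks$hv_putamen_left)
  expect_gt(sbr_of(1), sbr_of(2))
  expect_gt(sbr_of(2), sbr_of(4))
  # scalp variants are strictly brighter in the scalp shell
  expect_gt(max(tset$templates[[5]]$data - tset$templates[[1]]$data), 0.1)
})
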