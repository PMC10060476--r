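test_that("source_cube_mask covers the stated cube around the center of mass", {
  g <- vol3d(array(0, c(21, 21, 21)), voxel_size = c(2, 2, 2))
  g$data[11, 11, 11] <- 5  # world origin
  m <- source_cube_mask(g, edge_mm = 20)
  w <- datspect:::grid_world(g)
  inside <- abs(w[1, ]) <= 10 & abs(w[2, ]) <= 10 & abs(w[3, ]) <= 10
  expect_identical(as.numeric(m$data), as.numeric(inside))

  # uniform image on a small grid: cube of 200 mm covers the whole grid
  u <- vol3d(array(1, c(10, 10, 10)), voxel_size = c(2, 2, 2))
  expect_true(all(source_cube_mask(u, 200)$data == 1))

  # two equal point masses: cube centered at their midpoint
  g2 <- vol3d(array(0, c(31, 11, 11)), voxel_size = c(2, 2, 2))
  g2$data[6, 6, 6] <- 1    # world x = -20
  g2$data[26, 6, 6] <- 1   # world x = +20
  m2 <- source_cube_mask(g2, edge_mm = 20)
  w2 <- datspect:::grid_world(g2)
  expect_identical(as.numeric(m2$data),
                   as.numeric(abs(w2[1, ]) <= 10 & abs(w2[2, ]) <= 10 &
                                abs(w2[3, ]) <= 10))

  z <- u
  z$data[] <- 0
  expect_error(source_cube_mask(z), "all-zero")
})

test_that("self-registration of a template is close to identity", {
  tmpl <- fix$templates$templates[[1]]
  scan <- tmpl
  scan$space <- "native"
  res <- normalize_scan(scan, template_set(list(tmpl)), fix$masks$head_mask)
  expect_lt(max(abs(res$transform$translation)), 0.5)
  expect_lt(max(abs(res$transform$zoom - 1)), 0.01)
  expect_equal(res$beta[1] / sum(res$beta), 1, tolerance = 0.1)
  expect_true(res$converged)
  # cost is non-increasing within every accepted level
  expect_true(all(res$cost_trace[, "cost_final"] <=
                    res$cost_trace[, "cost_initial"] + 1e-12))
})

test_that("translation equivariance: shifting the scan shifts the recovered translation", {
  spec <- fix$spec
  tr <- proto_truth(1.5)
  single <- template_set(fix$templates$templates[1])
  t_extra <- c(4, -6, 2)
  res <- list()
  for (k in 1:2) {
    tr$true_affine <- affine12(translation = c(2, 1, -3) +
                                 if (k == 2) t_extra else c(0, 0, 0))
    sim <- simulate_scan(spec, tr, noise_sd = 0, intensity_scale = 1)
    res[[k]] <- normalize_scan(sim$scan, single, fix$masks$head_mask)
  }
  shift <- res[[2]]$transform$translation - res[[1]]$transform$translation
  expect_lt(max(abs(shift - t_extra)), 2.5)  # within one native voxel
  expect_lt(abs(res[[2]]$det / res[[1]]$det - 1), 0.01)
})

test_that("multi-template coefficients concentrate on the generating template", {
  # linearly independent subset (with-ACSC templates); the full painted
  # 8-set shares one scalp-shell basis function, so only the fitted image,
  # not individual coefficients, is identifiable there
  spec <- fix$spec
  t4 <- template_set(fix$templates$templates[1:4], fix$templates$labels[1:4])
  A <- affine12(translation = c(3, -4, 2), rotation = c(0.05, -0.03, 0.08),
                zoom = c(0.97, 1.03, 1.01))
  native <- datspect:::native_grid(spec)
  scan <- resample(t4$templates[[2]], solve(as_matrix4(A)),
                   target = native, space = "native")
  res <- normalize_scan(scan, t4, fix$masks$head_mask)
  b <- res$beta
  expect_equal(which.max(abs(b)), 2L)
  expect_gte(abs(b[2]), 5 * max(abs(b[-2])))
  expect_lt(abs(res$det - det_of(A)) / det_of(A), 0.02)
})

test_that("degenerate weight masks are rejected", {
  tiny <- fix$masks$head_mask
  tiny$data[] <- 0
  tiny$data[1:5] <- 1
  scan <- fix$templates$templates[[1]]
  scan$space <- "native"
  expect_error(normalize_scan(scan, template_set(fix$templates$templates[1]),
                              tiny),
               "degenerate weight mask")
})
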