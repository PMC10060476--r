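test_that("histogram_sbr bins half-open at width 0.1 anchored at zero", {
  h <- histogram_sbr(c(0.05, 0.05, 0.15))
  expect_equal(h$centers, c(0.05, 0.15))
  expect_equal(h$counts, c(2L, 1L))

  set.seed(61)
  v <- rnorm(5000, 0.8, 0.4)
  h <- histogram_sbr(v)
  expect_equal(sum(h$counts), length(v))   # conservation
  expect_true(any(h$centers < 0))          # negative-k bins exist

  v <- rnorm(1e4, 1, 0.3)
  h <- histogram_sbr(v)
  expect_lt(abs(h$centers[which.max(h$counts)] - 1), 0.1 + 1e-9)

  expect_error(histogram_sbr(numeric(0)), "no finite")
})

test_that("fit_two_gaussians inverts exact model histograms", {
  p <- c(A1 = 50, M1 = 0.6, SD1 = 0.18, A2 = 40, M2 = 1.7, SD2 = 0.36)
  x <- seq(0.05, 3.05, 0.1)
  counts <- p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) +
    p[4] * exp(-(x - p[5])^2 / (2 * p[6]^2))
  fit <- fit_two_gaussians(x, counts)
  expect_equal(unname(coef(fit)), unname(p), tolerance = 1e-3)
  expect_lt(fit$sse, 1e-6 * sum(counts^2))
  expect_true(fit$converged)
  expect_lte(fit$M1, fit$M2)
  expect_gt(fit$SD1, 0)
  # cutoff sits strictly between the means
  expect_gt(fit$c, fit$M1)
  expect_lt(fit$c, fit$M2)
  # predict/residuals are consistent with the fitted curve
  expect_equal(predict(fit) + residuals(fit), counts, tolerance = 1e-12)
})

test_that("single-component histograms leave the second amplitude negligible", {
  x <- seq(0.05, 3.05, 0.1)
  counts <- 80 * exp(-(x - 1.2)^2 / (2 * 0.3^2))
  fit <- fit_two_gaussians(x, counts)
  expect_true(!fit$converged || fit$single_component)
  # a clean two-component histogram is NOT flagged
  good <- 50 * exp(-(x - 0.6)^2 / (2 * 0.18^2)) +
    40 * exp(-(x - 1.7)^2 / (2 * 0.36^2))
  expect_false(fit_two_gaussians(x, good)$single_component)
})

test_that("effect size and cutoff formulas, including shift behavior", {
  expect_equal(effect_size(0, 1, 1, 1), 1.0)
  expect_equal(cutoff(0.5, 0.2, 1.5, 0.2), 1.0)   # equal SDs: midpoint
  expect_equal(cutoff(0.7, 0.1, 0.7, 0.5), 0.7)   # equal means
  expect_equal(cutoff(0.63, 0.18, 1.72, 0.36), 0.99333, tolerance = 1e-4)

  # common shift: d invariant, cutoff shifts by the same amount (exact)
  s <- 0.37
  expect_equal(effect_size(0.6 + s, 0.18, 1.7 + s, 0.36),
               effect_size(0.6, 0.18, 1.7, 0.36), tolerance = 1e-12)
  expect_equal(cutoff(0.6 + s, 0.18, 1.7 + s, 0.36),
               cutoff(0.6, 0.18, 1.7, 0.36) + s, tolerance = 1e-12)
})

test_that("classify uses the pinned at-cutoff-is-normal rule", {
  expect_identical(classify(c(0.9, 1.1, 1.0), 1),
                   c("reduced", "normal", "normal"))
})

test_that("subsample_stability: degenerate full-fraction case and determinism", {
  set.seed(62)
  v <- c(rnorm(300, 0.6, 0.15), rnorm(350, 1.6, 0.3))
  st <- subsample_stability(v, n_rep = 5, frac = 1.0, seed = 1)
  expect_equal(st$sd_d, 0)
  expect_equal(st$cov, 0)

  a <- subsample_stability(v, n_rep = 10, seed = 99)
  b <- subsample_stability(v, n_rep = 10, seed = 99)
  expect_identical(a$d, b$d)
  expect_error(subsample_stability(rnorm(20), n_rep = 5), "below 50")
})

test_that("cross_tab and Cohen's kappa reproduce the printed agreement table", {
  lab <- c(rep("normal", 5), rep("reduced", 5))
  ct <- cross_tab(lab, lab)
  expect_equal(ct$counts[1, 2] + ct$counts[2, 1], 0)
  expect_equal(ct$concordance, 1)
  expect_equal(cohens_kappa(ct$counts)$kappa, 1)

  # published cross-table: rows multiple templates, columns single template
  counts <- matrix(c(930, 29, 8, 735), 2, 2,
                   dimnames = list(c("normal", "reduced"),
                                   c("normal", "reduced")))
  expect_equal(round(counts / sum(counts) * 100, 1),
               matrix(c(54.6, 1.7, 0.5, 43.2), 2, 2,
                      dimnames = dimnames(counts)))
  k <- cohens_kappa(counts)
  expect_equal(round(k$kappa, 3), 0.956)
  expect_equal(round(k$se, 3), 0.007)

  # independence table gives kappa 0
  ind <- matrix(c(40, 60, 40, 60), 2, 2)
  expect_equal(cohens_kappa(ind)$kappa, 0, tolerance = 1e-12)
  expect_error(cross_tab(lab, lab[-1]), "length")
})

test_that("regress: slopes, standardized betas, null behavior", {
  x <- seq(1, 10, length.out = 50)
  r <- suppressWarnings(regress(2 * x, x, with_constant = FALSE))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$beta, 1, tolerance = 1e-12)
  expect_lt(r$p, 1e-10)

  r <- suppressWarnings(regress(x + 1, x, with_constant = TRUE))
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-10)

  set.seed(63)
  xs <- rnorm(1e4)
  ys <- rnorm(1e4)
  r <- regress(ys, xs)
  expect_lt(abs(r$beta), 0.05)
  expect_error(regress(ys, rep(1, 1e4)), "constant")
})
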