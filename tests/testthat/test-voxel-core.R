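test_that("resample: identity, constants, and single-voxel translation", {
  img <- rand_vol(c(9, 8, 7), seed = 3)

  out <- resample(img, xf = NULL, target = img)
  expect_equal(out$data, img$data, tolerance = 1e-12)

  # constant image stays constant inside the mapped extent
  cimg <- img
  cimg$data[] <- 5
  xf <- affine12(translation = c(1.2, -0.7, 0.4),
                 rotation = c(0.03, -0.02, 0.05), zoom = c(1.02, 0.98, 1.01))
  small <- vol3d(array(0, c(3, 3, 3)), voxel_size = c(2, 2, 2))
  out <- resample(cimg, xf, target = small)
  expect_equal(out$data, array(5, c(3, 3, 3)), tolerance = 1e-6)

  # one-voxel-pitch translation moves a bright voxel to its neighbor
  bright <- vol3d(array(0, c(5, 5, 5)), voxel_size = c(2, 2, 2))
  bright$data[3, 3, 3] <- 7
  out <- resample(bright, affine12(translation = c(0, 2, 0)), target = bright)
  expect_equal(out$data[3, 4, 3], 7, tolerance = 1e-9)
  expect_equal(sum(out$data > 1e-9), 1L)

  expect_error(resample(img, matrix(0, 4, 4), target = img),
               "non-invertible")
})

test_that("resample round-trip through an affine and back is near-lossless on smooth images", {
  # 7 mm smoothed noise, sampled finely enough (1.5 mm) that two trilinear
  # passes stay within the interpolation tolerance
  img <- gaussian_smooth(rand_vol(c(40, 40, 36), voxel = 1, seed = 9), 7)
  xf <- affine12(translation = c(3, -2, 1.5), rotation = c(0.05, 0.04, -0.06),
                 zoom = c(1.05, 0.97, 1.02), shear = c(0.02, -0.01, 0.015))
  fwd <- resample(img, xf, target = img)
  back <- resample(fwd, solve(as_matrix4(xf)), target = img)
  core1 <- 11:30
  err <- max(abs(back$data[core1, core1, 11:26] -
                   img$data[core1, core1, 11:26]))
  expect_lt(err, 0.02 * diff(range(img$data)))
})

test_that("flip_lr mirrors indices, preserves values, and is an involution", {
  img <- rand_vol(c(8, 7, 6), seed = 4)
  f <- flip_lr(img)
  expect_identical(flip_lr(f)$data, img$data)
  expect_identical(sort(as.numeric(f$data)), sort(as.numeric(img$data)))
  d <- dim(img$data)
  expect_identical(f$data[2, 3, 4], img$data[d[1] - 1, 3, 4])

  sym <- img
  sym$data <- img$data + flip_lr(img)$data
  expect_identical(flip_lr(sym)$data, sym$data)

  expect_error(flip_lr(img, axis = 4), "axis")
})

test_that("gaussian_smooth: zero fwhm, DC preservation, impulse response", {
  img <- rand_vol(c(10, 9, 8), seed = 5)
  expect_identical(gaussian_smooth(img, 0)$data, img$data)

  cimg <- img
  cimg$data[] <- 3.7
  expect_equal(gaussian_smooth(cimg, c(7, 5, 9))$data, cimg$data,
               tolerance = 1e-12)

  # unit impulse: center value equals the product of the three normalized
  # 1D kernel centers (independent kernel computation)
  imp <- vol3d(array(0, c(15, 15, 15)), voxel_size = c(2, 2, 2))
  imp$data[8, 8, 8] <- 1
  sm <- gaussian_smooth(imp, 7)
  sigma <- 7 / (2 * sqrt(2 * log(2))) / 2
  r <- ceiling(3.5 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  expect_equal(sm$data[8, 8, 8], k[r + 1]^3, tolerance = 1e-12)

  expect_error(gaussian_smooth(img, -1), "fwhm")
})

test_that("masked_percentile interpolates order statistics and matches a sort oracle", {
  g <- vol3d(array(c(1, 2, 3, 4, 99, 99, 99, 99), c(2, 2, 2)))
  m <- vol3d(array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2)))
  expect_equal(masked_percentile(g, m, 0.75), 3.25)
  expect_equal(masked_percentile(g, m, 1), 4)

  cimg <- g
  cimg$data[] <- 2.5
  expect_equal(masked_percentile(cimg, m, 0.33), 2.5)

  # brute-force oracle: q-quantile by linear interpolation of the full sort
  oracle <- function(v, q) {
    v <- sort(v)
    h <- (length(v) - 1) * q
    lo <- floor(h) + 1
    v[lo] + (h - floor(h)) * (v[min(lo + 1, length(v))] - v[lo])
  }
  for (seed in 1:5) {
    img <- rand_vol(c(17, 13, 11), seed = seed)
    set.seed(seed + 100)
    msk <- img
    msk$data <- array(rbinom(prod(dim(img$data)), 1, 0.3), dim(img$data))
    q <- runif(1)
    expect_equal(masked_percentile(img, msk, q),
                 oracle(img$data[msk$data > 0], q), tolerance = 1e-12)
  }

  empty <- m
  empty$data[] <- 0
  expect_error(masked_percentile(g, empty, 0.5), "empty")
})

test_that("soft_mean averages voxelwise", {
  img <- rand_vol(c(6, 5, 4), seed = 6)
  expect_identical(soft_mean(list(img))$data, img$data)

  neg <- img
  neg$data <- -img$data
  expect_equal(soft_mean(list(img, neg))$data,
               array(0, dim(img$data)), tolerance = 1e-15)

  consts <- lapply(1:12, function(v) {
    x <- img
    x$data[] <- v
    x
  })
  expect_equal(unique(as.numeric(soft_mean(consts)$data)), 6.5)

  other <- rand_vol(c(6, 5, 5), seed = 7)
  expect_error(soft_mean(list(img, other)), "grid")
})

test_that("vol3d validates its invariants", {
  expect_error(vol3d(array(c(1, NA), c(2, 1, 1))), "finite")
  expect_error(vol3d(array(1, c(2, 2, 2)), voxel_size = c(2, 0, 2)),
               "positive")
  expect_error(vol3d(matrix(1, 2, 2)), "3D")
  v <- vol3d(array(1, c(4, 4, 4)), voxel_size = c(2, 3, 4))
  expect_equal(voxel_volume(v), 24)
  # centered default affine: world origin at the grid center
  ctr <- (dim(v$data) - 1) / 2
  expect_equal(as.numeric(v$v2w %*% c(ctr, 1))[1:3], c(0, 0, 0))
})
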