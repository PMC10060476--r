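#' Binary source-weighting cube
#'
#' The axis-aligned cube of given edge length centered at the
#' intensity-weighted center of mass of the image, in world coordinates.
#' Used to restrict the registration cost to the head region of the native
#' scan.
#'
#' @param img native `vol3d` with positive total intensity.
#' @param edge_mm cube edge length, mm.
#' @return Binary `vol3d` on the grid of `img`.
#' @export
source_cube_mask <- function(img, edge_mm = 200) {
  com <- center_of_mass(img)
  w <- grid_world(img)
  sel <- abs(w[1, ] - com[1]) <= edge_mm / 2 &
    abs(w[2, ] - com[2]) <= edge_mm / 2 &
    abs(w[3, ] - com[3]) <= edge_mm / 2
  as_mask_vol(sel, img)
}

# intensity-weighted center of mass in world coordinates
center_of_mass <- function(img) {
  tot <- sum(img$data)
  if (tot <= 0) stop("all-zero image: center of mass undefined")
  w <- grid_world(img)
  as.numeric(w %*% as.numeric(img$data)) / tot
}

#' Options for stereotactical normalization
#'
#' @param pyramid_fwhm extra smoothing (mm) applied to scan and templates
#'   at each coarse-to-fine level.
#' @param stride template-grid subsampling factor per level (cost is
#'   evaluated on every `stride`-th in-mask voxel).
#' @param maxit optimizer iteration budget per level.
#' @param method optimizer per level: `"NM"` (Nelder-Mead; robust far from
#'   the optimum) or `"BFGS"` (finite-difference quasi-Newton; sharp local
#'   convergence of the 12-parameter problem, which a simplex alone
#'   finishes poorly).
#' @param rigid_first optimize the 6 rigid parameters alone before the
#'   full 12 at the coarsest level.
#' @param rigid_maxit iteration budget of the rigid stage.
#' @param lambda weight of the quadratic zoom/shear regularization
#'   `lambda * (sum(log(zoom)^2) + sum(shear^2))` (the analogue of
#'   template-space regularization; keeps the affine near-orthogonal when
#'   the data are uninformative, and vanishes at identity so
#'   self-registration is unbiased).
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param restarts additional optimizer restarts at the last Nelder-Mead
#'   level (a fresh simplex escapes stagnation).
#' @param interp_fwhm extra smoothing (mm) applied to the templates only,
#'   in quadrature with the pyramid level, compensating the smoothing that
#'   trilinear interpolation applies to the resampled scan (which would
#'   otherwise bias the zooms). `NULL`: derived from the scan voxel size
#'   as `2.355 * voxel / sqrt(6)`, the average interpolation blur.
#' @return List of options.
#' @export
normalize_opts <- function(pyramid_fwhm = c(8, 4, 0),
                           stride = c(2, 2, 2),
                           maxit = c(400, 300, 80),
                           method = c("NM", "NM", "BFGS"),
                           rigid_first = TRUE,
                           rigid_maxit = 300, lambda = 0.005,
                           reltol = 1e-9, restarts = 1,
                           interp_fwhm = NULL) {
  list(pyramid_fwhm = pyramid_fwhm, stride = stride, maxit = maxit,
       method = method, rigid_first = rigid_first,
       rigid_maxit = rigid_maxit, lambda = lambda, reltol = reltol,
       restarts = restarts, interp_fwhm = interp_fwhm)
}

# weighted LS coefficients with a minimal Tikhonov term; template sets whose
# columns are (near-)collinear -- e.g. scalp variants sharing one shell --
# would otherwise make the normal equations singular
ridge_solve <- function(X, y, eps = 1e-8) {
  XtX <- crossprod(X)
  solve(XtX + eps * mean(diag(XtX)) * diag(ncol(X)), crossprod(X, y))
}

# strided logical subsample of TRUE positions in a 3D logical array
strided_which <- function(sel, d, stride) {
  if (stride > 1) {
    keep <- array(FALSE, d)
    keep[seq(1, d[1], stride), seq(1, d[2], stride), seq(1, d[3], stride)] <- TRUE
    sel <- sel & keep
  }
  which(sel)
}

#' Affine stereotactical normalization to template space
#'
#' Finds the 12-parameter affine mapping a native scan into template space
#' by minimizing the head-masked sum of squared residuals between the
#' transformed scan and the best linear combination of the template(s)
#' (single template: one coefficient plus intercept). The template
#' coefficients are solved in closed form by weighted linear least squares
#' at every cost evaluation; the affine parameters are optimized by
#' Nelder-Mead over a coarse-to-fine smoothing pyramid, starting from
#' center-of-mass alignment with unit zooms. Zooms and shears are
#' penalized quadratically toward identity (see [normalize_opts()]).
#'
#' The residual weight is the product of the template-space head mask and
#' the source cube of 200 mm edge centered at the scan's center of mass
#' mapped to template space.
#'
#' @param img native `vol3d` scan.
#' @param templates a [template_set] or a single template `vol3d`.
#' @param head_mask binary template-space weighting mask.
#' @param source_edge_mm edge of the source weighting cube, mm.
#' @param opts options from [normalize_opts()].
#' @return An object of class `normalization_result`: `transform`
#'   ([affine12]), `beta` (template coefficients), `intercept`, `det`,
#'   `normalized` (the scan resampled onto the template grid), `cost_trace`
#'   (per-level initial/final cost and evaluation counts) and `converged`.
#' @export
normalize_scan <- function(img, templates, head_mask, source_edge_mm = 200,
                           opts = normalize_opts()) {
  if (inherits(templates, "vol3d")) templates <- template_set(list(templates))
  stopifnot(inherits(templates, "template_set"))
  tgrid <- templates$templates[[1]]
  stopifnot_same_grid(tgrid, head_mask)
  K <- length(templates$templates)
  d_t <- dim(tgrid$data)
  sel <- head_mask$data > 0

  com <- center_of_mass(img)
  # center of mass of the first template under the head mask, as the
  # translation initializer target
  t1 <- templates$templates[[1]]
  wt <- t1$data * head_mask$data
  com_t <- as.numeric(grid_world(t1) %*% as.numeric(wt)) / sum(wt)
  theta <- affine_to_par(affine12(translation = com_t - com))

  # scan intensities on a common scale so the regularization weight is
  # meaningful across scans (beta absorbs the true scale)
  scale0 <- mean(img$data[img$data > 0.05 * max(img$data)])
  img0 <- img
  img0$data <- img$data / scale0

  v2w_img_inv <- solve(img0$v2w)
  d_s <- dim(img0$data)
  half <- source_edge_mm / 2

  interp_fwhm <- if (is.null(opts$interp_fwhm))
    2.355 * mean(img$voxel_size) / sqrt(6) else opts$interp_fwhm

  trace <- list()
  converged <- TRUE
  nlev <- length(opts$pyramid_fwhm)
  for (lev in seq_len(nlev)) {
    fw <- opts$pyramid_fwhm[lev]
    fw_t <- sqrt(fw^2 + interp_fwhm^2)
    scan_sm <- if (fw > 0) gaussian_smooth(img0, fw) else img0
    tmpl_sm <- lapply(templates$templates,
                      function(t) if (fw_t > 0) gaussian_smooth(t, fw_t) else t)
    idx <- strided_which(sel, d_t, opts$stride[lev])
    if (length(idx) < 13 + K)
      stop("degenerate weight mask: fewer in-mask voxels than parameters")
    P <- index_grid_hom(d_t)[, idx, drop = FALSE]
    Wld <- tgrid$v2w %*% P            # template world coords, 4 x n
    B <- cbind(vapply(tmpl_sm, function(t) as.numeric(t$data)[idx],
                      numeric(length(idx))), 1)
    arr <- as.numeric(scan_sm$data)
    denom <- sum((B[, 1] - mean(B[, 1]))^2)

    cost <- function(p, rigid = FALSE) {
      if (rigid) p <- c(p, rep(0, 6))
      M <- as_matrix4(par_to_affine(p))
      Minv <- solve(M)
      wn <- Minv %*% Wld              # native world coords of mask voxels
      pts <- (v2w_img_inv %*% wn)[1:3, , drop = FALSE]
      inside <- abs(wn[1, ] - com[1]) <= half &
        abs(wn[2, ] - com[2]) <= half & abs(wn[3, ] - com[3]) <= half
      if (sum(inside) < 13 + K) return(1e6)
      v <- cpp_trilinear(arr, d_s, pts)
      Bi <- B[inside, , drop = FALSE]
      vi <- v[inside]
      beta <- tryCatch(ridge_solve(Bi, vi), error = function(e) NULL)
      if (is.null(beta)) return(1e6)
      ss <- sum((vi - Bi %*% beta)^2)
      ss / denom + opts$lambda * (sum(p[7:9]^2) + sum(p[10:12]^2))
    }

    pscale <- c(rep(5, 3), rep(0.05, 3), rep(0.03, 3), rep(0.03, 3))
    if (lev == 1 && opts$rigid_first) {
      fit_r <- stats::optim(theta[1:6], cost, rigid = TRUE,
                            method = "Nelder-Mead",
                            control = list(maxit = opts$rigid_maxit,
                                           reltol = opts$reltol,
                                           parscale = pscale[1:6]))
      theta[1:6] <- fit_r$par
    }
    meth <- opts$method[lev]
    last_nm <- meth == "NM" &&
      (lev == nlev || opts$method[min(lev + 1, nlev)] != "NM")
    c0 <- cost(theta)
    best <- c0
    nrun <- 1L + if (last_nm) opts$restarts else 0L
    evals <- 0L
    for (run in seq_len(nrun)) {
      fit <- stats::optim(theta, cost,
                          method = if (meth == "NM") "Nelder-Mead" else "BFGS",
                          control = list(maxit = opts$maxit[lev],
                                         reltol = opts$reltol,
                                         parscale = pscale))
      evals <- evals + unname(fit$counts[1])
      if (fit$value <= best) {
        theta <- fit$par
        best <- fit$value
      }
      if (lev == nlev) converged <- fit$convergence == 0 || fit$value < c0
    }
    trace[[lev]] <- c(level = lev, fwhm = fw, cost_initial = c0,
                      cost_final = best, evaluations = evals)
  }

  xf <- par_to_affine(theta)
  M <- as_matrix4(xf)
  # final coefficients at full resolution, no extra smoothing
  idx <- strided_which(sel, d_t, 1L)
  P <- index_grid_hom(d_t)[, idx, drop = FALSE]
  Wld <- tgrid$v2w %*% P
  wn <- solve(M) %*% Wld
  pts <- (v2w_img_inv %*% wn)[1:3, , drop = FALSE]
  inside <- abs(wn[1, ] - com[1]) <= half & abs(wn[2, ] - com[2]) <= half &
    abs(wn[3, ] - com[3]) <= half
  B <- cbind(vapply(templates$templates,
                    function(t) as.numeric(gaussian_smooth(t, interp_fwhm)$data)[idx],
                    numeric(length(idx))), 1)[inside, , drop = FALSE]
  v <- cpp_trilinear(as.numeric(img0$data), d_s, pts)[inside]
  beta_full <- as.numeric(ridge_solve(B, v))

  normalized <- resample(img, xf = M, target = tgrid, space = "template")
  structure(list(transform = xf, beta = beta_full[seq_len(K)],
                 intercept = beta_full[K + 1], det = det_of(xf),
                 normalized = normalized,
                 cost_trace = do.call(rbind, trace),
                 converged = converged),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat("<normalization_result>\n")
  print(x$transform)
  cat(sprintf("  template coefficients: %s\n",
              paste(sprintf("%.3f", x$beta), collapse = " ")))
  cat(sprintf("  converged: %s, final cost: %.6g\n", x$converged,
              x$cost_trace[nrow(x$cost_trace), "cost_final"]))
  invisible(x)
}
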