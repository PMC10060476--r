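#' Histogram of cohort SBR values
#'
#' Bins SBR values into half-open bins `[k*w, (k+1)*w)` of width `w`
#' anchored at 0 (negative values fall into negative-`k` bins). Returns
#' the contiguous run of bins from the smallest to the largest occupied
#' bin, including empty bins in between.
#'
#' @param values numeric SBR values.
#' @param bin_width bin width (default 0.1).
#' @return List with `centers`, `counts` and `bin_width`.
#' @export
histogram_sbr <- function(values, bin_width = 0.1) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to bin")
  k <- floor(values / bin_width)
  kr <- min(k):max(k)
  counts <- as.integer(tabulate(k - min(k) + 1L, nbins = length(kr)))
  list(centers = (kr + 0.5) * bin_width, counts = counts,
       bin_width = bin_width)
}

gauss2_model <- function(p, x) {
  p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) +
    p[4] * exp(-(x - p[5])^2 / (2 * p[6]^2))
}

#' Fit the sum of two Gaussians to an SBR histogram
#'
#' Models the histogram counts as
#' `A1 exp(-(x - M1)^2 / (2 SD1^2)) + A2 exp(-(x - M2)^2 / (2 SD2^2))`
#' and minimizes the sum of squared deviations over the six parameters by
#' Nelder-Mead (the `fminsearch` idiom), with the SDs forced positive via
#' their absolute value inside the model. Components are relabeled after
#' the fit so that `M1 <= M2` (component 1 = reduced uptake). Initial
#' values default to the two largest local maxima of the histogram with
#' SD 0.2, plus a small grid of fallback starts; the best SSE wins.
#'
#' @param centers,counts histogram as from [histogram_sbr()], or a list
#'   with those elements passed as `centers`.
#' @param init optional starting vector `c(A1, M1, SD1, A2, M2, SD2)`.
#' @param bin_width recorded in the result (taken from a list input when
#'   available).
#' @return An object of class `gauss2`: the six parameters, effect size
#'   `d`, cutoff `c`, `sse`, `converged`, a `single_component` flag (raised
#'   when the two-component model is not identifiable on the data), and the
#'   data it was fitted to. Methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `plot`.
#' @export
fit_two_gaussians <- function(centers, counts = NULL, init = NULL,
                              bin_width = NULL) {
  if (is.list(centers)) {
    if (is.null(bin_width)) bin_width <- centers$bin_width
    counts <- centers$counts
    centers <- centers$centers
  }
  stopifnot(length(centers) == length(counts))
  if (sum(counts > 0) < 6)
    stop("need at least 6 nonzero histogram bins")
  if (is.null(bin_width))
    bin_width <- if (length(centers) > 1) min(diff(centers)) else 0.1

  obj <- function(p) sum((counts - gauss2_model(abs_sd(p), centers))^2)
  abs_sd <- function(p) { p[c(3, 6)] <- abs(p[c(3, 6)]); p }

  starts <- list()
  if (!is.null(init)) starts <- list(as.numeric(init))
  # two largest local maxima of the histogram
  n <- length(counts)
  locmax <- which(counts >= c(-Inf, counts[-n]) &
                    counts >= c(counts[-1], -Inf) & counts > 0)
  if (length(locmax) >= 2) {
    top2 <- locmax[order(counts[locmax], decreasing = TRUE)][1:2]
    top2 <- sort(top2)
    starts <- c(starts, list(c(counts[top2[1]], centers[top2[1]], 0.2,
                               counts[top2[2]], centers[top2[2]], 0.2)))
  }
  # fallback: weighted quartile split
  cum <- cumsum(counts) / sum(counts)
  q <- function(f) centers[which(cum >= f)[1]]
  starts <- c(starts,
              list(c(max(counts), q(0.25), 0.2, max(counts), q(0.75), 0.2)),
              list(c(max(counts) / 2, q(0.10), 0.3, max(counts), q(0.60), 0.3)))

  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    # polish
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- abs_sd(best$par)
  if (p[5] < p[2]) p <- p[c(4, 5, 6, 1, 2, 3)]
  out <- list(A1 = p[1], M1 = p[2], SD1 = p[3],
              A2 = p[4], M2 = p[5], SD2 = p[6],
              d = effect_size(p[2], p[3], p[5], p[6]),
              c = cutoff(p[2], p[3], p[5], p[6]),
              bin_width = bin_width, sse = best$value,
              converged = best$convergence == 0,
              # two-component model not identifiable: one amplitude is
              # negligible, the components collapse onto each other, or one
              # mean sits outside the histogram support (ghost component)
              single_component =
                min(abs(p[1]), abs(p[4])) < 0.05 * max(abs(p[1]), abs(p[4])) ||
                abs(p[5] - p[2]) < 0.5 * max(p[3], p[6]) ||
                p[2] < min(centers) - 2 * p[3] ||
                p[2] > max(centers) + 2 * p[3] ||
                p[5] < min(centers) - 2 * p[6] ||
                p[5] > max(centers) + 2 * p[6],
              centers = centers, counts = counts)
  class(out) <- "gauss2"
  out
}

#' Effect size of the separation between the two Gaussian components
#'
#' `d = (M2 - M1) / sqrt((SD1^2 + SD2^2) / 2)`: the distance between the
#' component means scaled to the pooled standard deviation.
#'
#' @param m1 either a `gauss2` fit or the mean of component 1.
#' @param sd1,m2,sd2 component parameters when `m1` is numeric.
#' @return Scalar effect size `d`.
#' @export
effect_size <- function(m1, sd1 = NULL, m2 = NULL, sd2 = NULL) {
  if (inherits(m1, "gauss2"))
    return(effect_size(m1$M1, m1$SD1, m1$M2, m1$SD2))
  (m2 - m1) / sqrt((sd1^2 + sd2^2) / 2)
}

#' SBR cutoff between the two Gaussian components
#'
#' `c = (SD2 * M1 + SD1 * M2) / (SD1 + SD2)`: the threshold halfway
#' between the component means in units of their standard deviations, used
#' to dichotomize SBR as normal or reduced.
#'
#' @inheritParams effect_size
#' @return Scalar cutoff `c` in SBR units.
#' @export
cutoff <- function(m1, sd1 = NULL, m2 = NULL, sd2 = NULL) {
  if (inherits(m1, "gauss2"))
    return(cutoff(m1$M1, m1$SD1, m1$M2, m1$SD2))
  (sd2 * m1 + sd1 * m2) / (sd1 + sd2)
}

#' Dichotomize SBR values at a cutoff
#'
#' Values below the cutoff are `"reduced"`, values at or above it are
#' `"normal"` (at-cutoff counts as normal).
#'
#' @param values numeric SBR values.
#' @param c cutoff, e.g. from [cutoff()].
#' @return Character vector of `"normal"` / `"reduced"`.
#' @export
classify <- function(values, c) {
  ifelse(values < c, "reduced", "normal")
}

#' @export
print.gauss2 <- function(x, ...) {
  cat("Two-Gaussian fit of the SBR histogram\n")
  cat(sprintf("  reduced : A1 = %8.3f  M1 = %6.3f  SD1 = %6.3f\n",
              x$A1, x$M1, x$SD1))
  cat(sprintf("  normal  : A2 = %8.3f  M2 = %6.3f  SD2 = %6.3f\n",
              x$A2, x$M2, x$SD2))
  cat(sprintf("  effect size d = %.3f, cutoff c = %.3f\n", x$d, x$c))
  cat(sprintf("  sse = %.4g, converged: %s\n", x$sse, x$converged))
  invisible(x)
}

#' @export
coef.gauss2 <- function(object, ...) {
  c(A1 = object$A1, M1 = object$M1, SD1 = object$SD1,
    A2 = object$A2, M2 = object$M2, SD2 = object$SD2)
}

#' @export
summary.gauss2 <- function(object, ...) {
  print(object)
  n <- sum(object$counts)
  cat(sprintf("  fitted on %d values in %d bins of width %.3g\n", n,
              length(object$counts), object$bin_width))
  invisible(object)
}

#' @export
predict.gauss2 <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$centers else newdata
  gauss2_model(unname(coef(object)), x)
}

#' @export
residuals.gauss2 <- function(object, ...) {
  object$counts - predict(object)
}

#' @export
plot.gauss2 <- function(x, ...) {
  graphics::plot(x$centers, x$counts, type = "h", lwd = 3, col = "grey60",
                 xlab = "putamen SBR", ylab = "count", ...)
  xs <- seq(min(x$centers), max(x$centers), length.out = 400)
  graphics::lines(xs, predict(x, xs), col = "firebrick", lwd = 2)
  graphics::abline(v = x$c, lty = 2)
  invisible(x)
}

#' Stability of the effect size over random subsamples
#'
#' Repeats the histogram / two-Gaussian fit / effect-size chain on
#' `n_rep` random subsamples each holding `frac` of the values (drawn
#' without replacement), and summarizes the spread of the effect-size
#' estimate.
#'
#' @param values cohort SBR values.
#' @param n_rep number of subsample replicates.
#' @param frac subsample fraction (0.9 = 90% subsamples).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param bin_width histogram bin width.
#' @return List with `mean_d`, `sd_d`, `cov` (= sd/mean), and the vector
#'   `d` of per-replicate effect sizes.
#' @export
subsample_stability <- function(values, n_rep = 1000, frac = 0.9, seed = 1,
                                bin_width = 0.1) {
  n <- length(values)
  m <- floor(frac * n)
  if (m < 50) stop("subsample size below 50")
  set.seed(seed)
  d <- rep(NA_real_, n_rep)
  fails <- 0L
  for (i in seq_len(n_rep)) {
    sub <- values[sample.int(n, m)]
    fit <- tryCatch(fit_two_gaussians(histogram_sbr(sub, bin_width)),
                    error = function(e) NULL)
    if (is.null(fit)) fails <- fails + 1L else d[i] <- fit$d
    if (fails > 0.05 * n_rep)
      stop("more than 5% of subsample fits failed")
  }
  d <- d[!is.na(d)]
  list(mean_d = mean(d), sd_d = stats::sd(d),
       cov = stats::sd(d) / mean(d), d = d)
}

#' Cross-table of two binary SBR classifications
#'
#' 2x2 counts of `"normal"` / `"reduced"` labels (rows: `labels_a`,
#' columns: `labels_b`) with cell percentages of the total and the
#' concordance fraction.
#'
#' @param labels_a,labels_b character vectors of `"normal"`/`"reduced"`.
#' @return List with `counts` (2x2 matrix), `percent` (2x2, % of total)
#'   and `concordance`.
#' @export
cross_tab <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  lv <- c("normal", "reduced")
  counts <- table(factor(labels_a, lv), factor(labels_b, lv))
  counts <- matrix(as.integer(counts), 2, 2, dimnames = dimnames(counts))
  total <- sum(counts)
  list(counts = counts, percent = counts / total * 100,
       concordance = sum(diag(counts)) / total)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginals; the standard error is the
#' large-sample formula `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`.
#'
#' @param counts 2x2 matrix of counts.
#' @return List with `kappa` and `se`.
#' @export
cohens_kappa <- function(counts) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  if (n <= 0) stop("empty table")
  po <- sum(diag(counts)) / n
  pe <- sum(rowSums(counts) * colSums(counts)) / n^2
  if (pe >= 1) stop("degenerate marginals: chance agreement is 1")
  list(kappa = (po - pe) / (1 - pe),
       se = sqrt(po * (1 - po) / (n * (1 - pe)^2)))
}

#' Linear regression of SBR on DET (and kin)
#'
#' Ordinary least squares of `y` on `x`, with or without an intercept.
#' The standardized coefficient is `slope * sd(x) / sd(y)` for the
#' with-constant model and `slope * sqrt(sum(x^2) / sum(y^2))` for the
#' through-origin model. The p-value is the two-sided t-test of the
#' slope.
#'
#' @param y,x numeric vectors.
#' @param with_constant include an intercept?
#' @return List with `slope`, `intercept` (`NA` when absent), `beta`
#'   (standardized), and `p`.
#' @export
regress <- function(y, x, with_constant = TRUE) {
  if (length(y) != length(x)) stop("length mismatch")
  if (length(y) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x is constant")
  fit <- if (with_constant) stats::lm(y ~ x) else stats::lm(y ~ 0 + x)
  sm <- summary(fit)$coefficients
  slope <- sm["x", "Estimate"]
  list(slope = slope,
       intercept = if (with_constant) sm["(Intercept)", "Estimate"] else NA_real_,
       beta = if (with_constant) slope * stats::sd(x) / stats::sd(y)
              else slope * sqrt(sum(x^2) / sum(y^2)),
       p = sm["x", "Pr(>|t|)"])
}
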