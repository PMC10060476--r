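#' Run configuration
#'
#' Assembles and validates the configuration of a full simulated
#' experiment. Any element can be overridden; defaults reproduce the
#' package's standard phantom world.
#'
#' @param n cohort size.
#' @param seed global seed; recorded in every artifact.
#' @param out_dir output directory (created if missing).
#' @param phantom list of [phantom_spec()] overrides.
#' @param mixture list of [cohort_mixture()] overrides.
#' @param scalp_frac fraction of scans with scalp signal.
#' @param registration list of [normalize_opts()] overrides.
#' @param volume_ml hottest-voxels volume, ml.
#' @param bin_width SBR histogram bin width.
#' @param n_subsample subsample-stability replicates (0 disables).
#' @param write_nifti write the simulated scans and masks as NIfTI files?
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(n = 60, seed = 1, out_dir = "datspect-run",
                       phantom = list(), mixture = list(),
                       scalp_frac = 0.3, registration = list(),
                       volume_ml = 10, bin_width = 0.1, n_subsample = 0,
                       write_nifti = FALSE) {
  cfg <- list(n = n, seed = seed, out_dir = out_dir,
              phantom = do.call(phantom_spec, phantom),
              mixture = do.call(cohort_mixture, mixture),
              scalp_frac = scalp_frac,
              registration = do.call(normalize_opts, registration),
              volume_ml = volume_ml, bin_width = bin_width,
              n_subsample = n_subsample, write_nifti = write_nifti)
  if (cfg$n < 1) stop("'n' must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a JSON file
#' @param path JSON file whose top-level keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                        auto_unbox = TRUE, digits = 10, force = TRUE)
  # small stable polynomial hash; avoids extra dependencies
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run a full simulated experiment
#'
#' Simulates a cohort from the phantom spec, paints the eight-template
#' set, quantifies every scan under single- and multi-template
#' normalization with both ROI methods, and computes the cohort
#' statistics: per-setting two-Gaussian histogram fits with effect size
#' and cutoff, the single-versus-multiple classification cross-table with
#' Cohen's kappa, SBR-versus-DET regressions per class, and the
#' DET-versus-DET through-origin regressions. Artifacts (manifest CSV,
#' results CSV, summary JSON) are written under `config$out_dir`, each
#' stamped with the seed and a config hash.
#'
#' @param config a [run_config()] (or list of its arguments).
#' @param progress print per-scan progress?
#' @return Invisibly, a list with `results` (SBR records), `manifest`,
#'   `summary` (cohort statistics) and `paths`.
#' @export
run_experiment <- function(config = run_config(), progress = TRUE) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  spec <- config$phantom

  anat <- make_anatomy(spec)
  templates <- paint_template_set(spec)
  cohort <- simulate_cohort(spec, config$n, config$mixture,
                            seed = config$seed,
                            scalp_frac = config$scalp_frac)

  if (config$write_nifti) {
    nd <- file.path(config$out_dir, "nifti")
    dir.create(nd, showWarnings = FALSE)
    for (nm in names(anat$masks))
      write_nifti(anat$masks[[nm]], file.path(nd, paste0(nm, ".nii.gz")),
                  datatype = "uint8")
    for (i in seq_along(cohort$scans))
      write_nifti(cohort$scans[[i]],
                  file.path(nd, sprintf("scan%04d.nii.gz", i)))
  }

  res <- vector("list", 2 * config$n)
  for (i in seq_len(config$n)) {
    id <- cohort$manifest$scan_id[i]
    for (mode in c("single", "multiple")) {
      if (progress)
        message(sprintf("[%s] quantify %s (%s)", hash, id, mode))
      res[[2 * (i - 1) + (mode == "multiple") + 1]] <-
        quantify_scan(cohort$scans[[i]], templates, anat$masks,
                      template_mode = mode, scan_id = id,
                      volume_ml = config$volume_ml,
                      opts = config$registration)
    }
  }
  results <- do.call(rbind, res)

  summary <- cohort_summary(results, bin_width = config$bin_width,
                            n_subsample = config$n_subsample,
                            seed = config$seed)
  summary$seed <- config$seed
  summary$config_hash <- hash

  manifest <- cohort$manifest
  manifest$config_hash <- hash
  manifest$seed <- config$seed
  results$config_hash <- hash
  paths <- list(
    manifest = file.path(config$out_dir, "manifest.csv"),
    results = file.path(config$out_dir, "results.csv"),
    summary = file.path(config$out_dir, "summary.json"))
  utils::write.csv(manifest, paths$manifest, row.names = FALSE)
  utils::write.csv(results, paths$results, row.names = FALSE)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, force = TRUE)
  invisible(list(results = results, manifest = manifest, summary = summary,
                 paths = paths))
}

#' Cohort-level statistics from a table of SBR records
#'
#' @param results data.frame of stacked [quantify_scan()] rows.
#' @param bin_width histogram bin width.
#' @param n_subsample subsample-stability replicates for the HV-min
#'   settings (0 disables).
#' @param seed seed for the subsampling.
#' @return List with per-setting `fits` (coefficients, d, c), the HV-min
#'   single-versus-multiple `crosstab` and `kappa`, `regressions`
#'   (SBR on DET per class and mode; DET single on DET multiple through
#'   origin among concordant cases), and optional `stability`.
#' @export
cohort_summary <- function(results, bin_width = 0.1, n_subsample = 0,
                           seed = 1) {
  setting_values <- function(mode, method, characteristic) {
    sub <- results[results$template_mode == mode &
                     results$roi_method == method, ]
    sub <- sub[order(sub$scan_id), ]
    switch(characteristic,
           min = sub$sbr_min, mean = sub$sbr_mean,
           left = sub$sbr_left, right = sub$sbr_right)
  }
  fits <- list()
  for (mode in c("single", "multiple"))
    for (method in c("HV", "AAL"))
      for (ch in c("min", "mean", "left", "right")) {
        v <- setting_values(mode, method, ch)
        fit <- tryCatch(fit_two_gaussians(histogram_sbr(v, bin_width)),
                        error = function(e) NULL)
        key <- paste(method, ch, mode, sep = "_")
        fits[[key]] <- if (is.null(fit)) list(error = "fit failed") else
          list(A1 = fit$A1, M1 = fit$M1, SD1 = fit$SD1, A2 = fit$A2,
               M2 = fit$M2, SD2 = fit$SD2, d = fit$d, c = fit$c,
               converged = fit$converged)
      }

  out <- list(fits = fits)
  fs <- fits[["HV_min_single"]]
  fm <- fits[["HV_min_multiple"]]
  if (is.null(fs$error) && is.null(fm$error)) {
    v_s <- setting_values("single", "HV", "min")
    v_m <- setting_values("multiple", "HV", "min")
    lab_s <- classify(v_s, fs$c)
    lab_m <- classify(v_m, fm$c)
    ct <- cross_tab(lab_m, lab_s)
    out$crosstab <- list(counts = ct$counts, percent = ct$percent,
                         concordance = ct$concordance)
    out$kappa <- cohens_kappa(ct$counts)

    det_of_mode <- function(mode) {
      sub <- results[results$template_mode == mode &
                       results$roi_method == "HV", ]
      sub$det[order(sub$scan_id)]
    }
    det_s <- det_of_mode("single")
    det_m <- det_of_mode("multiple")
    regs <- list()
    for (mode in c("single", "multiple")) {
      v <- if (mode == "single") v_s else v_m
      dd <- if (mode == "single") det_s else det_m
      lab <- if (mode == "single") lab_s else lab_m
      for (cl in c("normal", "reduced")) {
        selc <- lab == cl
        regs[[paste("sbr_on_det", mode, cl, sep = "_")]] <-
          if (sum(selc) >= 3 && stats::sd(dd[selc]) > 0)
            regress(v[selc], dd[selc], with_constant = TRUE)
          else list(error = "too few cases")
      }
    }
    conc <- lab_s == lab_m
    for (cl in c("normal", "reduced")) {
      selc <- conc & lab_m == cl
      regs[[paste("det_single_on_det_multiple", cl, sep = "_")]] <-
        if (sum(selc) >= 3 && stats::sd(det_m[selc]) > 0)
          regress(det_s[selc], det_m[selc], with_constant = FALSE)
        else list(error = "too few cases")
    }
    out$regressions <- regs
    if (n_subsample > 0) {
      out$stability <- list(
        HV_min_single = subsample_stability(v_s, n_rep = n_subsample,
                                            seed = seed)[c("mean_d", "sd_d", "cov")],
        HV_min_multiple = subsample_stability(v_m, n_rep = n_subsample,
                                              seed = seed)[c("mean_d", "sd_d", "cov")])
    }
  }
  out
}
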