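# Shared fixtures, built once per test run (all in code, no binary files).

fix <- local({
  spec <- phantom_spec()
  anat <- make_anatomy(spec)
  templates <- paint_template_set(spec)
  list(spec = spec, anat = anat, masks = anat$masks, templates = templates)
})

# a subject with fully specified striatal profile (no RNG)
proto_truth <- function(sbr, asym = 0, category = "normal",
                        worse = "right", caud_excess = NULL) {
  if (is.null(caud_excess)) caud_excess <- if (category == "reduced") 0.5 else 0.1
  sbrv <- c(left = sbr, right = sbr)
  better <- if (worse == "left") "right" else "left"
  sbrv[better] <- sbrv[worse] + asym
  structure(list(category = category, worse_side = worse,
                 sbr_putamen = sbrv, sbr_caudate = sbrv + caud_excess,
                 dvr_putamen = sbrv + 1, dvr_caudate = sbrv + caud_excess + 1,
                 true_affine = NULL),
            class = "subject_truth")
}

# small random volume on its own grid
rand_vol <- function(d = c(7, 6, 5), voxel = 2, seed = 1, space = "native") {
  set.seed(seed)
  vol3d(array(rnorm(prod(d)), d), voxel_size = rep(voxel, 3), space = space)
}

# cheap registration options for unit tests that only need a rough fit
fast_opts <- normalize_opts(pyramid_fwhm = c(8, 4), stride = c(2, 2),
                            maxit = c(250, 60), method = c("NM", "BFGS"),
                            restarts = 0)
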