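# Shared fixtures, built once per test run and cached across test files.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, maker) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- maker()
  .fx_cache[[name]]
}

# wrap a ground-truth label grid as a segmentation-like object (ventricle
# voxels present as CSF, as the intensity model would see them)
seg_from_truth <- function(truth) {
  lab <- truth$labels
  lab[lab == 5L] <- 2L
  list(labels = lab, spacing = truth$spacing)
}

# small phantom for registration tests: fits comfortably with room to move
small_config <- function() {
  phantom_config(grid_shape = c(48, 48, 48), spacing_mm = c(2, 2, 2),
                 brain_radii_mm = c(28, 30, 24),
                 sulci = list(amplitude_mm = 3, wavelength_mm = 25),
                 ventricle_radii_mm = list(left = c(5, 9, 6),
                                           right = c(5, 9, 6)),
                 ventricle_offset_mm = c(9, -3, 0))
}

# compact cohort base for the determinism check
tiny_cohort_config <- function() {
  phantom_config(grid_shape = c(48, 48, 48), spacing_mm = c(2.5, 2.5, 2.5),
                 brain_radii_mm = c(34, 40, 30), gm_thickness_mm = 6,
                 sulci = list(amplitude_mm = 4, wavelength_mm = 40),
                 ventricle_radii_mm = list(left = c(7, 12, 8),
                                           right = c(7, 12, 8)),
                 ventricle_offset_mm = c(11, -4, 0))
}

fx_template <- function() fx("template", function() build_anatomy(cohort_phantom_config()))

fx_atlas_m <- function() fx("atlas_m", function()
  atlas_extend(fx_template()$atlas, cohort_phantom_config()$spacing_mm))

# a cohort-resolution phantom carrying a 1.0 mL WM lesion (r = 6.2 mm) and
# +2 mL left ventricular enlargement, plus its ground truth
fx_lesion_truth <- function() fx("lesion_truth", function() {
  cfg <- cohort_phantom_config()
  tr <- build_anatomy(cfg)
  co <- cpinjury:::voxel_coords_mm(dim(tr$labels), cfg$spacing_mm)
  wm <- tr$labels == 4L
  din <- distance_transform(!wm, cfg$spacing_mm)
  deep <- which(din > 6.5)
  i <- deep[which.max(din[deep])]
  ctr <- c(co$x[i], co$y[i], co$z[i])
  spec <- injury_spec(
    lesions = list(list(center_mm = ctr, radius_mm = 6.2, tissue = "WM",
                        contrast = c(T1 = 0.85, T2 = 1.9))),
    ventricle_enlargement = list(left = list(added_ml = 2,
                                             direction = c(0, -1, 0.3))))
  inject_injuries(tr, spec)
})

# preprocess a simulated acquisition the way the pipeline does
preprocess_mri <- function(mri, denoise_iter = 2) {
  t1 <- denoise_mcde(mri$t1, denoise_iter)
  t2 <- denoise_mcde(mri$t2, denoise_iter)
  mask <- strip_skull(t1)
  t1 <- normalize_intensity(correct_bias(t1, mask), mask)
  t2 <- normalize_intensity(correct_bias(t2, mask), mask)
  list(t1 = t1, t2 = t2, mask = mask)
}

# segmentation + lesion detection of the 1 mL lesion phantom at SNR 20
fx_lesion_fit <- function() fx("lesion_fit", function() {
  tr <- fx_lesion_truth()
  mri <- simulate_mri(tr, acquisition_spec(seed = 11))
  pp <- preprocess_mri(mri)
  priors <- make_tissue_priors(fx_template())
  fit <- fit_em_mrf(pp$t1, pp$t2, pp$mask, priors, beta = 0.5, max_iter = 30)
  les <- detect_lesions(pp$t1, pp$t2, pp$mask, fit)
  list(truth = tr, pp = pp, fit = fit, les = les, priors = priors)
})

# 20 jittered control phantoms: shape summaries + ventricle shapes (left),
# measured on ground-truth labels (shape/SSM module accuracy, no EM noise)
fx_controls20 <- function() fx("controls20", function() {
  base <- cohort_phantom_config()
  cohort <- simulate_cohort(20, 0, base, seed = 5)
  atlas_m <- fx_atlas_m()
  box_l <- cpinjury:::ventricle_box_side(fx_template()$atlas,
                                         base$spacing_mm, "left")
  summaries <- list()
  shapes <- list()
  for (i in 1:20) {
    tr <- realize_subject(cohort$subjects[[i]])
    seg <- seg_from_truth(tr)
    maps <- compute_shape_maps(seg)
    summaries[[i]] <- summarize_regions(maps, atlas_m)
    shapes[[i]] <- extract_ventricle_shape(seg, atlas_m, "left", box_l,
                                           subject_id = cohort$subjects[[i]]$id)
  }
  list(cohort = cohort, summaries = summaries, shapes = shapes,
       norm = build_normative_stats(summaries), box_l = box_l)
})

# the full simulated study: 44 controls + 95 patients through the imaging
# pipeline (shared by the structure-function recovery checks)
fx_cohort139 <- function() fx("cohort139", function()
  run_cohort_analysis(n_controls = 44, n_patients = 95, seed = 7,
                      fit_models = FALSE))

# L-BFGS-B solution of the negativity-constrained lasso objective: the
# penalty is linear on the feasible set, so box-constrained quasi-Newton
# solves the problem exactly (independent oracle)
qp_oracle_neg_lasso <- function(X, Z, y, lambda) {
  n <- length(y)
  p <- ncol(X)
  q <- if (is.null(Z)) 0 else ncol(Z)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(sweep(X, 2, xm)^2))
  keep <- xs > 1e-12
  xs[!keep] <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  Xs[, !keep] <- 0
  Zc <- if (q > 0) scale(Z, scale = FALSE) else NULL
  yc <- y - mean(y)
  obj <- function(par) {
    b <- par[1:p]
    g <- if (q > 0) par[(p + 1):(p + q)] else numeric(0)
    r <- yc - Xs %*% b - (if (q > 0) Zc %*% g else 0)
    sum(r^2) / (2 * n) - lambda * sum(b)
  }
  o <- optim(rep(0, p + q), obj, method = "L-BFGS-B",
             upper = c(rep(0, p), rep(Inf, q)), lower = rep(-Inf, p + q),
             control = list(maxit = 3000, factr = 1e2))
  o$par[1:p]
}
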