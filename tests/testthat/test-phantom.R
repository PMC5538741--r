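# Synthetic phantom generator: anatomy geometry, injury injection with exact
# ground-truth volumes, MR simulation, cohort and score generation.

test_that("anatomy geometry honours ribbon width, symmetry and ventricle volume", {
  cfg <- cohort_phantom_config()
  tr <- fx_template()
  sp <- cfg$spacing_mm
  L <- TISSUE_LABELS

  # every GM voxel lies within the ribbon width (+ one voxel diagonal) of
  # both the WM and the exterior interfaces
  gm <- tr$labels == L[["gm"]]
  wm <- tr$labels == L[["wm"]] | tr$labels == L[["ventricle"]]
  ext <- !(tr$labels %in% c(L[["gm"]], L[["wm"]], L[["ventricle"]])) |> array(dim(tr$labels))
  diag_mm <- sqrt(sum(sp^2))
  # deep-grey GM shell sits around the ventricles, away from the pial side;
  # restrict to the cortical ribbon (atlas cortical labels)
  ribbon <- gm & cpinjury:::arr_in(tr$atlas$labels, tr$atlas$table$id[tr$atlas$table$class == "cortical"])
  expect_lte(max(distance_transform(wm, sp)[ribbon]), cfg$gm_thickness_mm + diag_mm)
  expect_lte(max(distance_transform(ext, sp)[ribbon]), cfg$gm_thickness_mm + diag_mm)

  # mirror symmetry: identical label counts per hemisphere
  nx <- dim(tr$labels)[1]
  left <- table(factor(tr$labels[1:(nx / 2), , ], levels = 0:7))
  right <- table(factor(tr$labels[(nx / 2 + 1):nx, , ], levels = 0:7))
  expect_identical(as.vector(left), as.vector(right))

  # ventricle volume close to the analytic ellipsoid volume
  va <- 4 / 3 * pi * prod(cfg$ventricle_radii_mm$left)
  vl <- sum(tr$atlas$labels == 401L) * voxel_volume_mm3(sp)
  expect_lt(abs(vl - va) / va, 0.05)

  # atlas richness: >= 8 cortical, >= 4 WM, >= 4 deep-grey regions
  tb <- tr$atlas$table
  expect_gte(sum(tb$class == "cortical"), 8)
  expect_gte(sum(tb$class == "white-matter"), 4)
  expect_gte(sum(tb$class == "deep-grey"), 4)

  # grid too small for the anatomy -> sizing error
  expect_error(phantom_config(grid_shape = c(32, 32, 32)), "too small")
})

test_that("injury injection updates ground truth volumes exactly", {
  tr0 <- fx_template()

  # empty spec is the identity
  tr_same <- inject_injuries(tr0, injury_spec())
  expect_identical(tr_same$labels, tr0$labels)
  expect_identical(tr_same$true_lesion_ml, tr0$true_lesion_ml)

  tr <- fx_lesion_truth()
  vox_ml <- voxel_volume_mm3(tr$spacing) / 1000
  # 1.0 mL sphere (r = 6.2 mm) within 5% by voxel counting
  expect_lt(abs(sum(tr$true_lesion_ml) - 1.0), 0.05)
  # volume conservation: per-region tallies equal the voxel count exactly
  expect_equal(sum(tr$true_lesion_ml), sum(tr$labels == 6L) * vox_ml)
  # +2 mL left enlargement within one voxel; right untouched
  expect_lt(abs(tr$true_enlargement_ml[["left"]] - 2), 0.1)
  expect_identical(tr$true_enlargement_ml[["right"]], 0)

  # lesion centred outside its host tissue is rejected
  # the brain centre lies in the deep grey shell, not white matter
  bad <- injury_spec(lesions = list(list(center_mm = c(0, 0, 0),
                                         radius_mm = 3, tissue = "WM",
                                         contrast = c(T1 = 1, T2 = 1))))
  expect_error(inject_injuries(tr0, bad), "not inside")

  # thinning rescales the ribbon and the truth bookkeeping
  thin <- injury_spec(cortical_thinning = list(
    list(region_id = 103L, thickness_scale = 0.5)))
  trt <- inject_injuries(tr0, thin)
  expect_equal(trt$true_thickness_mm[["103"]],
               tr0$config$gm_thickness_mm * 0.5)
  expect_lt(sum(trt$labels == 3L), sum(tr0$labels == 3L))
})

test_that("MR simulation follows the Rician noise and bias model", {
  tr <- fx_template()
  # sigma = 0, no bias -> exact piecewise-constant tissue means
  m0 <- simulate_mri(tr, acquisition_spec(bias_amplitude = 0,
                                          noise_sigma = c(T1 = 0, T2 = 0),
                                          seed = 1))
  means <- default_tissue_means()
  expect_equal(unique(as.vector(m0$t1$data[tr$labels == 4L])),
               means$wm[["T1"]])
  expect_equal(unique(as.vector(m0$t2$data[tr$labels == 2L])),
               means$csf[["T2"]])

  # high-SNR limit: sample sd on a flat region approximates sigma within 10%
  m5 <- simulate_mri(tr, acquisition_spec(bias_amplitude = 0,
                                          noise_sigma = c(T1 = 5, T2 = 5),
                                          seed = 3))
  wmi <- mask_erode(tr$labels == 4L, 4, tr$spacing)
  expect_gt(sum(wmi), 5e3)
  expect_lt(abs(sd(m5$t1$data[wmi]) - 5) / 5, 0.10)

  # same seed -> bit-identical volumes
  m5b <- simulate_mri(tr, acquisition_spec(bias_amplitude = 0,
                                           noise_sigma = c(T1 = 5, T2 = 5),
                                           seed = 3))
  expect_identical(m5$t1$data, m5b$t1$data)

  # a tissue without an intensity entry is a config error
  tm <- default_tissue_means()
  tm$wm <- NULL
  expect_error(simulate_mri(tr, acquisition_spec(tissue_means = tm)),
               "missing tissue intensity")
})

test_that("cohort simulation produces the requested composition deterministically", {
  base <- tiny_cohort_config()
  co <- simulate_cohort(44, 95, base, seed = 2)
  expect_equal(nrow(co$manifest), 139)
  expect_equal(sum(co$manifest$group == "control"), 44)
  # controls carry no injuries
  ctrl <- co$subjects[1:44]
  expect_true(all(vapply(ctrl, function(s)
    length(s$plan$lesions) + length(s$plan$enlargement) +
      length(s$plan$thinning) == 0, logical(1))))
  expect_true(all(co$manifest$age >= 5 & co$manifest$age <= 17))

  # fixed seed -> identical manifest
  co2 <- simulate_cohort(44, 95, base, seed = 2)
  expect_identical(co$manifest, co2$manifest)

  # degenerate cohort: one patient, no controls; normative stage must refuse
  co1 <- simulate_cohort(0, 1, base, seed = 2)
  expect_equal(nrow(co1$manifest), 1)
  expect_error(build_normative_stats(list()), "insufficient")
})

test_that("clinical scores are a sparse negative linear model of true injury", {
  # noiseless, zero weights -> exactly intercept + covariate terms
  feats <- data.frame(subject_id = c("a", "b"), age = c(10, 12),
                      sex = c("F", "M"), sequence = c("A", "B"),
                      les_wm_01 = c(0, 10))
  w0 <- list(AHA = c(les_wm_01 = 0))
  gen0 <- score_generator_spec(
    weights = w0,
    covariate_effects = list(AHA = c(age = 0.3, sexF = 1.5, sequenceB = -2)),
    intercepts = c(AHA = 100), noise_sd = 0)
  sc0 <- simulate_clinical_scores(feats, gen0)
  expect_equal(sc0$AHA, c(100 + 3 + 1.5, 100 + 3.6 - 2))

  # a -0.05/mL weight separates 10 mL from 0 mL by exactly -0.5
  gen1 <- score_generator_spec(
    weights = list(AHA = c(les_wm_01 = -0.05)),
    covariate_effects = list(AHA = c(age = 0, sexF = 0, sequenceB = 0)),
    intercepts = c(AHA = 100), noise_sd = 0)
  sc1 <- simulate_clinical_scores(feats, gen1)
  expect_equal(sc1$AHA[2] - sc1$AHA[1], -0.5)

  # empirical residual sd matches noise_sd within 10% at n = 1000
  n <- 1000
  withr::with_seed(4, {
    big <- data.frame(subject_id = as.character(1:n), age = runif(n, 5, 17),
                      sex = sample(c("M", "F"), n, TRUE),
                      sequence = sample(c("A", "B"), n, TRUE),
                      les_wm_01 = rexp(n, 0.3))
  })
  gen2 <- score_generator_spec(
    weights = list(AHA = c(les_wm_01 = -1)),
    covariate_effects = list(AHA = c(age = 0.3, sexF = 1.5, sequenceB = -2)),
    intercepts = c(AHA = 100), noise_sd = 7, seed = 9)
  sc2 <- simulate_clinical_scores(big, gen2)
  lp <- 100 - big$les_wm_01 + 0.3 * big$age + 1.5 * (big$sex == "F") -
    2 * (big$sequence == "B")
  expect_lt(abs(sd(sc2$AHA - lp) - 7) / 7, 0.10)

  # unknown feature name in the weights is rejected
  genx <- score_generator_spec(weights = list(AHA = c(nope = -1)),
                               covariate_effects = list(AHA = c(age = 0, sexF = 0, sequenceB = 0)),
                               intercepts = c(AHA = 1), noise_sd = 0)
  expect_error(simulate_clinical_scores(feats, genx), "unknown feature")

  # positive biomarker weights are rejected by construction
  expect_error(score_generator_spec(weights = list(AHA = c(les_wm_01 = 0.1))),
               "<= 0")
})
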