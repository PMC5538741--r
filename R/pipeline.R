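# End-to-end orchestration: simulate -> preprocess -> segment -> shape ->
# ventricles -> assemble -> model -> report, with a config/manifest layer.

#' Default phantom configuration for cohort runs
#'
#' 64^3 voxels at 2 mm spacing with a 6 mm cortical ribbon: the ribbon must
#' span at least three voxels so thinning by half keeps it resolvable. Used
#' by the cohort-level analyses; single-subject shape accuracy work uses the
#' finer default of [phantom_config()].
#' @return a [phantom_config()].
#' @export
cohort_phantom_config <- function() {
  phantom_config(grid_shape = c(64, 64, 64), spacing_mm = c(2, 2, 2),
                 brain_radii_mm = c(40, 48, 36), gm_thickness_mm = 6,
                 sulci = list(amplitude_mm = 4, wavelength_mm = 40),
                 skull_thickness_mm = 3, csf_thickness_mm = 2,
                 ventricle_radii_mm = list(left = c(8, 14, 9),
                                           right = c(8, 14, 9)),
                 ventricle_offset_mm = c(12, -4, 0),
                 deep_gm_thickness_mm = 5)
}

#' Default pipeline stage options
#' @return named list of stage parameters.
#' @export
pipeline_options <- function() {
  list(denoise_iter = 2, bias_order = 3, em_beta = 0.5, em_max_iter = 30,
       em_tol = 1e-4, lesion_epsilon = 0.02, min_lesion_voxels = 5,
       variance_to_retain = 0.95, z_threshold = 2.5, hull_radius_mm = 15,
       train_fraction = 0.75)
}

#' Extend an atlas parcellation to unlabelled space
#'
#' Assigns every unlabelled voxel the id of its nearest labelled voxel, so a
#' template parcellation can be applied to subjects whose (jittered) anatomy
#' does not coincide exactly with the template — the phantom-frame analogue
#' of an affinely registered atlas.
#'
#' @param atlas template atlas (list with `labels`, `table`).
#' @param spacing voxel spacing mm.
#' @return atlas with fully labelled `labels`.
#' @export
atlas_extend <- function(atlas, spacing) {
  lab <- atlas$labels
  ids <- atlas$table$id
  best_d <- array(Inf, dim(lab))
  out <- array(0L, dim(lab))
  for (id in ids) {
    m <- lab == id
    if (!any(m)) next
    d <- distance_transform(m, spacing)
    upd <- d < best_d
    out[upd] <- id
    best_d[upd] <- d[upd]
  }
  list(labels = out, table = atlas$table)
}

#' Process a single subject through the imaging pipeline
#'
#' Realizes the phantom, simulates acquisition, denoises, skull-strips,
#' bias-corrects, normalises, runs the EM/MRF segmentation with lesion
#' classes, computes shape maps and regional summaries, regional lesion
#' volumes, and ventricle shapes. Returns per-subject measurements plus the
#' ground truth features.
#'
#' @param subject descriptor from [simulate_cohort()].
#' @param priors tissue priors from the template ([make_tissue_priors()]).
#' @param atlas_m measurement atlas (template, extended).
#' @param boxes list with `left`/`right` [ventricle_box()]es.
#' @param opts [pipeline_options()].
#' @return list of per-subject results.
#' @export
process_subject <- function(subject, priors, atlas_m, boxes,
                            opts = pipeline_options()) {
  truth <- realize_subject(subject)
  mri <- simulate_mri(truth, subject$acq)
  t1 <- denoise_mcde(mri$t1, iterations = opts$denoise_iter)
  t2 <- denoise_mcde(mri$t2, iterations = opts$denoise_iter)
  mask <- strip_skull(t1, csf_margin_mm = subject$config$csf_thickness_mm)
  t1 <- correct_bias(t1, mask, order = opts$bias_order)
  t2 <- correct_bias(t2, mask, order = opts$bias_order)
  t1 <- normalize_intensity(t1, mask)
  t2 <- normalize_intensity(t2, mask)
  fit <- fit_em_mrf(t1, t2, mask, priors, beta = opts$em_beta,
                    max_iter = opts$em_max_iter, tol = opts$em_tol)
  les <- detect_lesions(t1, t2, mask, fit, epsilon = opts$lesion_epsilon,
                        min_voxels = opts$min_lesion_voxels,
                        beta = opts$em_beta, tol = opts$em_tol)
  lesion_df <- regional_lesion_volumes(
    list(wm_lesion = les$wm_lesion, gm_lesion = les$gm_lesion),
    atlas_m, t1$spacing)
  maps <- compute_shape_maps(les$seg, mask, hull_radius_mm = opts$hull_radius_mm)
  summ <- summarize_regions(maps, atlas_m)
  shapes <- list()
  for (side in c("left", "right")) {
    shapes[[side]] <- tryCatch(
      extract_ventricle_shape(les$seg, atlas_m, side, boxes[[side]],
                              subject_id = subject$id),
      error = function(e) NULL)
  }
  tf <- truth_features(truth)
  list(id = subject$id, group = subject$group, age = subject$age,
       sex = subject$sex, sequence = subject$sequence,
       summary = summ, lesions = lesion_df, shapes = shapes,
       truth = tf, seg_log = fit$model$log)
}

#' Run the full cohort analysis in memory
#'
#' Simulates a cohort, processes every subject, builds normative statistics
#' and the ventricle shape models from the controls, assembles the biomarker
#' table, applies the binary injury rules, simulates clinical scores from
#' the ground truth, and fits the six structure-function models.
#'
#' @param n_controls,n_patients cohort sizes.
#' @param base phantom config shared by the cohort.
#' @param acq acquisition spec.
#' @param gen score generator spec.
#' @param seed master seed.
#' @param opts [pipeline_options()].
#' @param model_seed seed for splits/folds (defaults to `seed`).
#' @param fit_models whether to fit the six score models.
#' @param progress print per-subject progress.
#' @return list with `table` (biomarker + scores), `prevalence`, `models`,
#'   `evaluations`, `norm`, `ssm`, `manifest`, `subjects` (light results).
#' @export
run_cohort_analysis <- function(n_controls = 44, n_patients = 95,
                                base = cohort_phantom_config(),
                                acq = acquisition_spec(),
                                gen = score_generator_spec(),
                                seed = 1L, opts = pipeline_options(),
                                model_seed = seed, fit_models = TRUE,
                                progress = FALSE) {
  cohort <- simulate_cohort(n_controls, n_patients, base, acq, seed = seed)
  template <- build_anatomy(base)
  priors <- make_tissue_priors(template)
  atlas_m <- atlas_extend(template$atlas, base$spacing_mm)
  boxes <- list(left = ventricle_box_side(template$atlas, base$spacing_mm, "left"),
                right = ventricle_box_side(template$atlas, base$spacing_mm, "right"))
  res <- vector("list", length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    res[[i]] <- process_subject(cohort$subjects[[i]], priors, atlas_m, boxes, opts)
    if (progress) message(sprintf("processed %s (%d/%d)", res[[i]]$id, i,
                                  length(res)))
  }
  is_ctrl <- vapply(res, function(r) r$group == "control", logical(1))

  # normative shape statistics from controls
  norm <- build_normative_stats(lapply(res[is_ctrl], `[[`, "summary"))

  # ventricle SSMs per side from controls
  ssm <- list()
  for (side in c("left", "right")) {
    ctrl_shapes <- Filter(Negate(is.null),
                          lapply(res[is_ctrl], function(r) r$shapes[[side]]))
    ssm[[side]] <- build_ssm(ctrl_shapes, opts$variance_to_retain)
  }

  # per-subject z-scores and enlargement
  dg_names <- atlas_m$table$name[atlas_m$table$class == "deep-grey"]
  subject_results <- lapply(res, function(r) {
    z <- zscore_regions(r$summary, norm)
    enl <- setNames(numeric(length(dg_names)), dg_names)
    for (side in c("left", "right")) {
      if (is.null(r$shapes[[side]])) next
      rec <- reconstruct_healthy(r$shapes[[side]], ssm[[side]])
      loc <- localize_enlargement(r$shapes[[side]], rec, atlas_m)
      enl <- enl + loc$by_anatomy[dg_names]
    }
    list(id = r$id, group = r$group, age = r$age, sex = r$sex,
         sequence = r$sequence, zscores = z, lesions = r$lesions,
         enlargement = enl, atlas_table = atlas_m$table)
  })
  table <- assemble_table(subject_results)

  vox_ml <- voxel_volume_mm3(base$spacing_mm) / 1000
  profiles <- lapply(seq_len(nrow(table)), function(i)
    classify_injury(table[i, ], z_threshold = opts$z_threshold,
                    volume_floor_ml = vox_ml))
  prevalence <- cohort_prevalence(profiles, groups = table$group)

  # clinical scores from ground truth features
  tf <- do.call(rbind, lapply(res, function(r)
    as.data.frame(as.list(r$truth), check.names = FALSE)))
  tf$subject_id <- vapply(res, `[[`, character(1), "id")
  tf$age <- vapply(res, `[[`, numeric(1), "age")
  tf$sex <- vapply(res, `[[`, character(1), "sex")
  tf$sequence <- vapply(res, `[[`, character(1), "sequence")
  scores <- simulate_clinical_scores(tf, gen)
  table <- merge(table, scores, by = "subject_id", sort = FALSE)

  models <- list()
  evaluations <- NULL
  if (fit_models) {
    thr <- bonferroni_threshold(0.05, length(names(gen$weights)))
    for (sc in names(gen$weights)) {
      models[[sc]] <- fit_score_model(table, sc, fraction = opts$train_fraction,
                                      seed = model_seed, threshold = thr)
    }
    evaluations <- do.call(rbind, lapply(names(models), function(sc) {
      ev <- models[[sc]]$evaluation
      data.frame(score = sc, r = ev$r, ci_lo = ev$ci[1], ci_hi = ev$ci[2],
                 relative_mean_error_pct = ev$relative_mean_error_pct,
                 p_value = ev$p_value, significant = ev$significant,
                 n_retained = length(models[[sc]]$retained),
                 adj_r2_train = models[[sc]]$refit$adj_r2,
                 stringsAsFactors = FALSE)
    }))
  }
  list(table = table, prevalence = prevalence, models = models,
       evaluations = evaluations, norm = norm, ssm = ssm,
       manifest = cohort$manifest, truth_features = tf,
       subjects = lapply(res, function(r) r[c("id", "group")]))
}

# per-side bounding box (ids 401/402 separately)
ventricle_box_side <- function(atlas, spacing, side) {
  sid <- if (side == "left") 401L else 402L
  sub <- list(labels = array(ifelse(atlas$labels == sid, sid, 0L),
                             dim(atlas$labels)),
              table = atlas$table)
  # reuse ventricle_box on the single-side atlas
  m <- sub$labels == sid
  dm <- dim(sub$labels)
  co <- which(m, arr.ind = TRUE)
  pad <- ceiling(10 / spacing)
  lo <- pmax(1L, apply(co, 2, min) - pad)
  hi <- pmin(dm, apply(co, 2, max) + pad)
  list(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
}

#' Read / write a pipeline run configuration
#'
#' JSON round-trip of the run configuration. Unknown top-level keys are
#' rejected.
#'
#' @param path JSON file path.
#' @param config configuration list.
#' @return the configuration list / `path`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("n_controls", "n_patients", "seed", "phantom", "acquisition",
               "scores", "options", "out_dir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  required <- c("n_controls", "n_patients", "seed")
  miss <- setdiff(required, names(cfg))
  if (length(miss) > 0)
    stop("missing config key(s): ", paste(miss, collapse = ", "))
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the pipeline from a configuration
#'
#' Executes the full chain and persists the biomarker table, clinical
#' scores, evaluation table, prevalence summary and a run manifest under
#' `out_dir`. Rerunning with the same config and seed reproduces identical
#' outputs.
#'
#' @param config a list (or JSON path) as accepted by [read_run_config()].
#' @return the run manifest (invisibly): seeds, parameters, output hashes.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- if (!is.null(config$out_dir)) config$out_dir else "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- do.call(phantom_config, as.list(config$phantom))
  acq <- do.call(acquisition_spec, as.list(config$acquisition))
  gen <- do.call(score_generator_spec, as.list(config$scores))
  opts <- utils::modifyList(pipeline_options(),
                            if (is.null(config$options)) list() else config$options)
  res <- run_cohort_analysis(config$n_controls, config$n_patients, base, acq,
                             gen, seed = config$seed, opts = opts)
  paths <- c(biomarkers = file.path(out_dir, "biomarkers.csv"),
             evaluations = file.path(out_dir, "evaluations.csv"),
             prevalence = file.path(out_dir, "prevalence.json"),
             manifest = file.path(out_dir, "run_manifest.json"))
  write.csv(res$table, paths[["biomarkers"]], row.names = FALSE)
  if (!is.null(res$evaluations))
    write.csv(res$evaluations, paths[["evaluations"]], row.names = FALSE)
  jsonlite::write_json(list(cells = res$prevalence$cells,
                            totals = as.list(res$prevalence$totals),
                            percent = as.list(res$prevalence$percent)),
                       paths[["prevalence"]], auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = config$seed, n_controls = config$n_controls,
    n_patients = config$n_patients,
    package_version = as.character(utils::packageVersion("cpinjury")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    outputs = as.list(tools::md5sum(paths[c("biomarkers")])))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(res, list(run_manifest = manifest)))
}
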