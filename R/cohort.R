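# Cohort simulation: controls and patients with per-subject anatomical
# jitter, sampled injuries, acquisition covariates, and clinical scores
# generated as a sparse negative linear function of true injury load.

#' Default injury sampler for patient phantoms
#'
#' Draws an injury plan per patient: white/grey matter lesions (lesion
#' presence 55%), ventricular enlargement (75% given lesions, 60% otherwise,
#' i.e. a marginal rate near 68% with the known lesion-enlargement
#' co-occurrence above 60%), and cortical thinning (30%). Lesion target
#' volumes are log-normal (roughly 0.5-12 mL); thinning scales are uniform
#' on [0.5, 0.9]. Returns a function of no arguments to be called under the
#' cohort RNG stream.
#'
#' @param p_lesion,p_thin marginal injury probabilities.
#' @param p_enl_given_lesion,p_enl_no_lesion conditional enlargement rates.
#' @param n_cortical_sectors number of cortical regions in the atlas.
#' @return a sampler closure returning an injury plan list.
#' @export
default_injury_sampler <- function(p_lesion = 0.55, p_thin = 0.30,
                                   p_enl_given_lesion = 0.75,
                                   p_enl_no_lesion = 0.60,
                                   n_cortical_sectors = 8) {
  function() {
    plan <- list(lesions = list(), enlargement = list(), thinning = list())
    has_lesion <- runif(1) < p_lesion
    if (has_lesion) {
      n_les <- sample(1:3, 1, prob = c(0.5, 0.3, 0.2))
      for (i in seq_len(n_les)) {
        vol_ml <- min(12, max(0.5, exp(rnorm(1, log(2), 0.7))))
        tissue <- if (runif(1) < 0.7) "WM" else "GM"
        plan$lesions[[i]] <- list(
          tissue = tissue,
          radius_mm = (3 * vol_ml * 1000 / (4 * pi))^(1 / 3),
          theta = runif(1, -pi, pi),
          elev = runif(1, -0.9, 0.9),
          rho_frac = if (tissue == "WM") runif(1, 0.45, 0.75) else runif(1, 0.9, 1),
          contrast = if (tissue == "WM") c(T1 = 0.85, T2 = 1.9) else c(T1 = 0.8, T2 = 1.3))
      }
    }
    p_enl <- if (has_lesion) p_enl_given_lesion else p_enl_no_lesion
    if (runif(1) < p_enl) {
      sides <- if (runif(1) < 0.35) c("left", "right")
               else if (runif(1) < 0.6) "left" else "right"
      for (s in sides)
        plan$enlargement[[s]] <- list(added_ml = runif(1, 1, 4),
                                      direction = c(0, -1, 0.3))
    }
    if (runif(1) < p_thin) {
      n_thin <- sample(1:2, 1, prob = c(0.7, 0.3))
      regs <- sample(seq_len(n_cortical_sectors), n_thin)
      for (r in regs)
        plan$thinning[[length(plan$thinning) + 1]] <-
          list(region_id = 100L + r, thickness_scale = runif(1, 0.5, 0.9))
    }
    plan
  }
}

# jitter a config's anatomy for between-subject variability
.jitter_config <- function(base, seed) {
  cfg <- base
  cfg$brain_radii_mm <- base$brain_radii_mm *
    pmin(1.06, pmax(0.94, rnorm(3, 1, 0.03)))
  cfg$gm_thickness_mm <- base$gm_thickness_mm *
    min(1.12, max(0.88, rnorm(1, 1, 0.05)))
  cfg$sulci$amplitude_mm <- base$sulci$amplitude_mm *
    min(1.25, max(0.75, rnorm(1, 1, 0.1)))
  for (s in c("left", "right"))
    cfg$ventricle_radii_mm[[s]] <- base$ventricle_radii_mm[[s]] *
      pmin(1.12, pmax(0.88, rnorm(3, 1, 0.05)))
  cfg$seed <- as.integer(seed)
  cfg
}

#' Simulate a cohort of control and patient phantoms
#'
#' Controls carry an empty injury plan; patients draw injuries from the
#' sampler. Per-subject age (Uniform 5-17 years), sex (Bernoulli 0.5) and
#' scanner sequence (A/B) covariates are drawn, and each subject's anatomy is
#' jittered around the base configuration so that normative statistics and the
#' ventricle shape model see realistic between-subject variability. The
#' returned subjects are descriptors; [realize_subject()] builds the actual
#' phantom deterministically from a descriptor.
#'
#' @param n_controls,n_patients cohort sizes (>= 0).
#' @param base a [phantom_config()] shared by the cohort.
#' @param acq an [acquisition_spec()]; each subject gets a derived seed.
#' @param injury_sampler sampler closure, see [default_injury_sampler()].
#' @param seed cohort seed.
#' @param out_dir optional directory; writes `manifest.csv` when given.
#' @return list with `subjects` (list of descriptors) and `manifest`
#'   (data frame of ids, groups and covariates).
#' @export
simulate_cohort <- function(n_controls, n_patients, base = phantom_config(),
                            acq = acquisition_spec(),
                            injury_sampler = default_injury_sampler(
                              n_cortical_sectors = base$n_cortical_sectors),
                            seed = 1L, out_dir = NULL) {
  stopifnot(n_controls >= 0, n_patients >= 0)
  n <- n_controls + n_patients
  subjects <- vector("list", n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      group <- if (i <= n_controls) "control" else "patient"
      cfg <- .jitter_config(base, seed = seed + 1000L + i)
      subjects[[i]] <- list(
        id = sprintf("S%03d", i),
        group = group,
        age = round(runif(1, 5, 17), 1),
        sex = if (runif(1) < 0.5) "M" else "F",
        sequence = if (runif(1) < 0.5) "A" else "B",
        config = cfg,
        acq = local({a <- acq; a$seed <- as.integer(seed + 5000L + i); a}),
        plan = if (group == "patient") injury_sampler()
               else list(lesions = list(), enlargement = list(), thinning = list()))
    }
  })
  manifest <- do.call(rbind, lapply(subjects, function(s) data.frame(
    subject_id = s$id, group = s$group, age = s$age, sex = s$sex,
    sequence = s$sequence, n_lesions = length(s$plan$lesions),
    n_enlarged_sides = length(s$plan$enlargement),
    n_thinned_regions = length(s$plan$thinning),
    stringsAsFactors = FALSE)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(subjects = subjects, manifest = manifest)
}

#' Realize one subject's phantom
#'
#' Builds the jittered anatomy, resolves planned lesion positions to valid
#' in-tissue centres (the planned direction/depth is snapped to the nearest
#' voxel of the host tissue with enough clearance), injects all injuries and
#' returns the ground truth.
#'
#' @param subject a descriptor from [simulate_cohort()].
#' @return a `ground_truth`.
#' @export
realize_subject <- function(subject) {
  truth <- build_anatomy(subject$config)
  plan <- subject$plan
  L <- TISSUE_LABELS
  sp <- truth$spacing
  dm <- dim(truth$labels)
  if (length(plan$lesions) > 0) {
    co <- voxel_coords_mm(dm, sp)
    a <- subject$config$brain_radii_mm
    # lesions are snapped and injected one at a time so each snap sees the
    # labels left by the previous lesion (centres never land inside one)
    for (pl in plan$lesions) {
      host <- if (pl$tissue == "WM") L[["wm"]] else L[["gm"]]
      host_mask <- truth$labels == host
      d_in <- distance_transform(!host_mask, sp)   # clearance inside host
      dirv <- c(cos(pl$elev) * cos(pl$theta), cos(pl$elev) * sin(pl$theta),
                sin(pl$elev))
      target <- pl$rho_frac * a * dirv
      clear <- min(pl$radius_mm * 0.5, 4)
      ok <- which(host_mask & d_in >= clear)
      if (length(ok) == 0) ok <- which(host_mask)
      d2 <- (co$x[ok] - target[1])^2 + (co$y[ok] - target[2])^2 +
        (co$z[ok] - target[3])^2
      pick <- ok[which.min(d2)]
      les <- list(center_mm = c(co$x[pick], co$y[pick], co$z[pick]),
                  radius_mm = pl$radius_mm, tissue = pl$tissue,
                  contrast = pl$contrast)
      truth <- inject_injuries(truth, injury_spec(lesions = list(les),
                                                  seed = subject$config$seed))
    }
  }
  spec <- injury_spec(ventricle_enlargement = plan$enlargement,
                      cortical_thinning = plan$thinning,
                      seed = subject$config$seed)
  inject_injuries(truth, spec)
}

#' True injury features of a realized phantom
#'
#' The generator-side biomarkers used to synthesise clinical scores: cortical
#' thinning in mm per cortical region, true lesion mL per atlas region (by
#' lesion class), and true enlargement mL per side.
#'
#' @param truth a realized `ground_truth`.
#' @return named numeric vector of true features.
#' @export
truth_features <- function(truth) {
  tb <- truth$atlas$table
  base_t <- truth$config$gm_thickness_mm
  out <- c()
  cort <- tb[tb$class == "cortical", ]
  for (i in seq_len(nrow(cort))) {
    rid <- as.character(cort$id[i])
    out[paste0("thin_", cort$name[i])] <- base_t - truth$true_thickness_mm[[rid]]
  }
  for (i in seq_len(nrow(tb))) {
    cls <- tb$class[i]
    if (!cls %in% c("cortical", "white-matter", "deep-grey")) next
    rid <- as.character(tb$id[i])
    out[paste0("les_", tb$name[i])] <- truth$true_lesion_ml[[rid]]
  }
  out["enl_left"] <- truth$true_enlargement_ml[["left"]]
  out["enl_right"] <- truth$true_enlargement_ml[["right"]]
  out
}

#' Clinical score generator specification
#'
#' Scores are `intercept + sum(w_j x_j) + covariate effects + N(0, noise_sd)`
#' with all biomarker weights required to be <= 0 (injury can only reduce
#' function, matching the sign constraint the models enforce). When
#' `noise_sd` is NULL the noise is calibrated per score so the linear
#' predictor explains about `target_r2` of the score variance.
#'
#' @param weights named list per score: named numeric vectors of biomarker
#'   weights (all <= 0), names matching [truth_features()] columns.
#' @param covariate_effects named list per score with `age`, `sexF`,
#'   `sequenceB` additive effects.
#' @param intercepts named numeric per score.
#' @param noise_sd fixed residual sd, or NULL to use `target_r2`.
#' @param target_r2 fraction of variance explained when calibrating noise.
#' @param seed integer seed.
#' @return a `score_generator_spec`.
#' @export
score_generator_spec <- function(weights = default_score_weights(),
                                 covariate_effects = default_covariate_effects(),
                                 intercepts = c(AHA = 100, BRIEF = 200, SDQ = 80,
                                                TVPS = 130, WR = 95, VOC = 60),
                                 noise_sd = NULL, target_r2 = 0.7, seed = 1L) {
  for (sc in names(weights))
    if (any(weights[[sc]] > 0))
      stop("biomarker weights must be <= 0 (score ", sc, ")")
  if (!is.null(noise_sd) && any(noise_sd < 0)) stop("noise_sd must be >= 0")
  structure(list(weights = weights, covariate_effects = covariate_effects,
                 intercepts = intercepts, noise_sd = noise_sd,
                 target_r2 = target_r2, seed = as.integer(seed)),
            class = "score_generator_spec")
}

#' Default sparse score weights
#'
#' Each of the six clinical scores loads on a small set of true injury
#' features: cortical thinning (per mm of ribbon loss) and regional lesion
#' load (per mL). Ventricular enlargement carries no direct weight — in the
#' generative model it is a secondary consequence co-occurring with lesions,
#' so enlargement features are (noisy) proxies that selection should discard.
#' @return named list of named weight vectors.
#' @export
default_score_weights <- function() {
  list(AHA = c(thin_ctx_02 = -6, thin_ctx_05 = -4, les_wm_01 = -1.2, les_wm_03 = -0.8),
       BRIEF = c(thin_ctx_03 = -5, les_wm_02 = -1.0),
       SDQ = c(thin_ctx_01 = -4, thin_ctx_06 = -3, les_wm_04 = -0.9),
       TVPS = c(thin_ctx_07 = -5, les_wm_02 = -0.6, les_wm_01 = -0.4),
       WR = c(thin_ctx_04 = -5, les_wm_03 = -0.7),
       VOC = c(thin_ctx_08 = -4, les_wm_01 = -0.5))
}

#' Default covariate effects on scores
#' @return named list per score of age/sexF/sequenceB additive effects.
#' @export
default_covariate_effects <- function() {
  list(AHA = c(age = 0.3, sexF = 1.5, sequenceB = -2),
       BRIEF = c(age = 1.2, sexF = 8, sequenceB = 2),
       SDQ = c(age = 0.2, sexF = 1.5, sequenceB = 0.5),
       TVPS = c(age = 0.5, sexF = 3, sequenceB = 0.3),
       WR = c(age = -2.3, sexF = -3, sequenceB = -5),
       VOC = c(age = 4.1, sexF = 0.6, sequenceB = -2.7))
}

#' Simulate clinical scores from true injury features
#'
#' @param features data frame: one row per subject with [truth_features()]
#'   columns plus `subject_id`, `age`, `sex`, `sequence`.
#' @param gen a [score_generator_spec()].
#' @return data frame of subject_id plus the six scores.
#' @export
simulate_clinical_scores <- function(features, gen) {
  stopifnot(inherits(gen, "score_generator_spec"))
  n <- nrow(features)
  out <- data.frame(subject_id = features$subject_id, stringsAsFactors = FALSE)
  with_seed(gen$seed, {
    for (sc in names(gen$weights)) {
      w <- gen$weights[[sc]]
      unknown <- setdiff(names(w), colnames(features))
      if (length(unknown) > 0)
        stop("unknown feature(s) in score weights: ",
             paste(unknown, collapse = ", "))
      lp <- rep(gen$intercepts[[sc]], n)
      for (f in names(w)) lp <- lp + w[[f]] * features[[f]]
      ce <- gen$covariate_effects[[sc]]
      lp <- lp + ce[["age"]] * features$age +
        ce[["sexF"]] * (features$sex == "F") +
        ce[["sequenceB"]] * (features$sequence == "B")
      sdn <- if (!is.null(gen$noise_sd)) {
        if (length(gen$noise_sd) > 1) gen$noise_sd[[sc]] else gen$noise_sd
      } else {
        s <- sd(lp)
        if (!is.finite(s) || s == 0) 1
        else s * sqrt(1 / gen$target_r2 - 1)
      }
      out[[sc]] <- lp + rnorm(n, 0, sdn)
    }
  })
  out
}
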