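# Assembly of per-subject biomarker vectors, binary injury-presence rules,
# and cohort prevalence as a three-set Venn decomposition.

.metric_short <- c(thickness = "thick", curvature = "curv",
                   sulcal_depth = "depth")

#' Assemble the cohort biomarker table
#'
#' One row per subject: absolute shape z-scores per (cortical region,
#' metric), lesion mL per admissible region and lesion class, enlargement mL
#' per deep grey anatomy, and the age/sex/sequence covariates. Missing
#' biomarker families (e.g. no T2, hence no lesion stage) propagate as NA,
#' never as zero.
#'
#' @param subject_results list; each element needs `id`, `group`, `age`,
#'   `sex`, `sequence`, and optionally `zscores` ([zscore_regions()] output),
#'   `lesions` ([regional_lesion_volumes()] output) and `enlargement`
#'   (named mL vector per deep anatomy).
#' @return data frame, one row per subject.
#' @export
assemble_table <- function(subject_results) {
  rows <- lapply(subject_results, function(s) {
    row <- list(subject_id = s$id, group = s$group, age = s$age,
                sex = s$sex, sequence = s$sequence)
    if (!is.null(s$zscores)) {
      z <- s$zscores
      nm <- paste0("z_", .region_name_of(z$region_id, s$atlas_table), "_",
                   .metric_short[z$metric])
      row[nm] <- z$z
    }
    if (!is.null(s$lesions)) {
      l <- s$lesions
      keep <- l$region_id != 0L
      nm <- paste0(ifelse(l$lesion_class == "wm_lesion", "leswm_", "lesgm_"),
                   l$region_name)
      row[nm[keep]] <- l$volume_ml[keep]
    }
    if (!is.null(s$enlargement))
      row[paste0("enl_", names(s$enlargement))] <- as.numeric(s$enlargement)
    row
  })
  cols <- unique(unlist(lapply(rows, names)))
  feat_cols <- setdiff(cols, c("subject_id", "group", "age", "sex", "sequence"))
  # subjects missing whole families keep NA in those columns
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(cols, names(r))
    r[miss] <- NA
    as.data.frame(r[cols], stringsAsFactors = FALSE)
  }))
  # schema check: feature sets must agree where present (same atlas)
  have <- lapply(rows, function(r) intersect(names(r), feat_cols))
  full <- lengths(have) == length(feat_cols)
  if (any(full) && any(!full)) {
    # allowed: whole-family absence; anything else is a schema error
    fam <- function(x) unique(sub("_.*", "", x))
    for (h in have[!full]) {
      missing <- setdiff(feat_cols, h)
      present_fams <- fam(h)
      missing_fams <- fam(missing)
      if (length(intersect(present_fams, missing_fams)) > 0)
        stop("inconsistent feature sets across subjects (schema error)")
    }
  }
  rownames(out) <- NULL
  out
}

.region_name_of <- function(ids, table) {
  if (is.null(table)) return(sprintf("r%03d", ids))
  table$name[match(ids, table$id)]
}

#' Binary injury classification of one subject
#'
#' Applies the fixed rules: lesion present iff any regional lesion volume
#' exceeds the floor; ventricular enlargement present iff any enlargement
#' volume exceeds the floor; cortical malformation present iff any regional
#' absolute shape z-score exceeds `z_threshold` (2.5). "Greater than 0 mL"
#' is operationalised as greater than one voxel volume so discretisation
#' noise cannot flag injury.
#'
#' @param v one row of the biomarker table (data frame or named list).
#' @param z_threshold malformation threshold on |z|.
#' @param volume_floor_ml volume floor; default one 1 mm^3 voxel (0.001 mL).
#' @return list of three logicals: `has_cortical_malformation`,
#'   `has_lesion`, `has_ventricular_enlargement`.
#' @export
classify_injury <- function(v, z_threshold = 2.5, volume_floor_ml = 0.001) {
  v <- as.list(v)
  nm <- names(v)
  fam <- list(z = grep("^z_", nm, value = TRUE),
              les = grep("^les(wm|gm)_", nm, value = TRUE),
              enl = grep("^enl_", nm, value = TRUE))
  for (f in names(fam)) {
    if (length(fam[[f]]) == 0)
      stop("missing biomarker family: ", f)
    if (anyNA(unlist(v[fam[[f]]])))
      stop("incomplete biomarker family: ", f)
  }
  list(has_cortical_malformation = any(unlist(v[fam$z]) > z_threshold),
       has_lesion = any(unlist(v[fam$les]) > volume_floor_ml),
       has_ventricular_enlargement = any(unlist(v[fam$enl]) > volume_floor_ml))
}

#' Cohort injury prevalence (Venn decomposition)
#'
#' Exact counts of the 8 cells of the three-set Venn diagram (cortical
#' malformation x lesion x enlargement), totals per injury class, and the
#' total injured, with percentages over the full cohort and over patients
#' only.
#'
#' @param profiles list of [classify_injury()] results.
#' @param groups optional character vector ("control"/"patient") aligned with
#'   `profiles` for the patients-only denominator.
#' @return list with `cells` (data frame of the 8 combinations), `totals`,
#'   `n`, `percent` and optionally `percent_patients`.
#' @export
cohort_prevalence <- function(profiles, groups = NULL) {
  n <- length(profiles)
  if (n == 0) stop("empty profile list")
  m <- t(vapply(profiles, function(p) c(
    cortical = p$has_cortical_malformation, lesion = p$has_lesion,
    enlargement = p$has_ventricular_enlargement), logical(3)))
  cells <- expand.grid(cortical = c(FALSE, TRUE), lesion = c(FALSE, TRUE),
                       enlargement = c(FALSE, TRUE))
  cells$count <- apply(cells, 1, function(cl)
    sum(m[, "cortical"] == cl[["cortical"]] & m[, "lesion"] == cl[["lesion"]] &
          m[, "enlargement"] == cl[["enlargement"]]))
  totals <- c(cortical = sum(m[, "cortical"]), lesion = sum(m[, "lesion"]),
              enlargement = sum(m[, "enlargement"]),
              injured = sum(rowSums(m) > 0))
  out <- list(cells = cells, totals = totals, n = n,
              percent = 100 * totals / n)
  if (!is.null(groups)) {
    pm <- m[groups == "patient", , drop = FALSE]
    np <- nrow(pm)
    if (np > 0) {
      tp <- c(cortical = sum(pm[, "cortical"]), lesion = sum(pm[, "lesion"]),
              enlargement = sum(pm[, "enlargement"]),
              injured = sum(rowSums(pm) > 0))
      out$percent_patients <- 100 * tp / np
      out$n_patients <- np
    }
  }
  out
}
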