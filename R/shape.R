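# Cortical shape morphometry: thickness, curvature and sulcal depth maps on
# the cortical surface, regional summaries, and absolute z-scores against a
# normative (control) cohort.

#' Compute cortical shape maps
#'
#' Three voxel-based shape measures on the cortical grey matter:
#' * thickness (mm): symmetric nearest-boundary distance sum — distance to
#'   the WM interface plus distance to the pial interface, minus one voxel to
#'   compensate for centre-to-centre measurement; defined on GM voxels;
#' * curvature: divergence of the normalised gradient of the signed distance
#'   embedding of the pial surface, `div(grad phi / |grad phi|)` (the sum of
#'   principal curvatures; 2/R on a sphere of radius R, units 1/mm).
#'   Optionally the Gaussian curvature (units 1/mm^2) via the adjugate
#'   Hessian formula;
#' * sulcal depth (mm): Euclidean distance below the outer cerebral hull
#'   (morphological closing of the brain tissue mask, ball radius
#'   `hull_radius_mm`), evaluated at pial surface voxels.
#'
#' @param seg segmentation (list with `labels` in [TISSUE_LABELS] codes and
#'   `spacing`), e.g. from [fit_em_mrf()], or a ground-truth label grid
#'   wrapped the same way.
#' @param mask logical brain mask.
#' @param hull_radius_mm closing ball for the sulcal hull.
#' @param gaussian_curvature use Gaussian instead of mean curvature.
#' @return list of maps (`thickness`, `curvature`, `sulcal_depth`), each a
#'   numeric array NA outside its domain, plus `surface` (logical pial
#'   surface voxels) and `spacing`.
#' @export
compute_shape_maps <- function(seg, mask = NULL, hull_radius_mm = 15,
                               gaussian_curvature = FALSE) {
  lab <- seg$labels
  sp <- seg$spacing
  dm <- dim(lab)
  gm <- lab == 3L | lab == 7L
  wm <- lab == 4L | lab == 6L
  if (!any(gm)) stop("no grey matter voxels in segmentation")
  # brain tissue region whose outer boundary is the pial surface; interior
  # CSF (ventricles) is filled so it cannot masquerade as pial surface
  tissue <- fill_holes(gm | wm | lab == 5L)
  exterior <- !tissue
  d_ext <- distance_transform(exterior, sp)
  d_tis <- distance_transform(tissue, sp)
  # pial surface: GM voxels touching the exterior
  surface <- gm & d_ext <= min(sp) + 1e-9

  # thickness on GM: distance to WM interface + distance to pial interface
  d_wm <- distance_transform(wm, sp)
  thickness <- array(NA_real_, dm)
  thickness[gm] <- d_wm[gm] + d_ext[gm] - mean(sp)

  # signed distance embedding of the pial surface (negative inside), mildly
  # smoothed so second derivatives are not dominated by voxelization noise
  phi <- .binomial_smooth(d_tis - d_ext, passes = 2)
  g <- .central_grad(phi, sp)
  gmag <- pmax(sqrt(g$x^2 + g$y^2 + g$z^2), 1e-8)
  curvature <- array(NA_real_, dm)
  if (!gaussian_curvature) {
    kv <- .divergence(g$x / gmag, g$y / gmag, g$z / gmag, sp)
    curvature[surface] <- kv[surface]
  } else {
    H <- .hessian(phi, sp)
    # K = (grad' adj(H) grad) / |grad|^4 for a level-set surface
    a11 <- H$yy * H$zz - H$yz^2
    a22 <- H$xx * H$zz - H$xz^2
    a33 <- H$xx * H$yy - H$xy^2
    a12 <- H$xz * H$yz - H$xy * H$zz
    a13 <- H$xy * H$yz - H$xz * H$yy
    a23 <- H$xy * H$xz - H$xx * H$yz
    num <- g$x^2 * a11 + g$y^2 * a22 + g$z^2 * a33 +
      2 * (g$x * g$y * a12 + g$x * g$z * a13 + g$y * g$z * a23)
    curvature[surface] <- (num / gmag^4)[surface]
  }

  hull <- mask_close(tissue, hull_radius_mm, sp)
  d_hull_out <- distance_transform(!hull, sp)
  depth <- array(NA_real_, dm)
  depth[surface] <- pmax(d_hull_out[surface] - min(sp), 0)

  list(thickness = thickness, curvature = curvature, sulcal_depth = depth,
       surface = surface, spacing = sp)
}

# separable 1-2-1 binomial smoothing
.binomial_smooth <- function(a, passes = 1) {
  for (p in seq_len(passes)) {
    for (ax in 1:3)
      a <- 0.25 * .shift_arr(a, ax, -1) + 0.5 * a + 0.25 * .shift_arr(a, ax, 1)
  }
  a
}

.hessian <- function(a, sp) {
  d2 <- function(ax, s) (.shift_arr(a, ax, 1) - 2 * a + .shift_arr(a, ax, -1)) / s^2
  dxy <- function(a1, a2, s1, s2)
    (.shift_arr(.shift_arr(a, a1, 1), a2, 1) - .shift_arr(.shift_arr(a, a1, 1), a2, -1) -
       .shift_arr(.shift_arr(a, a1, -1), a2, 1) + .shift_arr(.shift_arr(a, a1, -1), a2, -1)) /
    (4 * s1 * s2)
  list(xx = d2(1, sp[1]), yy = d2(2, sp[2]), zz = d2(3, sp[3]),
       xy = dxy(1, 2, sp[1], sp[2]), xz = dxy(1, 3, sp[1], sp[3]),
       yz = dxy(2, 3, sp[2], sp[3]))
}

#' Summarize shape maps per cortical atlas region
#'
#' Mean of each map over the pial surface voxels of each cortical region.
#' Regions with fewer than `min_voxels` surface voxels are flagged
#' unreliable (value still reported).
#'
#' @param maps output of [compute_shape_maps()].
#' @param atlas region atlas (list with `labels`, `table`).
#' @param min_voxels reliability floor on surface voxel count.
#' @return data frame (region_id, region_name, metric, value, n_voxels,
#'   reliable).
#' @export
summarize_regions <- function(maps, atlas, min_voxels = 20) {
  cort <- atlas$table[atlas$table$class == "cortical", ]
  if (nrow(cort) == 0) stop("atlas has no cortical regions")
  rows <- list()
  for (i in seq_len(nrow(cort))) {
    rid <- cort$id[i]
    on_surf <- maps$surface & atlas$labels == rid
    n <- sum(on_surf)
    for (metric in c("thickness", "curvature", "sulcal_depth")) {
      v <- maps[[metric]][on_surf]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1]] <- data.frame(
        region_id = rid, region_name = cort$name[i], metric = metric,
        value = if (length(v) > 0) mean(v) else NA_real_,
        n_voxels = n, reliable = n >= min_voxels, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Normative statistics from control summaries
#'
#' Per (region, metric) sample mean and sd (denominator n - 1) across the
#' control cohort.
#'
#' @param control_summaries list of [summarize_regions()] data frames.
#' @param min_controls minimum cohort size (default 10).
#' @return data frame (region_id, metric, mean, sd, n_controls).
#' @export
build_normative_stats <- function(control_summaries, min_controls = 10) {
  if (length(control_summaries) < min_controls)
    stop(sprintf("insufficient normative cohort: %d controls < %d required",
                 length(control_summaries), min_controls))
  all <- do.call(rbind, lapply(seq_along(control_summaries), function(i) {
    s <- control_summaries[[i]]
    s$subject <- i
    s
  }))
  agg <- aggregate(value ~ region_id + metric, data = all,
                   FUN = function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  data.frame(region_id = agg$region_id, metric = agg$metric,
             mean = agg$value[, "mean"], sd = agg$value[, "sd"],
             n_controls = agg$value[, "n"], stringsAsFactors = FALSE)
}

#' Absolute regional shape z-scores
#'
#' `|z| = |x - mu| / sigma` per (region, metric) against the normative
#' statistics. Absolute values make all shape biomarkers non-negative with
#' "larger = more abnormal", aligning them with the volumetric injury
#' biomarkers and the sign-constrained regression.
#'
#' @param summary a patient's [summarize_regions()] data frame.
#' @param norm a [build_normative_stats()] data frame.
#' @return data frame (region_id, metric, value, z).
#' @export
zscore_regions <- function(summary, norm) {
  key <- paste(summary$region_id, summary$metric)
  nkey <- paste(norm$region_id, norm$metric)
  m <- match(key, nkey)
  if (anyNA(m)) stop("missing normative entry for some (region, metric)")
  mu <- norm$mean[m]
  sg <- norm$sd[m]
  if (any(!is.na(sg) & sg <= 0))
    stop("degenerate normative sd (controls identical) for some region")
  data.frame(region_id = summary$region_id, metric = summary$metric,
             value = summary$value, z = abs(summary$value - mu) / sg,
             reliable = summary$reliable, stringsAsFactors = FALSE)
}
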