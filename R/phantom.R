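# Synthetic brain phantom generator.
#
# The anatomy is a sulcated ellipsoid shell model: concentric skull / CSF /
# cortical grey-matter ribbon / white matter with two ventricular cavities and
# a deep grey matter shell around each ventricle. It is not a template brain:
# the downstream methods need tissue interfaces, regional labels and injuries
# with known ground truth, not anatomical realism.

#' Tissue label codes used in ground-truth label grids
#' @export
TISSUE_LABELS <- c(background = 0L, skull = 1L, csf = 2L, gm = 3L, wm = 4L,
                   ventricle = 5L, wm_lesion = 6L, gm_lesion = 7L)

#' Phantom geometry configuration
#'
#' @param grid_shape voxels per axis (length 3).
#' @param spacing_mm voxel size in mm.
#' @param brain_radii_mm ellipsoid semi-axes of the pial surface (mm).
#' @param gm_thickness_mm cortical ribbon width (mm), > 0.
#' @param sulci list with `amplitude_mm`, `wavelength_mm` and optionally
#'   `sectors` (cortical sector indices to perturb; NULL = all).
#' @param skull_thickness_mm,csf_thickness_mm shell widths (mm).
#' @param ventricle_radii_mm list with `left` and `right` length-3 semi-axes.
#' @param ventricle_offset_mm centre offset (mm) of each ventricle from the
#'   brain centre; mirrored in x across sides.
#' @param deep_gm_thickness_mm width of the deep grey shell around ventricles.
#' @param n_cortical_sectors number of cortical atlas regions (multiple of 8).
#' @param seed integer seed (stored; anatomy itself is deterministic).
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(96, 96, 96),
                           spacing_mm = c(1, 1, 1),
                           brain_radii_mm = c(30, 36, 28),
                           gm_thickness_mm = 3,
                           sulci = list(amplitude_mm = 3, wavelength_mm = 30,
                                        sectors = NULL),
                           skull_thickness_mm = 3,
                           csf_thickness_mm = 2,
                           ventricle_radii_mm = list(left = c(6, 11, 7),
                                                     right = c(6, 11, 7)),
                           ventricle_offset_mm = c(11, -4, 0),
                           deep_gm_thickness_mm = 5,
                           n_cortical_sectors = 8,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3, length(brain_radii_mm) == 3)
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3)
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  if (gm_thickness_mm <= 0) stop("gm_thickness_mm must be positive")
  if (is.null(sulci$amplitude_mm)) sulci$amplitude_mm <- 0
  if (is.null(sulci$wavelength_mm)) sulci$wavelength_mm <- 30
  cfg <- list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
              brain_radii_mm = as.numeric(brain_radii_mm),
              gm_thickness_mm = gm_thickness_mm, sulci = sulci,
              skull_thickness_mm = skull_thickness_mm,
              csf_thickness_mm = csf_thickness_mm,
              ventricle_radii_mm = ventricle_radii_mm,
              ventricle_offset_mm = as.numeric(ventricle_offset_mm),
              deep_gm_thickness_mm = deep_gm_thickness_mm,
              n_cortical_sectors = as.integer(n_cortical_sectors),
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  # grid must hold brain + CSF + skull + sulcal crests with a 2-voxel margin
  half_fov <- grid_shape * spacing_mm / 2
  need <- max(brain_radii_mm) + sulci$amplitude_mm + csf_thickness_mm +
    skull_thickness_mm + 2 * max(spacing_mm)
  if (need > min(half_fov))
    stop(sprintf("grid too small: anatomy needs %.1f mm half-extent, grid provides %.1f mm",
                 need, min(half_fov)))
  cfg
}

# angular sector index from azimuth/elevation, used for cortical + WM atlas
.angular_sector <- function(theta, elev, n_azim, n_elev) {
  a <- pmin(n_azim, 1L + floor((theta + pi) / (2 * pi / n_azim)))
  e <- pmin(n_elev, 1L + floor((elev + pi / 2) / (pi / n_elev)))
  (e - 1L) * n_azim + a
}

#' Build phantom anatomy with ground truth
#'
#' Constructs the tissue label grid and region atlas for one subject. The
#' pial surface is an ellipsoid perturbed by a sinusoidal undulation (the
#' "sulci"), the grey ribbon has constant thickness measured from the pial
#' surface, two ellipsoidal ventricles are carved from the white matter, and
#' a deep grey shell surrounds each ventricle. The atlas partitions cortical
#' GM into angular sectors, WM into quadrants, and the deep grey shell into
#' four anatomies (anterior/posterior x left/right).
#'
#' @param config a [phantom_config()].
#' @return a `ground_truth` list: `labels` (integer array), `atlas`
#'   (`labels` array + `table` data frame), `spacing`, `config`, plus true
#'   injury tallies (all zero for a freshly built control).
#' @export
build_anatomy <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  dm <- config$grid_shape
  sp <- config$spacing_mm
  co <- voxel_coords_mm(dm, sp)
  a <- config$brain_radii_mm
  abar <- mean(a)

  rho <- sqrt((co$x / a[1])^2 + (co$y / a[2])^2 + (co$z / a[3])^2)
  r3 <- sqrt(co$x^2 + co$y^2 + co$z^2)
  theta <- atan2(co$y, co$x)
  elev <- asin(pmin(1, pmax(-1, co$z / pmax(r3, 1e-9))))

  amp <- config$sulci$amplitude_mm
  wl <- config$sulci$wavelength_mm
  n_cort <- config$n_cortical_sectors
  n_azim <- max(4L, n_cort %/% 2L)
  n_elev <- n_cort %/% n_azim
  sector <- .angular_sector(theta, elev, n_azim, n_elev)
  if (amp > 0) {
    # separable cosine undulation: smooth, mirror-symmetric in every axis
    g <- cos(2 * pi * co$x / wl) * cos(2 * pi * co$y / wl) *
      cos(2 * pi * co$z / wl)
    if (!is.null(config$sulci$sectors))
      g <- g * (sector %in% config$sulci$sectors)
    rho_eff <- rho + (amp / abar) * g
  } else rho_eff <- rho

  pial <- rho_eff <= 1                      # brain interior incl. everything inside pia
  dist_in <- distance_transform(!pial, sp)  # mm to the nearest exterior voxel centre
  # half-voxel offset: a voxel whose centre sits k mm from the nearest exterior
  # centre lies k - spacing/2 mm below the pial boundary
  wm <- pial & dist_in >= config$gm_thickness_mm + min(sp) / 2
  gm <- pial & !wm

  # ventricles carved from WM, deep grey shell around them (GM tissue class)
  off <- config$ventricle_offset_mm
  vent <- array(FALSE, dm)
  vent_side <- array(0L, dm)                # 1 = left (x < 0), 2 = right
  for (s in 1:2) {
    rv <- config$ventricle_radii_mm[[if (s == 1) "left" else "right"]]
    cx <- c(if (s == 1) -off[1] else off[1], off[2], off[3])
    vmask <- ((co$x - cx[1]) / rv[1])^2 + ((co$y - cx[2]) / rv[2])^2 +
      ((co$z - cx[3]) / rv[3])^2 <= 1
    vmask <- vmask & wm
    vent <- vent | vmask
    vent_side[vmask] <- s
  }
  dgm <- wm & !vent & (distance_transform(vent, sp) <= config$deep_gm_thickness_mm)
  wm_final <- wm & !vent & !dgm

  dist_out <- distance_transform(pial, sp)
  csf <- !pial & dist_out <= config$csf_thickness_mm
  skull <- !pial & !csf &
    dist_out <= config$csf_thickness_mm + config$skull_thickness_mm

  L <- TISSUE_LABELS
  labels <- array(L[["background"]], dm)
  labels[skull] <- L[["skull"]]
  labels[csf] <- L[["csf"]]
  labels[gm] <- L[["gm"]]
  labels[dgm] <- L[["gm"]]
  labels[wm_final] <- L[["wm"]]
  labels[vent] <- L[["ventricle"]]

  # ---- atlas ----
  atlas <- array(0L, dm)
  rows <- list()
  # cortical sectors on the GM ribbon
  for (k in seq_len(n_cort)) {
    m <- gm & sector == k
    atlas[m] <- 100L + k
    rows[[length(rows) + 1]] <- data.frame(
      id = 100L + k, name = sprintf("ctx_%02d", k), class = "cortical")
  }
  # WM quadrants (azimuth)
  wsec <- .angular_sector(theta, elev, 4L, 1L)
  for (k in 1:4) {
    m <- wm_final & wsec == k
    atlas[m] <- 200L + k
    rows[[length(rows) + 1]] <- data.frame(
      id = 200L + k, name = sprintf("wm_%02d", k), class = "white-matter")
  }
  # deep grey anatomies: side x anterior/posterior
  dnames <- c("dgm_left_ant", "dgm_left_post", "dgm_right_ant", "dgm_right_post")
  dside <- ifelse(co$x < 0, 1L, 2L)
  dant <- ifelse(co$y >= off[2], 1L, 2L)
  dk <- (dside - 1L) * 2L + dant
  for (k in 1:4) {
    m <- dgm & dk == k
    atlas[m] <- 300L + k
    rows[[length(rows) + 1]] <- data.frame(
      id = 300L + k, name = dnames[k], class = "deep-grey")
  }
  atlas[vent & vent_side == 1L] <- 401L
  atlas[vent & vent_side == 2L] <- 402L
  rows[[length(rows) + 1]] <- data.frame(id = 401L, name = "vent_left", class = "ventricle")
  rows[[length(rows) + 1]] <- data.frame(id = 402L, name = "vent_right", class = "ventricle")
  table <- do.call(rbind, rows)

  cort_ids <- table$id[table$class == "cortical"]
  truth <- list(
    labels = labels,
    atlas = list(labels = atlas, table = table),
    spacing = sp,
    config = config,
    lesions = list(),
    true_lesion_ml = setNames(
      numeric(nrow(table)), as.character(table$id)),
    true_enlargement_ml = c(left = 0, right = 0),
    true_thickness_mm = setNames(
      rep(config$gm_thickness_mm, length(cort_ids)), as.character(cort_ids)),
    thinning_scale = setNames(rep(1, length(cort_ids)), as.character(cort_ids)))
  class(truth) <- "ground_truth"
  truth
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %s voxels, %d atlas regions, %d lesions, enlargement %.2f/%.2f mL>\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$atlas$table),
              length(x$lesions), x$true_enlargement_ml[["left"]],
              x$true_enlargement_ml[["right"]]))
  invisible(x)
}

#' Injury specification
#'
#' @param lesions list of lesions, each a list with `center_mm` (length-3, in
#'   the grid-centred world frame), `radius_mm`, `tissue` ("WM" or "GM") and
#'   `contrast` (named multiplicative intensity factors, e.g.
#'   `c(T1 = 0.75, T2 = 1.6)`).
#' @param ventricle_enlargement list per side (`left`/`right`) with
#'   `added_ml` >= 0 and optionally `direction` (length-3 growth preference).
#' @param cortical_thinning list of lists with `region_id` (a cortical atlas
#'   id) and `thickness_scale` in (0, 2].
#' @param seed integer seed.
#' @return an `injury_spec` list.
#' @export
injury_spec <- function(lesions = list(), ventricle_enlargement = list(),
                        cortical_thinning = list(), seed = 1L) {
  for (l in lesions) {
    if (l$radius_mm <= 0) stop("lesion radius must be positive")
    if (!l$tissue %in% c("WM", "GM")) stop("lesion tissue must be WM or GM")
  }
  for (v in ventricle_enlargement)
    if (v$added_ml < 0) stop("added volume must be >= 0")
  for (th in cortical_thinning)
    if (th$thickness_scale <= 0 || th$thickness_scale > 2)
      stop("thickness_scale must lie in (0, 2]")
  structure(list(lesions = lesions,
                 ventricle_enlargement = ventricle_enlargement,
                 cortical_thinning = cortical_thinning, seed = as.integer(seed)),
            class = "injury_spec")
}

#' Inject injuries into a ground-truth phantom
#'
#' Applies focal lesions (spheres relabelled within their host tissue),
#' ventricular enlargement (the ventricle mask grows outward through white and
#' deep grey matter, preferring the requested direction, until the added
#' volume is reached), and cortical thinning (the ribbon of a named region is
#' rescaled by removing its outer layer to CSF). All true-volume tallies are
#' updated from voxel counts.
#'
#' @param truth a `ground_truth` from [build_anatomy()].
#' @param spec an [injury_spec()].
#' @return the modified `ground_truth`.
#' @export
inject_injuries <- function(truth, spec) {
  stopifnot(inherits(truth, "ground_truth"), inherits(spec, "injury_spec"))
  L <- TISSUE_LABELS
  dm <- dim(truth$labels)
  sp <- truth$spacing
  vox_ml <- voxel_volume_mm3(sp) / 1000
  co <- voxel_coords_mm(dm, sp)

  # ---- focal lesions ----
  for (l in spec$lesions) {
    host <- if (l$tissue == "WM") L[["wm"]] else L[["gm"]]
    ci <- round(l$center_mm / sp + (dm + 1) / 2)
    if (any(ci < 1 | ci > dm)) stop("lesion center outside the grid")
    if (truth$labels[ci[1], ci[2], ci[3]] != host)
      stop(sprintf("lesion center is not inside %s tissue", l$tissue))
    sph <- (co$x - l$center_mm[1])^2 + (co$y - l$center_mm[2])^2 +
      (co$z - l$center_mm[3])^2 <= l$radius_mm^2
    m <- sph & truth$labels == host
    new_lab <- if (l$tissue == "WM") L[["wm_lesion"]] else L[["gm_lesion"]]
    truth$labels[m] <- new_lab
    idx <- which(m)
    truth$lesions[[length(truth$lesions) + 1]] <-
      list(voxels = idx, tissue = l$tissue, contrast = l$contrast)
    reg <- truth$atlas$labels[idx]
    tb <- table(reg[reg > 0])
    for (rid in names(tb))
      truth$true_lesion_ml[rid] <- truth$true_lesion_ml[rid] +
        as.numeric(tb[[rid]]) * vox_ml
  }

  # ---- ventricular enlargement ----
  for (side in names(spec$ventricle_enlargement)) {
    ve <- spec$ventricle_enlargement[[side]]
    if (ve$added_ml <= 0) next
    side_id <- if (side == "left") 401L else 402L
    vmask <- truth$atlas$labels == side_id & truth$labels == L[["ventricle"]]
    if (!any(vmask)) stop("no ventricle voxels on side ", side)
    allowed <- truth$labels == L[["wm"]] |
      (truth$labels == L[["gm"]] &
         truth$atlas$table$class[match(truth$atlas$labels, truth$atlas$table$id)] == "deep-grey")
    allowed[is.na(allowed)] <- FALSE
    d <- distance_transform(vmask, sp)
    cand <- which(allowed & is.finite(d) & d > 0)
    n_need <- round(ve$added_ml / vox_ml)
    if (n_need > length(cand)) stop("not enough adjacent tissue to enlarge into")
    dirv <- if (!is.null(ve$direction)) ve$direction / sqrt(sum(ve$direction^2)) else c(0, -1, 0)
    ctr <- c(mean(co$x[vmask]), mean(co$y[vmask]), mean(co$z[vmask]))
    rel <- cbind(co$x[cand] - ctr[1], co$y[cand] - ctr[2], co$z[cand] - ctr[3])
    pref <- rel %*% dirv / pmax(sqrt(rowSums(rel^2)), 1e-9)
    layer <- ceiling(d[cand] / min(sp) - 1e-9)
    ord <- order(layer, -pref)
    take <- cand[ord[seq_len(n_need)]]
    truth$labels[take] <- L[["ventricle"]]
    truth$atlas$labels[take] <- side_id
    truth$true_enlargement_ml[[side]] <-
      truth$true_enlargement_ml[[side]] + n_need * vox_ml
  }

  # ---- cortical thinning ----
  if (length(spec$cortical_thinning) > 0) {
    interior <- fill_holes(arr_in(truth$labels,
                                  c(L[["gm"]], L[["wm"]], L[["ventricle"]],
                                    L[["wm_lesion"]], L[["gm_lesion"]])))
    dist_in <- distance_transform(!interior, sp)
    for (th in spec$cortical_thinning) {
      rid <- as.character(th$region_id)
      cls <- truth$atlas$table$class[truth$atlas$table$id == th$region_id]
      if (length(cls) != 1 || cls != "cortical")
        stop("thinning region_id must be a cortical atlas region")
      t0 <- truth$true_thickness_mm[[rid]]
      # feather the cut towards the sector boundary (taper 6 mm) so thinning
      # does not leave a cliff that contaminates neighbouring regions' shape;
      # the taper distance is measured to the other cortical sectors, i.e.
      # along the ribbon, not through it
      region <- truth$atlas$labels == th$region_id
      tb <- truth$atlas$table
      cort_ids <- tb$id[tb$class == "cortical"]
      others <- arr_in(truth$atlas$labels, setdiff(cort_ids, th$region_id))
      d_edge <- distance_transform(others, sp)
      # smoothstep taper beginning 4 mm inside the sector: the measurement
      # kernel of neighbouring sectors never touches altered surface
      tt <- pmin(1, pmax(0, (d_edge - 4) / 8))
      ramp <- tt * tt * (3 - 2 * tt)
      cut <- (1 - th$thickness_scale) * t0 * ramp + min(sp) / 2
      m <- truth$labels == L[["gm"]] & region & dist_in <= cut - 1e-9
      truth$labels[m] <- L[["csf"]]
      truth$atlas$labels[m] <- 0L
      truth$true_thickness_mm[[rid]] <- t0 * th$thickness_scale
      truth$thinning_scale[[rid]] <- th$thickness_scale
    }
  }
  truth
}

#' Acquisition specification
#'
#' Per-tissue mean MR intensities for T1- and T2-like contrasts, a smooth
#' multiplicative polynomial bias field, and Rician noise.
#'
#' @param tissue_means named list mapping tissue names (background, skull,
#'   csf, gm, wm, ventricle, wm_lesion, gm_lesion) to `c(T1 =, T2 =)` means.
#' @param bias_order polynomial order of the bias field.
#' @param bias_amplitude peak fractional deviation of the bias field, in
#'   `[0, 0.5]`.
#' @param noise_sigma named Rician sigma per modality, `c(T1 =, T2 =)`.
#' @param seed integer seed controlling bias coefficients and noise.
#' @return an `acquisition_spec` list.
#' @export
acquisition_spec <- function(tissue_means = default_tissue_means(),
                             bias_order = 2, bias_amplitude = 0.15,
                             noise_sigma = c(T1 = 4.5, T2 = 3.5),
                             seed = 1L) {
  if (bias_amplitude < 0 || bias_amplitude > 0.5)
    stop("bias_amplitude must lie in [0, 0.5]")
  if (any(noise_sigma < 0)) stop("noise_sigma must be >= 0")
  if (any(unlist(tissue_means) <= 0)) stop("tissue means must be positive")
  structure(list(tissue_means = tissue_means, bias_order = bias_order,
                 bias_amplitude = bias_amplitude, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Default tissue mean intensities
#'
#' T1-like contrast: WM > GM > CSF, skull moderately bright, dark background.
#' T2-like contrast: CSF bright, WM dark. Lesions default to T2-hyperintense
#' relative to their host tissue (their per-lesion contrast in the
#' [injury_spec()] overrides these).
#' @return named list of `c(T1 =, T2 =)` intensity pairs.
#' @export
default_tissue_means <- function() {
  list(background = c(T1 = 5, T2 = 5),
       skull = c(T1 = 35, T2 = 25),
       csf = c(T1 = 25, T2 = 95),
       gm = c(T1 = 70, T2 = 65),
       wm = c(T1 = 90, T2 = 45),
       ventricle = c(T1 = 25, T2 = 95),
       wm_lesion = c(T1 = 76.5, T2 = 85.5),
       gm_lesion = c(T1 = 56, T2 = 84.5))
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# smooth random polynomial bias field, unit mean over the brain, peak
# deviation = amplitude
.bias_field <- function(dm, sp, order, amplitude, brain) {
  if (amplitude <= 0 || order < 1) return(array(1, dm))
  co <- voxel_coords_mm(dm, sp)
  half <- dm * sp / 2
  u <- co$x / half[1]; v <- co$y / half[2]; w <- co$z / half[3]
  field <- array(0, dm)
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j)) {
    if (i + j + k == 0) next
    field <- field + rnorm(1) * u^i * v^j * w^k
  }
  field <- field - mean(field[brain])
  mx <- max(abs(field[brain]))
  if (mx < 1e-12) return(array(1, dm))
  1 + amplitude * field / mx
}

#' Simulate T1- and T2-like MR volumes from a phantom
#'
#' Each voxel takes its tissue mean intensity, is modulated by a smooth
#' multiplicative bias field, and is corrupted by Rician noise
#' `sqrt((s + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma)` — the magnitude-MRI
#' noise model, approximately Gaussian at high SNR. Deterministic given the
#' acquisition seed.
#'
#' @param truth a `ground_truth`.
#' @param acq an [acquisition_spec()].
#' @return list with `t1` and `t2` [image_volume()]s and the `bias` fields.
#' @export
simulate_mri <- function(truth, acq) {
  stopifnot(inherits(truth, "ground_truth"), inherits(acq, "acquisition_spec"))
  L <- TISSUE_LABELS
  dm <- dim(truth$labels)
  sp <- truth$spacing
  need <- names(L)
  missing <- setdiff(need[match(unique(as.vector(truth$labels)), L)], names(acq$tissue_means))
  if (length(missing) > 0)
    stop("missing tissue intensity for: ", paste(missing, collapse = ", "))
  brain <- truth$labels != L[["background"]] & truth$labels != L[["skull"]]

  with_seed(acq$seed, {
    out <- list()
    for (mod in c("T1", "T2")) {
      s <- array(0, dm)
      for (nm in names(acq$tissue_means))
        if (nm %in% names(L))
          s[truth$labels == L[[nm]]] <- acq$tissue_means[[nm]][[mod]]
      # per-lesion multiplicative contrast on the host tissue mean
      for (les in truth$lesions) {
        host_mean <- acq$tissue_means[[tolower(les$tissue)]][[mod]]
        ctr <- if (mod %in% names(les$contrast)) les$contrast[[mod]] else 1
        keep <- les$voxels[truth$labels[les$voxels] %in%
                             c(L[["wm_lesion"]], L[["gm_lesion"]])]
        s[keep] <- host_mean * ctr
      }
      bias <- .bias_field(dm, sp, acq$bias_order, acq$bias_amplitude, brain)
      s <- s * bias
      sg <- acq$noise_sigma[[mod]]
      if (sg > 0) {
        n1 <- array(rnorm(length(s), 0, sg), dm)
        n2 <- array(rnorm(length(s), 0, sg), dm)
        s <- sqrt((s + n1)^2 + n2^2)
      }
      out[[mod]] <- list(img = image_volume(s, sp, mod), bias = bias)
    }
    list(t1 = out$T1$img, t2 = out$T2$img,
         bias = list(T1 = out$T1$bias, T2 = out$T2$bias))
  })
}

#' Tissue prior probability maps from a template anatomy
#'
#' Builds spatially varying CSF/GM/WM prior maps from a reference label grid
#' (the phantom template plays the role of a registered atlas): a soft
#' distance-based kernel around each tissue class, floored and normalised per
#' voxel. Ventricle voxels contribute to the CSF prior.
#'
#' @param truth a `ground_truth` used as template.
#' @param sigma_mm kernel width of the prior softening.
#' @param floor minimum prior mass per class (keeps likelihood decisive where
#'   the template disagrees with the subject).
#' @return named list of prior arrays (`csf`, `gm`, `wm`) summing to 1.
#' @export
make_tissue_priors <- function(truth, sigma_mm = 2.5, floor = 0.01) {
  L <- TISSUE_LABELS
  sp <- truth$spacing
  csf <- arr_in(truth$labels, c(L[["csf"]], L[["ventricle"]]))
  gm <- arr_in(truth$labels, c(L[["gm"]], L[["gm_lesion"]]))
  wm <- arr_in(truth$labels, c(L[["wm"]], L[["wm_lesion"]]))
  pr <- list(csf = soft_prior_from_mask(csf, sigma_mm, sp) + floor,
             gm = soft_prior_from_mask(gm, sigma_mm, sp) + floor,
             wm = soft_prior_from_mask(wm, sigma_mm, sp) + floor)
  tot <- pr$csf + pr$gm + pr$wm
  lapply(pr, function(p) p / tot)
}
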