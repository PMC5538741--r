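# Statistical shape model (SSM) of healthy lateral ventricles: signed
# distance fields on a common grid, PCA shape space from controls, and
# localized enlargement as the volume outside the nearest healthy shape
# within the model's variability envelope.

#' Common bounding box around the ventricle atlas regions
#'
#' Index ranges of the atlas ventricle labels dilated by a margin, shared by
#' all subjects of a cohort (phantoms live in one spatial frame).
#'
#' @param atlas region atlas of the template subject.
#' @param spacing voxel spacing mm.
#' @param margin_mm extra margin around the ventricle labels.
#' @return list of three integer index vectors (`i`, `j`, `k`).
#' @export
ventricle_box <- function(atlas, spacing, margin_mm = 10) {
  m <- arr_in(atlas$labels, c(401L, 402L))
  if (!any(m)) stop("atlas has no ventricle labels")
  dm <- dim(atlas$labels)
  co <- which(m, arr.ind = TRUE)
  pad <- ceiling(margin_mm / spacing)
  lo <- pmax(1L, apply(co, 2, min) - pad)
  hi <- pmin(dm, apply(co, 2, max) + pad)
  list(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
}

#' Extract a ventricle shape as a signed distance field
#'
#' The ventricle mask is taken as CSF-labelled voxels inside the dilated
#' ventricle atlas region of the requested side (largest connected
#' component), then converted to a signed Euclidean distance field (negative
#' inside) and cropped to the common bounding box.
#'
#' @param seg segmentation (list with `labels`, `spacing`) — hard labels in
#'   [TISSUE_LABELS] codes (ventricle voxels are segmented as CSF).
#' @param atlas region atlas on the same grid.
#' @param side "left" or "right".
#' @param box common box from [ventricle_box()].
#' @param dilate_vox dilation (voxels) of the atlas region when collecting
#'   candidate CSF voxels.
#' @param subject_id optional id carried along.
#' @return a `ventricle_shape` list: `field` (cropped signed distance, mm),
#'   `box`, `side`, `volume_ml`, `subject_id`.
#' @export
extract_ventricle_shape <- function(seg, atlas, side = c("left", "right"),
                                    box, dilate_vox = 3, subject_id = NA) {
  side <- match.arg(side)
  sp <- seg$spacing
  sid <- if (side == "left") 401L else 402L
  region <- atlas$labels == sid
  if (!any(region)) stop("atlas has no ventricle region on side ", side)
  cand <- mask_dilate(region, dilate_vox * min(sp), sp)
  vm <- (seg$labels == 2L) & cand
  if (!any(vm)) stop("ventricle extraction failure: no CSF voxels in region")
  vm <- largest_component(vm)
  sdf <- distance_transform(vm, sp) - distance_transform(!vm, sp)
  structure(list(field = sdf[box$i, box$j, box$k], box = box, side = side,
                 volume_ml = sum(vm) * voxel_volume_mm3(sp) / 1000,
                 spacing = sp, subject_id = subject_id),
            class = "ventricle_shape")
}

#' Build the PCA statistical shape model from control shapes
#'
#' PCA of the centred signed-distance-field vectors. The smallest number of
#' modes reaching `variance_to_retain` of the total variance is kept.
#' Eigenvector sign is fixed so each mode's largest-magnitude component is
#' positive, making the model deterministic.
#'
#' @param controls list of `ventricle_shape`s (one side).
#' @param variance_to_retain fraction of variance kept (default 0.95).
#' @param min_controls minimum training shapes.
#' @return a `ventricle_ssm`: `mean`, `basis` (p x k), `evals` (descending),
#'   `all_evals`, `var_frac`, `n_train`, `box`, `side`, `spacing`.
#' @export
build_ssm <- function(controls, variance_to_retain = 0.95, min_controls = 10) {
  if (length(controls) < min_controls)
    stop(sprintf("insufficient training shapes: %d < %d", length(controls),
                 min_controls))
  side <- controls[[1]]$side
  X <- do.call(rbind, lapply(controls, function(s) as.numeric(s$field)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  evals <- sv$d^2 / (nrow(X) - 1)
  tot <- sum(evals)
  if (tot < 1e-12) {
    k <- 0L
  } else {
    k <- which(cumsum(evals) / tot >= variance_to_retain - 1e-12)[1]
  }
  basis <- if (k > 0) sv$v[, seq_len(k), drop = FALSE] else
    matrix(0, ncol(X), 0)
  if (k > 0) for (j in seq_len(k)) {
    i_max <- which.max(abs(basis[, j]))
    if (basis[i_max, j] < 0) basis[, j] <- -basis[, j]
  }
  structure(list(mean = mu, basis = basis,
                 evals = if (k > 0) evals[seq_len(k)] else numeric(0),
                 all_evals = evals,
                 var_frac = if (tot > 0 && k > 0) sum(evals[seq_len(k)]) / tot else 1,
                 n_train = nrow(X), box = controls[[1]]$box, side = side,
                 spacing = controls[[1]]$spacing),
            class = "ventricle_ssm")
}

#' Reconstruct the nearest healthy ventricle shape
#'
#' Projects the centred patient field onto the retained modes and clamps
#' each coefficient to +/- 3 sqrt(eigenvalue) — the healthy variability
#' envelope — so the reconstruction is the nearest shape the model considers
#' healthy.
#'
#' @param patient a `ventricle_shape`.
#' @param model a `ventricle_ssm` on the same box.
#' @return list with `field` (reconstruction array), `coefficients`,
#'   `clamped` (logical per mode).
#' @export
reconstruct_healthy <- function(patient, model) {
  x <- as.numeric(patient$field)
  if (length(x) != length(model$mean)) stop("grid mismatch between patient and model")
  k <- ncol(model$basis)
  if (k == 0) {
    co <- numeric(0); cl <- logical(0)
    rec <- model$mean
  } else {
    co <- as.numeric(crossprod(model$basis, x - model$mean))
    lim <- 3 * sqrt(model$evals)
    cl <- abs(co) > lim
    co <- pmin(pmax(co, -lim), lim)
    rec <- model$mean + as.numeric(model$basis %*% co)
  }
  list(field = array(rec, dim(patient$field)), coefficients = co, clamped = cl)
}

#' Localize ventricular enlargement and attribute it to deep grey anatomies
#'
#' The enlargement mask is the set of voxels inside the patient ventricle
#' (field < 0) but outside the healthy reconstruction (field >= 0). Each
#' enlargement voxel is attributed to the nearest deep grey matter anatomy,
#' so the per-anatomy volumes partition the total exactly.
#'
#' @param patient a `ventricle_shape`.
#' @param reconstruction output of [reconstruct_healthy()].
#' @param atlas region atlas (full grid; cropped internally to the box).
#' @return list: `total_ml`, `by_anatomy` (named mL vector), `mask`
#'   (logical array on the box), `side`.
#' @export
localize_enlargement <- function(patient, reconstruction, atlas) {
  box <- patient$box
  sp <- patient$spacing
  enl <- patient$field < 0 & reconstruction$field >= 0
  vox_ml <- voxel_volume_mm3(sp) / 1000
  total <- sum(enl) * vox_ml
  dg <- atlas$table[atlas$table$class == "deep-grey", ]
  by <- setNames(numeric(nrow(dg)), dg$name)
  if (total > 0 && nrow(dg) > 0) {
    sub <- atlas$labels[box$i, box$j, box$k]
    dist_k <- sapply(seq_len(nrow(dg)), function(i) {
      m <- sub == dg$id[i]
      if (!any(m)) return(rep(Inf, sum(enl)))
      distance_transform(m, sp)[enl]
    })
    dist_k <- matrix(dist_k, nrow = sum(enl))
    nearest <- max.col(-dist_k, ties.method = "first")
    tb <- tabulate(nearest, nbins = nrow(dg))
    by[] <- tb * vox_ml
  }
  list(total_ml = total, by_anatomy = by, mask = enl, side = patient$side)
}

#' Leave-one-out reconstruction residual of an SSM
#'
#' For each control, builds the model on the remaining shapes, reconstructs
#' the held-out shape and measures the volume of the symmetric difference
#' between the held-out ventricle and its reconstruction.
#'
#' @param shapes list of `ventricle_shape`s (one side), length > min_controls.
#' @param variance_to_retain passed to [build_ssm()].
#' @return list: `residual_ml` per shape, `mean_volume_ml`,
#'   `relative_residual` (mean residual / mean volume).
#' @export
ssm_loo_residual <- function(shapes, variance_to_retain = 0.95) {
  n <- length(shapes)
  vox_ml <- voxel_volume_mm3(shapes[[1]]$spacing) / 1000
  res <- numeric(n)
  for (i in seq_len(n)) {
    m <- build_ssm(shapes[-i], variance_to_retain,
                   min_controls = min(10, n - 1))
    rec <- reconstruct_healthy(shapes[[i]], m)
    a <- shapes[[i]]$field < 0
    b <- rec$field < 0
    res[i] <- sum(xor(a, b)) * vox_ml
  }
  mv <- mean(sapply(shapes, function(s) s$volume_ml))
  list(residual_ml = res, mean_volume_ml = mv,
       relative_residual = mean(res) / mv)
}
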