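# Pre-processing chain: affine registration, polynomial bias correction,
# modified-curvature diffusion denoising, percentile intensity normalisation
# and morphology-based skull stripping.

#' Affine (rigid) transform
#'
#' @param matrix 3x3 linear part (must be invertible).
#' @param translation length-3 translation in mm.
#' @return an `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  stopifnot(all(dim(matrix) == c(3, 3)))
  if (abs(det(matrix)) < 1e-12) stop("affine matrix is not invertible")
  structure(list(matrix = matrix, translation = as.numeric(translation)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(cbind(x$matrix, x$translation))
  invisible(x)
}

#' Compose / invert affine transforms
#' @param a,b `affine_transform`s; `compose_affine(a, b)` applies b then a.
#' @return an `affine_transform`.
#' @export
compose_affine <- function(a, b) {
  affine_transform(a$matrix %*% b$matrix,
                   as.vector(a$matrix %*% b$translation) + a$translation)
}

#' @rdname compose_affine
#' @export
invert_affine <- function(a) {
  mi <- solve(a$matrix)
  affine_transform(mi, -as.vector(mi %*% a$translation))
}

# rigid parameters (tx,ty,tz mm, rx,ry,rz degrees) -> affine_transform
.rigid_from_params <- function(p) {
  r <- p[4:6] * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  affine_transform(Rz %*% Ry %*% Rx, p[1:3])
}

#' Rotation angle of a transform, in degrees
#' @param tr an `affine_transform`.
#' @return scalar rotation angle (degrees).
#' @export
rotation_angle_deg <- function(tr) {
  ct <- (sum(diag(tr$matrix)) - 1) / 2
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Resample a moving volume through an affine transform
#'
#' The transform maps fixed-frame world coordinates (mm, grid-centred) to
#' moving-frame world coordinates; resampling is trilinear.
#'
#' @param moving an [image_volume()].
#' @param transform an [affine_transform()].
#' @param fixed_dim,fixed_spacing geometry of the output grid (defaults to
#'   the moving geometry).
#' @param fill value for samples outside the moving volume.
#' @return an [image_volume()] on the fixed grid.
#' @export
apply_affine <- function(moving, transform, fixed_dim = dim(moving$data),
                         fixed_spacing = moving$spacing, fill = 0) {
  dm_m <- dim(moving$data)
  co <- voxel_coords_mm(fixed_dim, fixed_spacing)
  pts <- cbind(as.vector(co$x), as.vector(co$y), as.vector(co$z))
  mm <- pts %*% t(transform$matrix) +
    matrix(transform$translation, nrow(pts), 3, byrow = TRUE)
  # world mm -> 0-based voxel coordinates of the moving grid
  vox <- sweep(sweep(mm, 2, moving$spacing, "/"), 2, (dm_m + 1) / 2 - 1, "+")
  vals <- trilinear_sample_cpp(as.numeric(moving$data), dm_m, vox, fill)
  image_volume(array(vals, fixed_dim), fixed_spacing, moving$modality)
}

# block-mean downsampling by an integer factor
.downsample3 <- function(arr, f) {
  if (f <= 1) return(arr)
  d <- dim(arr)
  nd <- pmax(1L, d %/% f)
  out <- array(0, nd)
  for (i in 0:(f - 1)) for (j in 0:(f - 1)) for (k in 0:(f - 1)) {
    out <- out + arr[seq(1 + i, by = f, length.out = nd[1]),
                     seq(1 + j, by = f, length.out = nd[2]),
                     seq(1 + k, by = f, length.out = nd[3])]
  }
  out / f^3
}

#' Affine registration by multi-resolution intensity matching
#'
#' Estimates the rigid transform (3 translations + 3 rotations) minimising
#' the mean squared intensity difference between the volumes over a
#' coarse-to-fine schedule with Nelder-Mead refinement at each level.
#' The translation is initialised from the intensity centroid offset, both
#' volumes are mildly smoothed per level, and the metric is evaluated on a
#' half-voxel-offset grid through which both images are interpolated — this
#' keeps interpolation blur identical for every candidate transform, so
#' lattice-aligned candidates gain no spurious advantage. Deterministic.
#'
#' @param moving,fixed [image_volume()]s with overlapping fields of view.
#' @param levels downsampling factors, coarse to fine.
#' @param maxit iterations per level.
#' @return an [affine_transform()] mapping fixed world coords to moving.
#' @export
affine_register <- function(moving, fixed, levels = c(4, 2, 1),
                            maxit = c(400, 200, 150)) {
  if (sd(as.numeric(fixed$data)) < 1e-9 || sd(as.numeric(moving$data)) < 1e-9)
    stop("registration failure: flat image(s)")
  com <- function(a, sp) {
    co <- voxel_coords_mm(dim(a), sp)
    w <- a - min(a)
    w <- w / sum(w)
    c(sum(co$x * w), sum(co$y * w), sum(co$z * w))
  }
  par <- c(com(moving$data, moving$spacing) - com(fixed$data, fixed$spacing),
           0, 0, 0)
  for (li in seq_along(levels)) {
    f <- levels[li]
    fx <- .binomial_smooth(.downsample3(fixed$data, f), passes = 2)
    mv <- .binomial_smooth(.downsample3(moving$data, f), passes = 2)
    fsp <- fixed$spacing * f
    msp <- moving$spacing * f
    dmf <- dim(fx)
    dmm <- dim(mv)
    # world coordinates of a half-voxel-offset sampling grid (interior only)
    co <- voxel_coords_mm(dmf, fsp)
    half <- fsp / 2
    keep <- as.vector(
      slice.index(co$x, 1) < dmf[1] & slice.index(co$x, 2) < dmf[2] &
        slice.index(co$x, 3) < dmf[3])
    pts <- cbind(as.vector(co$x) + half[1], as.vector(co$y) + half[2],
                 as.vector(co$z) + half[3])[keep, , drop = FALSE]
    vox_f <- sweep(sweep(pts, 2, fsp, "/"), 2, (dmf + 1) / 2 - 1, "+")
    # out-of-volume samples take the background level (border median), so
    # rotations that sweep corners out of the grid are not penalised
    border <- function(a) {
      d <- dim(a)
      median(c(a[c(1, d[1]), , ], a[, c(1, d[2]), ], a[, , c(1, d[3])]))
    }
    fx_ref <- trilinear_sample_cpp(as.numeric(fx), dmf, vox_f, border(fx))
    fill <- border(mv)
    obj <- function(p) {
      tr <- .rigid_from_params(p)
      mm <- pts %*% t(tr$matrix) +
        matrix(tr$translation, nrow(pts), 3, byrow = TRUE)
      vox <- sweep(sweep(mm, 2, msp, "/"), 2, (dmm + 1) / 2 - 1, "+")
      vals <- trilinear_sample_cpp(as.numeric(mv), dmm, vox, fill)
      mean((vals - fx_ref)^2)
    }
    if (li == 1) {
      # multi-start over a coarse rotation grid: near-symmetric anatomy can
      # trap a single descent in a rotated local minimum
      best <- NULL
      for (rx in c(-6, 0, 6)) for (ry in c(-6, 0, 6)) for (rz in c(-6, 0, 6)) {
        cand <- optim(c(par[1:3], rx, ry, rz), obj, method = "Nelder-Mead",
                      control = list(maxit = 60, reltol = 1e-8,
                                     parscale = c(1, 1, 1, 0.5, 0.5, 0.5)))
        if (is.null(best) || cand$value < best$value) best <- cand
      }
      par <- best$par
    }
    # two NM passes per level: the restart rebuilds the simplex around the
    # first pass's optimum, recovering from premature simplex collapse
    for (pass in 1:2) {
      opt <- optim(par, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit[li], reltol = 1e-10,
                                  parscale = c(1, 1, 1, 0.5, 0.5, 0.5)))
      par <- opt$par
    }
  }
  .rigid_from_params(par)
}

# polynomial basis of normalized coordinates, total degree <= order
.poly_basis <- function(dm, sp, order, idx = NULL) {
  co <- voxel_coords_mm(dm, sp)
  half <- dm * sp / 2
  u <- as.vector(co$x) / half[1]
  v <- as.vector(co$y) / half[2]
  w <- as.vector(co$z) / half[3]
  if (!is.null(idx)) { u <- u[idx]; v <- v[idx]; w <- w[idx] }
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j))
    cols[[length(cols) + 1]] <- u^i * v^j * w^k
  do.call(cbind, cols)
}

#' Correct multiplicative intensity bias
#'
#' Fits a low-order 3D polynomial to log-intensities with iteratively
#' reweighted least squares (Cauchy weights, 10 iterations), divides the
#' fitted field out, and restores the original in-mask mean. The fit is
#' restricted to the in-mask intensities above the 60th percentile
#' (`fit_quantile`), i.e. the WM-dominated tissue: within one tissue the
#' log-intensity residual is exactly the log bias field, whereas fitting
#' across tissues lets the polynomial absorb anatomical contrast. A
#' surrogate for N4-style correction adequate for smooth polynomial bias.
#'
#' @param img an [image_volume()].
#' @param mask logical array, non-empty brain mask.
#' @param order polynomial order (default 3).
#' @param n_iter reweighting iterations.
#' @param fit_quantile in-mask intensity quantile above which voxels enter
#'   the fit.
#' @return bias-corrected [image_volume()].
#' @export
correct_bias <- function(img, mask, order = 3, n_iter = 10,
                         fit_quantile = 0.6) {
  if (!any(mask)) stop("empty mask")
  dm <- dim(img$data)
  idx <- which(mask)
  v <- img$data[idx]
  sub <- idx[v >= quantile(v, fit_quantile)]
  if (length(sub) < 10 * (order + 1)^3) sub <- idx
  y <- log(pmax(img$data[sub], 1e-6))
  X <- .poly_basis(dm, img$spacing, order, sub)
  w <- rep(1, length(y))
  for (it in seq_len(n_iter)) {
    fit <- lm.wfit(X, y, w)
    r <- as.numeric(y - X %*% fit$coefficients)
    s <- max(mad(r), 1e-6)
    w <- 1 / (1 + (r / (2 * s))^2)
  }
  # evaluate the field inside the mask only; voxels outside the brain are
  # irrelevant downstream and pass through unchanged
  Xf <- .poly_basis(dm, img$spacing, order, idx)
  logb <- as.numeric(Xf %*% fit$coefficients)
  logb <- logb - mean(logb)
  out <- img$data
  out[idx] <- img$data[idx] / exp(logb)
  out[idx] <- out[idx] * mean(img$data[idx]) / mean(out[idx])
  image_volume(out, img$spacing, img$modality)
}

# shift an array along one axis with replicated (Neumann) boundaries
.shift_arr <- function(a, axis, by) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  if (axis == 1) a[idx, , , drop = FALSE]
  else if (axis == 2) a[, idx, , drop = FALSE]
  else a[, , idx, drop = FALSE]
}

.central_grad <- function(a, sp) {
  list(x = (.shift_arr(a, 1, 1) - .shift_arr(a, 1, -1)) / (2 * sp[1]),
       y = (.shift_arr(a, 2, 1) - .shift_arr(a, 2, -1)) / (2 * sp[2]),
       z = (.shift_arr(a, 3, 1) - .shift_arr(a, 3, -1)) / (2 * sp[3]))
}

.divergence <- function(fx, fy, fz, sp) {
  (.shift_arr(fx, 1, 1) - .shift_arr(fx, 1, -1)) / (2 * sp[1]) +
    (.shift_arr(fy, 2, 1) - .shift_arr(fy, 2, -1)) / (2 * sp[2]) +
    (.shift_arr(fz, 3, 1) - .shift_arr(fz, 3, -1)) / (2 * sp[3])
}

#' Modified curvature diffusion denoising
#'
#' Explicit iteration of `I <- I + dt * |grad I| * div(c(|grad I|) *
#' grad I / |grad I|)` with the rational conductance
#' `c(g) = 1 / (1 + (g/kappa)^2)`: level sets move by curvature flow
#' modulated by local contrast, smoothing noise while slowing at edges whose
#' gradient exceeds kappa.
#'
#' @param img an [image_volume()].
#' @param iterations number of diffusion steps (0 = identity).
#' @param conductance kappa; defaults to 2x the image intensity sd.
#' @param dt time step; must respect the 3D explicit stability bound 0.0625.
#' @return denoised [image_volume()].
#' @export
denoise_mcde <- function(img, iterations = 5, conductance = NULL, dt = 0.0625) {
  if (dt > 0.0625 + 1e-12) stop("dt exceeds the 3D explicit stability bound (0.0625)")
  if (iterations == 0) return(img)
  kappa <- if (is.null(conductance)) 2 * sd(as.numeric(img$data)) else conductance
  if (kappa <= 0) stop("conductance must be positive")
  a <- img$data
  sp <- img$spacing
  eps <- 1e-8
  for (it in seq_len(iterations)) {
    g <- .central_grad(a, sp)
    gm <- sqrt(g$x^2 + g$y^2 + g$z^2)
    w <- (1 / (1 + (gm / kappa)^2)) / pmax(gm, eps)   # c(|grad I|)/|grad I|
    # face-flux divergence: div(w grad I) with w averaged onto cell faces and
    # one-sided differences. Central differences would be blind to
    # voxel-frequency noise, which is exactly what denoising must remove.
    dv <- 0
    for (ax in 1:3) {
      wp <- 0.5 * (w + .shift_arr(w, ax, 1))
      wm <- 0.5 * (w + .shift_arr(w, ax, -1))
      dv <- dv + (wp * (.shift_arr(a, ax, 1) - a) -
                    wm * (a - .shift_arr(a, ax, -1))) / sp[ax]^2
    }
    a <- a + dt * gm * dv
  }
  image_volume(a, sp, img$modality)
}

#' Percentile intensity normalisation
#'
#' Linearly rescales so the in-mask 1st and 99th percentiles map to 0 and 1.
#' Order-preserving and invariant to global intensity scaling.
#'
#' @param img an [image_volume()].
#' @param mask logical array (non-empty).
#' @return normalised [image_volume()].
#' @export
normalize_intensity <- function(img, mask) {
  if (!any(mask)) stop("empty mask")
  q <- quantile(img$data[mask], c(0.01, 0.99), names = FALSE)
  if (diff(q) < 1e-9) stop("constant image: cannot normalise")
  image_volume((img$data - q[1]) / (q[2] - q[1]), img$spacing, img$modality)
}

#' Skull stripping by thresholding and morphology
#'
#' Otsu threshold on the T1-like volume, morphological opening (ball radius 2
#' voxels), largest connected component, hole filling, closing, and a final
#' dilation by the expected intradural CSF width so the mask covers brain
#' tissues plus intradural CSF while excluding the skull shell.
#'
#' @param t1 an [image_volume()] with bright brain, darker CSF, skull shell.
#' @param opening_radius_vox opening/closing ball radius in voxels.
#' @param csf_margin_mm outward dilation capturing the intradural CSF.
#' @return logical brain mask.
#' @export
strip_skull <- function(t1, opening_radius_vox = 2, csf_margin_mm = 2) {
  sp <- t1$spacing
  thr <- otsu_threshold(t1$data)
  fg <- t1$data > thr
  r_mm <- opening_radius_vox * min(sp)
  fg <- mask_open(fg, r_mm, sp)
  if (!any(fg)) stop("skull stripping failure: no foreground after opening")
  cc <- largest_component(fg)
  if (sum(cc) < 0.01 * length(cc))
    stop("skull stripping failure: largest component below 1% of the grid")
  m <- fill_holes(cc)
  m <- mask_close(m, r_mm, sp)
  m <- fill_holes(m)
  if (csf_margin_mm > 0) m <- mask_dilate(m, csf_margin_mm, sp)
  m
}
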