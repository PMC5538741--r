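# EM mixture segmentation with spatially varying priors and a mean-field
# Potts (MRF) smoothness term, plus lesion detection through explicit
# outlier mixture components initialised on the T2-hyperintense tails.

# neighbour row-index matrix (6-connectivity) for voxels inside the mask;
# 0 marks a missing neighbour
.neighbour_index <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  pos <- array(0L, dm)
  pos[idx] <- seq_len(n)
  co <- arrayInd(idx, dm)
  nb <- matrix(0L, n, 6)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  for (k in 1:6) {
    cc <- sweep(co, 2, offs[k, ], "+")
    ok <- cc[, 1] >= 1 & cc[, 1] <= dm[1] & cc[, 2] >= 1 & cc[, 2] <= dm[2] &
      cc[, 3] >= 1 & cc[, 3] <= dm[3]
    lin <- (cc[ok, 3] - 1L) * (dm[1] * dm[2]) + (cc[ok, 2] - 1L) * dm[1] + cc[ok, 1]
    nb[ok, k] <- pos[lin]
  }
  nb
}

# log density of a (possibly degenerate-ridged) Gaussian, Y n x d
.log_gauss <- function(Y, mu, sigma) {
  d <- ncol(Y)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    sigma <- sigma + diag(max(1e-6 * sum(diag(sigma)), 1e-8), d)
    ch <- chol(sigma)
  }
  logdet <- 2 * sum(log(diag(ch)))
  R <- sweep(Y, 2, mu)
  # Mahalanobis terms via the Cholesky factor: Sigma = t(ch) %*% ch
  w <- forwardsolve(t(ch), t(R))
  q <- colSums(w^2)
  -0.5 * (logdet + q + d * log(2 * pi))
}

# core EM / mean-field engine on masked voxels
.em_engine <- function(Y, P, nb, beta, mu, covs, max_iter, tol,
                       freeze_min = 0) {
  n <- nrow(Y)
  K <- ncol(P)
  d <- ncol(Y)
  logP <- log(pmax(P, 1e-12))
  q <- P
  loglik <- numeric(0)
  warn <- character(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ld <- matrix(0, n, K)
    for (k in 1:K) ld[, k] <- .log_gauss(Y, mu[k, ], covs[[k]])
    lq <- logP + ld
    # the smoothness term enters from the second iteration: the first pass is
    # a pure prior-times-likelihood assignment, so mean-field smoothing cannot
    # lock in the initial labelling before the data have spoken
    if (beta > 0 && it > 1) {
      for (k in 1:K) {
        qk <- c(0, q[, k])
        lq[, k] <- lq[, k] + beta * rowSums(matrix(qk[nb + 1L], n, 6))
      }
    }
    m <- apply(lq, 1, max)
    # observed-data log-likelihood (beta = 0 part); monotone under plain EM
    loglik <- c(loglik, sum(m + log(rowSums(exp(logP + ld - m)))))
    e <- exp(lq - m)
    q_new <- e / rowSums(e)
    delta <- mean(abs(q_new - q))
    q <- q_new
    # M-step
    for (k in 1:K) {
      wk <- q[, k]
      sw <- sum(wk)
      if (sw < freeze_min) next   # starving component: keep parameters fixed
      mu_k <- colSums(Y * wk) / sw
      R <- sweep(Y, 2, mu_k)
      S <- crossprod(R * wk, R) / sw
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-8) {
        S <- S + diag(max(1e-6 * sum(diag(S)), 1e-8), d)
        warn <- unique(c(warn, sprintf("class %d covariance ridge-regularised", k)))
      }
      mu[k, ] <- mu_k
      covs[[k]] <- S
    }
    if (it > 1 && delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warn <- unique(c(warn, "EM did not converge within max_iter"))
  list(q = q, mu = mu, covs = covs,
       log = list(iterations = it, loglik = loglik, converged = converged,
                  warnings = warn))
}

#' Fit the EM/MRF tissue segmentation
#'
#' Fits a Gaussian mixture over (T1, T2) intensities — or T1 alone when no T2
#' is available — with spatially varying class priors, an MRF smoothness term
#' realised as mean-field Potts coupling of the posteriors over the
#' 6-neighbourhood folded into each E-step, and per-class adaptive means and
#' covariances (ridge-regularised when degenerate).
#'
#' @param t1 an [image_volume()].
#' @param t2 an [image_volume()] or NULL (univariate fallback).
#' @param mask logical brain mask.
#' @param priors named list of prior probability arrays (one per class),
#'   e.g. from [make_tissue_priors()].
#' @param beta MRF coupling (>= 0).
#' @param max_iter maximum EM iterations.
#' @param tol mean absolute posterior change for convergence.
#' @return list with `model` (class names, means, covariances, beta,
#'   convergence log, `bivariate` flag) and `seg` (posterior arrays, hard
#'   label grid in [TISSUE_LABELS] codes, spacing, mask).
#' @export
fit_em_mrf <- function(t1, t2, mask, priors, beta = 0.5, max_iter = 50,
                       tol = 1e-4) {
  stopifnot(is.list(priors), length(priors) >= 2)
  if (beta < 0) stop("beta must be >= 0")
  idx <- which(mask)
  if (length(idx) == 0) stop("empty mask")
  Y <- if (is.null(t2)) cbind(t1$data[idx])
       else cbind(t1$data[idx], t2$data[idx])
  K <- length(priors)
  cls <- names(priors)
  P <- matrix(0, length(idx), K)
  for (k in 1:K) P[, k] <- priors[[k]][idx]
  P <- P / rowSums(P)
  nb <- .neighbour_index(mask)
  # prior-weighted moment initialisation anchors classes to their priors
  d <- ncol(Y)
  mu <- matrix(0, K, d)
  covs <- vector("list", K)
  for (k in 1:K) {
    wk <- P[, k]
    mu[k, ] <- colSums(Y * wk) / sum(wk)
    R <- sweep(Y, 2, mu[k, ])
    S <- crossprod(R * wk, R) / sum(wk)
    covs[[k]] <- S + diag(max(1e-6 * sum(diag(S)), 1e-8), d)
  }
  fit <- .em_engine(Y, P, nb, beta, mu, covs, max_iter, tol)
  .pack_segmentation(fit, cls, mask, idx, t1$spacing, priors,
                     bivariate = !is.null(t2))
}

# class name -> hard label code
.class_code <- function(cls) {
  codes <- c(csf = 2L, gm = 3L, wm = 4L, wm_lesion = 6L, gm_lesion = 7L)
  unname(codes[cls])
}

.pack_segmentation <- function(fit, cls, mask, idx, spacing, priors, bivariate) {
  dm <- dim(mask)
  post <- list()
  for (k in seq_along(cls)) {
    a <- array(0, dm)
    a[idx] <- fit$q[, k]
    post[[cls[k]]] <- a
  }
  hard <- array(0L, dm)
  hard[idx] <- .class_code(cls)[max.col(fit$q, ties.method = "first")]
  model <- list(classes = cls, means = fit$mu, covs = fit$covs,
                priors = priors, log = fit$log, bivariate = bivariate)
  seg <- list(posteriors = post, labels = hard, spacing = spacing, mask = mask)
  list(model = model, seg = seg)
}

#' Detect white and grey matter lesions as mixture outliers
#'
#' Extends a fitted healthy-tissue model with two explicit lesion components:
#' a WM lesion class initialised at the T2-hyperintense tail of white matter
#' (mean + 2 sd on T2) and a GM lesion class at the outlier tail of grey
#' matter, each with a small uniform spatial prior `epsilon` inside its
#' parent tissue's prior support. The extended mixture is refit; the final
#' lesion masks are the voxels whose posterior argmax is a lesion class.
#' Lesion components claiming fewer than `min_voxels` voxels (and connected
#' clumps smaller than `min_voxels`) are dissolved back into parent tissue.
#' Requires bivariate (T1 + T2) input.
#'
#' @param t1,t2 the co-registered [image_volume()]s used for the fit.
#' @param mask logical brain mask.
#' @param fit result of [fit_em_mrf()] with healthy classes csf/gm/wm.
#' @param epsilon uniform lesion prior inside the parent tissue support.
#' @param min_voxels minimum voxels for a lesion component / clump.
#' @param beta,max_iter,tol refit controls.
#' @return list with `wm_lesion` and `gm_lesion` logical masks, plus the
#'   refitted `model` and `seg` (5-class).
#' @export
detect_lesions <- function(t1, t2, mask, fit, epsilon = 0.03, min_voxels = 5,
                           beta = 0.5, max_iter = 25, tol = 1e-4) {
  if (is.null(t2) || !isTRUE(fit$model$bivariate))
    stop("lesion detection requires bivariate (T1 + T2) input")
  pr <- fit$model$priors
  stopifnot(all(c("csf", "gm", "wm") %in% names(pr)))
  dm <- dim(mask)
  sup_wm <- pr$wm > 0.3
  sup_gm <- pr$gm > 0.3
  eps_wm <- array(0, dm); eps_wm[sup_wm] <- epsilon
  eps_gm <- array(0, dm); eps_gm[sup_gm] <- epsilon
  scale <- 1 - eps_wm - eps_gm
  pr5 <- list(csf = pr$csf * scale, gm = pr$gm * scale, wm = pr$wm * scale,
              wm_lesion = eps_wm, gm_lesion = eps_gm)
  idx <- which(mask)
  Y <- cbind(t1$data[idx], t2$data[idx])
  P <- matrix(0, length(idx), 5)
  for (k in 1:5) P[, k] <- pr5[[k]][idx]
  P <- pmax(P, 1e-12)
  P <- P / rowSums(P)
  m0 <- fit$model
  ord <- match(c("csf", "gm", "wm"), m0$classes)
  mu <- rbind(m0$means[ord, , drop = FALSE], 0, 0)
  covs <- c(m0$covs[ord], list(NULL, NULL))
  wm_mu <- m0$means[ord[3], ]; wm_S <- m0$covs[[ord[3]]]
  gm_mu <- m0$means[ord[2], ]; gm_S <- m0$covs[[ord[2]]]
  # tail initialisation: each lesion component starts on the empirical
  # T2-hyperintense outliers of its parent tissue support (falling back to
  # mean + 2 sd when no outliers exist)
  tail_init <- function(sup, mu_p, S_p) {
    s2 <- sqrt(S_p[2, 2])
    out <- sup[idx] & Y[, 2] > mu_p[2] + 3 * s2
    if (sum(out) >= min_voxels) colMeans(Y[out, , drop = FALSE])
    else c(mu_p[1], mu_p[2] + 2 * s2)
  }
  mu[4, ] <- tail_init(pr$wm > 0.5, wm_mu, wm_S)
  mu[5, ] <- tail_init(pr$gm > 0.5, gm_mu, gm_S)
  covs[[4]] <- wm_S
  covs[[5]] <- gm_S
  nb <- .neighbour_index(mask)
  ref <- .em_engine(Y, P, nb, beta, mu, covs, max_iter, tol,
                    freeze_min = min_voxels)
  out <- .pack_segmentation(ref, names(pr5), mask, idx, t1$spacing, pr5,
                            bivariate = TRUE)
  les <- list()
  for (lc in c("wm_lesion", "gm_lesion")) {
    code <- .class_code(lc)
    m <- out$seg$labels == code
    if (sum(m) < min_voxels) {
      m[] <- FALSE
    } else {
      lab <- connected_components(m)
      if (max(lab) > 0) {
        sz <- tabulate(lab[lab > 0])
        keep <- which(sz >= min_voxels)
        m <- array(lab %in% keep & lab > 0, dm)
      }
    }
    # dissolved voxels revert to the parent tissue label
    parent <- if (lc == "wm_lesion") 4L else 3L
    dropped <- out$seg$labels == code & !m
    out$seg$labels[dropped] <- parent
    les[[lc]] <- m
  }
  c(les, out)
}

#' Regional lesion volumes in mL
#'
#' Counts lesion voxels per atlas region and converts to mL via the voxel
#' volume. GM lesions are reported against cortical and deep grey regions,
#' WM lesions against white matter regions; lesion voxels falling outside
#' the admissible regions are reported under region_id 0 ("other") so the
#' per-region volumes always sum exactly to the total lesion volume.
#'
#' @param lesion_masks list with `wm_lesion` / `gm_lesion` logical arrays.
#' @param atlas region atlas (list with `labels` array and `table`).
#' @param spacing voxel spacing mm.
#' @return data frame (region_id, region_name, lesion_class, volume_ml).
#' @export
regional_lesion_volumes <- function(lesion_masks, atlas, spacing) {
  vox_ml <- voxel_volume_mm3(spacing) / 1000
  rows <- list()
  for (lc in names(lesion_masks)) {
    m <- lesion_masks[[lc]]
    if (!all(dim(m) == dim(atlas$labels))) stop("atlas / mask grid mismatch")
    allowed <- if (lc == "gm_lesion") c("cortical", "deep-grey") else "white-matter"
    ids <- atlas$table$id[atlas$table$class %in% allowed]
    reg <- atlas$labels[m]
    for (rid in ids) {
      cnt <- sum(reg == rid)
      rows[[length(rows) + 1]] <- data.frame(
        region_id = rid,
        region_name = atlas$table$name[atlas$table$id == rid],
        lesion_class = lc, volume_ml = cnt * vox_ml,
        stringsAsFactors = FALSE)
    }
    other <- sum(!(reg %in% ids))
    rows[[length(rows) + 1]] <- data.frame(
      region_id = 0L, region_name = "other", lesion_class = lc,
      volume_ml = other * vox_ml, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Voxelwise segmentation accuracy against ground truth
#'
#' Maps ground-truth labels to the healthy tissue classes (ventricle counts
#' as CSF) and returns the fraction of in-mask brain voxels whose hard
#' segmentation label matches.
#'
#' @param seg segmentation from [fit_em_mrf()] / [detect_lesions()].
#' @param truth a `ground_truth`.
#' @param include_lesions whether lesion voxels take part (as their class).
#' @return scalar accuracy in `[0, 1]`.
#' @export
segmentation_accuracy <- function(seg, truth, include_lesions = FALSE) {
  L <- TISSUE_LABELS
  ref <- truth$labels
  want <- array(NA_integer_, dim(ref))
  want[ref == L[["csf"]]] <- 2L
  want[ref == L[["ventricle"]]] <- 2L
  want[ref == L[["gm"]]] <- 3L
  want[ref == L[["wm"]]] <- 4L
  if (include_lesions) {
    want[ref == L[["wm_lesion"]]] <- 6L
    want[ref == L[["gm_lesion"]]] <- 7L
  }
  ok <- !is.na(want) & seg$mask
  mean(seg$labels[ok] == want[ok])
}
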