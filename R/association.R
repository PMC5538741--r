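# Structure-function models: negativity-constrained LASSO per clinical
# score with unpenalized covariates, cross-validated lambda, post-selection
# OLS refit, held-out test evaluation with Fisher-z confidence intervals,
# Bonferroni family correction, and nested-model ANOVA across biomarker
# families.

#' Train/test split with sex stratification
#'
#' Complete-case rows for the outcome are split by a seeded permutation,
#' stratified by sex; the train share is rounded toward train (largest
#' remainder across strata). Disjoint and exhaustive.
#'
#' @param table biomarker + score data frame.
#' @param outcome outcome column name (rows with NA outcome are dropped, as
#'   are rows with NA in any feature column).
#' @param fraction train fraction (default 0.75).
#' @param seed integer seed.
#' @param min_cases minimum complete cases.
#' @return list with `train` and `test` data frames.
#' @export
split_data <- function(table, outcome, fraction = 0.75, seed = 1L,
                       min_cases = 20) {
  cc <- stats::complete.cases(table[, c(outcome, feature_columns(table)),
                                    drop = FALSE])
  d <- table[cc, , drop = FALSE]
  n <- nrow(d)
  if (n < min_cases)
    stop(sprintf("too few complete cases for %s: %d < %d", outcome, n, min_cases))
  n_train <- min(n, ceiling(fraction * n))
  strata <- if ("sex" %in% colnames(d)) d$sex else rep("all", n)
  take <- logical(n)
  with_seed(seed, {
    us <- unique(strata)
    quota <- fraction * tabulate(factor(strata, us))
    base <- floor(quota)
    extra <- n_train - sum(base)
    ord <- order(quota - base, decreasing = TRUE)
    alloc <- base
    if (extra > 0) alloc[ord[seq_len(extra)]] <- alloc[ord[seq_len(extra)]] + 1
    for (i in seq_along(us)) {
      rows <- which(strata == us[i])
      k <- min(length(rows), alloc[i])
      take[sample(rows, k)] <- TRUE
    }
  })
  list(train = d[take, , drop = FALSE], test = d[!take, , drop = FALSE])
}

#' Injury biomarker column names of a table
#' @param table biomarker data frame.
#' @return character vector of penalized feature columns.
#' @export
feature_columns <- function(table) {
  grep("^(z_|leswm_|lesgm_|enl_)", colnames(table), value = TRUE)
}

# numeric covariate design (age, sexF, sequenceB)
.covariate_design <- function(d) {
  cbind(age = d$age, sexF = as.numeric(d$sex == "F"),
        sequenceB = as.numeric(d$sequence == "B"))
}

# coordinate-descent core on pre-standardized data; beta constrained <= 0,
# gamma free. Returns updated coefficients and residual.
.cd_core <- function(Xs, Zc, yc, cj, cz, active, lambda, beta, gamma,
                     max_iter, tol) {
  n <- length(yc)
  p <- length(beta)
  q <- length(gamma)
  r <- as.numeric(yc - Xs %*% beta - (if (q > 0) Zc %*% gamma else 0))
  obj <- function() sum(r^2) / (2 * n) + lambda * sum(abs(beta))
  objective <- obj()
  dmax <- Inf
  for (it in seq_len(max_iter)) {
    dmax <- 0
    if (q > 0) for (j in seq_len(q)) {
      rho <- sum(Zc[, j] * r) / n + cz[j] * gamma[j]
      g_new <- rho / cz[j]
      d <- g_new - gamma[j]
      if (d != 0) { r <- r - Zc[, j] * d; gamma[j] <- g_new }
      dmax <- max(dmax, abs(d))
    }
    for (j in seq_len(p)) {
      if (!active[j]) next
      rho <- sum(Xs[, j] * r) / n + cj[j] * beta[j]
      b_new <- min(0, (rho + lambda) / cj[j])
      d <- b_new - beta[j]
      if (d != 0) { r <- r - Xs[, j] * d; beta[j] <- b_new }
      dmax <- max(dmax, abs(d))
    }
    objective <- c(objective, obj())
    if (dmax < tol) break
  }
  list(beta = beta, gamma = gamma, r = r, objective = objective,
       converged = dmax < tol)
}

#' Negativity-constrained LASSO by coordinate descent
#'
#' Minimises `(1/2n) ||y - X b - Z g||^2 + lambda * sum(|b_j|)` subject to
#' `b_j <= 0` for every penalized feature, with the covariate coefficients
#' `g` unpenalized and unconstrained. Penalized columns are standardized
#' (mean 0, unit sd), covariates and the outcome are centred. Because
#' `|b| = -b` on the constraint set, the coordinate update has the closed
#' form `b_j <- min(0, (rho_j + lambda) / c_j)` with `rho_j` the partial
#' residual correlation and `c_j` the column scale. The objective is
#' non-increasing across sweeps; convergence when the largest coefficient
#' change falls below `tol`.
#'
#' @param X n x p matrix of penalized features.
#' @param Z n x q covariate matrix (may have 0 columns).
#' @param y outcome vector.
#' @param lambda penalty (>= 0).
#' @param max_iter maximum sweeps.
#' @param tol convergence tolerance on coefficient change.
#' @param init optional warm start: a list with `beta` (standardized scale)
#'   and `gamma`, e.g. a previous fit along a lambda path.
#' @return a `neg_lasso_fit`: standardized coefficients `beta_std`,
#'   original-scale `beta`, covariate `gamma`, `intercept`, `lambda`,
#'   `objective` trace, and scaling metadata.
#' @export
fit_neg_lasso <- function(X, Z, y, lambda, max_iter = 1000, tol = 1e-7,
                          init = NULL) {
  X <- as.matrix(X)
  Z <- if (is.null(Z)) matrix(0, length(y), 0) else as.matrix(Z)
  if (any(!is.finite(X)) || any(!is.finite(y)) || any(!is.finite(Z)))
    stop("non-finite values in the design")
  if (lambda < 0) stop("lambda must be >= 0")
  n <- length(y)
  p <- ncol(X)
  q <- ncol(Z)
  xm <- colMeans(X)
  # population (1/n) scale so standardized columns have x'x/n = 1 exactly
  xs <- sqrt(colMeans(sweep(X, 2, xm)^2))
  active <- xs > 1e-12
  xs[!active] <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  Xs[, !active] <- 0
  zm <- if (q > 0) colMeans(Z) else numeric(0)
  Zc <- if (q > 0) sweep(Z, 2, zm) else Z
  ym <- mean(y)
  yc <- y - ym
  cj <- colSums(Xs^2) / n
  cj[cj < 1e-12] <- 1
  cz <- if (q > 0) colSums(Zc^2) / n else numeric(0)
  cz[cz < 1e-12] <- 1
  beta <- rep(0, p)
  gamma <- rep(0, q)
  if (!is.null(init)) {
    if (length(init$beta) == p) beta <- pmin(init$beta, 0)
    if (length(init$gamma) == q) gamma <- init$gamma
  }
  fit <- .cd_core(Xs, Zc, yc, cj, cz, active, lambda, beta, gamma,
                  max_iter, tol)
  beta <- setNames(fit$beta, colnames(X))
  gamma <- fit$gamma
  structure(list(
    beta_std = beta, beta = beta / xs,
    gamma = if (q > 0) setNames(gamma, colnames(Z)) else numeric(0),
    intercept = ym - sum((beta / xs) * xm) - if (q > 0) sum(gamma * zm) else 0,
    lambda = lambda, objective = fit$objective, converged = fit$converged,
    x_center = xm, x_scale = xs, z_center = zm, y_center = ym,
    cj = cj, active = active, residuals = fit$r, n = n),
    class = "neg_lasso_fit")
}

#' @export
print.neg_lasso_fit <- function(x, ...) {
  cat(sprintf("<neg_lasso_fit: lambda=%.4g, %d/%d features retained>\n",
              x$lambda, sum(x$beta_std != 0), length(x$beta_std)))
  invisible(x)
}

#' Predict from a constrained-LASSO fit
#' @param object a `neg_lasso_fit`.
#' @param X,Z new penalized / covariate matrices.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.neg_lasso_fit <- function(object, X, Z = NULL, ...) {
  X <- as.matrix(X)
  out <- object$intercept + X %*% object$beta
  if (length(object$gamma) > 0) out <- out + as.matrix(Z) %*% object$gamma
  as.numeric(out)
}

#' KKT optimality check for a constrained-LASSO solution
#'
#' For retained coefficients (`b_j < 0`) stationarity requires
#' `rho_j + lambda = c_j b_j`; for zero coefficients feasibility requires
#' `rho_j >= -lambda`. Returns the largest violation of either condition.
#'
#' @param fit a `neg_lasso_fit`.
#' @param X,Z,y the data the model was fitted on.
#' @return scalar maximum KKT violation (0 = perfectly optimal).
#' @export
kkt_violation <- function(fit, X, Z, y) {
  X <- as.matrix(X)
  n <- length(y)
  Xs <- sweep(sweep(X, 2, fit$x_center), 2, fit$x_scale, "/")
  Xs[, !fit$active] <- 0
  Zc <- if (length(fit$gamma) > 0) sweep(as.matrix(Z), 2, fit$z_center)
        else matrix(0, n, 0)
  yc <- y - fit$y_center
  r <- yc - Xs %*% fit$beta_std -
    (if (ncol(Zc) > 0) Zc %*% fit$gamma else 0)
  viol <- 0
  for (j in seq_along(fit$beta_std)) {
    if (!fit$active[j]) next
    rho <- sum(Xs[, j] * r) / n + fit$cj[j] * fit$beta_std[j]
    if (fit$beta_std[j] < 0) {
      viol <- max(viol, abs(rho + fit$lambda - fit$cj[j] * fit$beta_std[j]))
    } else {
      viol <- max(viol, max(0, -(rho + fit$lambda)))
    }
  }
  # covariates: exact orthogonality of residual to centred covariates
  if (ncol(Zc) > 0)
    viol <- max(viol, max(abs(crossprod(Zc, r) / n)))
  viol
}

#' Largest useful penalty for a problem
#'
#' The smallest lambda at which every penalized coefficient is exactly zero:
#' with covariates fitted by OLS alone, `lambda_max = max_j max(0, -rho_j)`.
#'
#' @param X,Z,y as in [fit_neg_lasso()].
#' @return scalar lambda_max (floored at 1e-6).
#' @export
lambda_max <- function(X, Z, y) {
  X <- as.matrix(X)
  n <- length(y)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(sweep(X, 2, xm)^2))
  xs[xs < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  yc <- y - mean(y)
  if (!is.null(Z) && ncol(as.matrix(Z)) > 0) {
    Zc <- sweep(as.matrix(Z), 2, colMeans(as.matrix(Z)))
    yc <- yc - Zc %*% qr.solve(crossprod(Zc) + diag(1e-10, ncol(Zc)),
                               crossprod(Zc, yc))
  }
  rho <- as.numeric(crossprod(Xs, yc)) / n
  max(c(-rho, 1e-6))
}

#' Cross-validated lambda selection
#'
#' 10-fold seeded CV over a 100-point log-spaced grid from `lambda_max` down
#' to `1e-3 * lambda_max`; returns the lambda minimising mean squared
#' prediction error.
#'
#' @param X,Z,y as in [fit_neg_lasso()].
#' @param n_folds folds (default 10).
#' @param n_lambda grid size.
#' @param lambda_min_ratio grid floor relative to lambda_max.
#' @param seed fold-assignment seed.
#' @return list with `lambda` (the minimiser), `grid`, `cv_mse`.
#' @export
select_lambda_cv <- function(X, Z, y, n_folds = 10, n_lambda = 100,
                             lambda_min_ratio = 1e-3, seed = 1L) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 2 * n_folds) n_folds <- max(2, n %/% 4)
  if (n_folds < 2) stop("degenerate folds: too few rows")
  lmax <- lambda_max(X, Z, y)
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = n_lambda))
  folds <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  err <- matrix(NA_real_, n_folds, n_lambda)
  Zm <- if (!is.null(Z)) as.matrix(Z) else matrix(0, n, 0)
  q <- ncol(Zm)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (sum(tr) < 3 || sum(!tr) < 1) stop("degenerate folds")
    # standardize the training fold once; walk the path with warm starts
    Xtr <- X[tr, , drop = FALSE]
    nt <- nrow(Xtr)
    xm <- colMeans(Xtr)
    xs <- sqrt(colMeans(sweep(Xtr, 2, xm)^2))
    active <- xs > 1e-12
    xs[!active] <- 1
    Xs <- sweep(sweep(Xtr, 2, xm), 2, xs, "/")
    Xs[, !active] <- 0
    zm <- if (q > 0) colMeans(Zm[tr, , drop = FALSE]) else numeric(0)
    Zc <- if (q > 0) sweep(Zm[tr, , drop = FALSE], 2, zm) else
      matrix(0, nt, 0)
    ym <- mean(y[tr])
    yc <- y[tr] - ym
    cj <- colSums(Xs^2) / nt
    cj[cj < 1e-12] <- 1
    cz <- if (q > 0) colSums(Zc^2) / nt else numeric(0)
    cz[cz < 1e-12] <- 1
    Xse <- sweep(sweep(X[!tr, , drop = FALSE], 2, xm), 2, xs, "/")
    Xse[, !active] <- 0
    Zce <- if (q > 0) sweep(Zm[!tr, , drop = FALSE], 2, zm) else
      matrix(0, sum(!tr), 0)
    yte <- y[!tr] - ym
    beta <- rep(0, ncol(X))
    gamma <- rep(0, q)
    for (li in seq_along(grid)) {
      fit <- .cd_core(Xs, Zc, yc, cj, cz, active, grid[li], beta, gamma,
                      max_iter = 1000, tol = 1e-7)
      beta <- fit$beta
      gamma <- fit$gamma
      pred <- Xse %*% beta + (if (q > 0) Zce %*% gamma else 0)
      err[f, li] <- mean((yte - pred)^2)
    }
  }
  mse <- colMeans(err)
  list(lambda = grid[which.min(mse)], grid = grid, cv_mse = mse)
}

#' Post-selection OLS refit
#'
#' Unconstrained ordinary least squares on the features retained by the
#' constrained LASSO plus the covariates, providing per-coefficient standard
#' errors, t-test p-values and adjusted R^2 — the standard mechanism for
#' post-selection summaries.
#'
#' @param train training data frame.
#' @param outcome outcome column.
#' @param retained retained feature names (may be empty: covariates-only).
#' @param covariates covariate column names.
#' @return a `refit_model`: the `lm` object, coefficient table,
#'   `adj_r2`, `r2`, `retained`.
#' @export
refit_ols <- function(train, outcome, retained,
                      covariates = c("age", "sex", "sequence")) {
  covariates <- intersect(covariates, colnames(train))
  rhs <- c(sprintf("`%s`", retained), covariates)
  if (length(rhs) == 0) rhs <- "1"
  fml <- as.formula(paste(sprintf("`%s`", outcome), "~", paste(rhs, collapse = " + ")))
  fit <- lm(fml, data = train)
  if (anyNA(coef(fit)))
    warning("rank-deficient refit: collinear columns dropped")
  sm <- summary(fit)
  structure(list(lm = fit, outcome = outcome, retained = retained,
                 covariates = covariates,
                 coefficients = sm$coefficients,
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 n = nrow(train)),
            class = "refit_model")
}

#' @export
print.refit_model <- function(x, ...) {
  cat(sprintf("<refit_model %s: %d features, adj R^2 = %.3f>\n",
              x$outcome, length(x$retained), x$adj_r2))
  invisible(x)
}

#' Evaluate a refit model on the held-out test set
#'
#' Pearson correlation between predictions and observed scores, 95%
#' confidence interval by the Fisher z transform with n - 3 denominator,
#' relative mean error `100 * (mean(pred) - mean(obs)) / mean(obs)` (%), and
#' a significance flag against a family-corrected threshold.
#'
#' @param model a `refit_model`.
#' @param test test data frame (>= 5 rows).
#' @param threshold per-test alpha, e.g. [bonferroni_threshold()].
#' @return list: `r`, `ci` (length 2), `relative_mean_error_pct`, `p_value`,
#'   `significant`, `n_test`.
#' @export
evaluate_test <- function(model, test, threshold = 0.05) {
  if (nrow(test) < 5) stop("test set too small (< 5 rows)")
  pred <- predict(model$lm, newdata = test)
  obs <- test[[model$outcome]]
  if (sd(pred) < 1e-12) stop("zero-variance predictions: correlation undefined")
  r <- cor(pred, obs)
  n <- length(obs)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  ci <- tanh(c(z - 1.96 * se, z + 1.96 * se))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  rme <- 100 * (mean(pred) - mean(obs)) / mean(obs)
  list(r = r, ci = ci, relative_mean_error_pct = rme, p_value = p,
       significant = p < threshold, n_test = n)
}

#' Bonferroni-corrected per-test threshold
#' @param alpha family-wise level in (0, 1).
#' @param m number of models/tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 6) {
  if (m < 1) stop("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / m
}

#' Nested-model ANOVA across biomarker families
#'
#' Compares the full refit model against a reduced model keeping only the
#' retained features of one biomarker family (cortical shape `z_` or lesion
#' `les*`) plus covariates, refit on the same rows:
#' `F = ((RSS_r - RSS_f) / (df_r - df_f)) / (RSS_f / df_f)`. When the
#' reduced set equals the full set (0 numerator df) or the family retains
#' nothing, the comparison is skipped with a flag.
#'
#' @param full a `refit_model`.
#' @param reduced_family "cortical" or "lesion".
#' @param train the training data the full model was fit on.
#' @return a list: `skipped` + reason, or `F`, `p_value`, `df`, `rss_full`,
#'   `rss_reduced`, and the reduced `refit_model`.
#' @export
compare_models_anova <- function(full, reduced_family = c("cortical", "lesion"),
                                 train) {
  reduced_family <- match.arg(reduced_family)
  pat <- if (reduced_family == "cortical") "^z_" else "^les(wm|gm)_"
  keep <- grep(pat, full$retained, value = TRUE)
  if (length(keep) == 0)
    return(list(skipped = TRUE, reason = sprintf(
      "no %s features retained by the full model", reduced_family)))
  if (length(keep) == length(full$retained))
    return(list(skipped = TRUE, reason = "reduced model equals full model (0 df)"))
  red <- refit_ols(train, full$outcome, keep, full$covariates)
  rss_f <- sum(residuals(full$lm)^2)
  rss_r <- sum(residuals(red$lm)^2)
  df_f <- full$lm$df.residual
  df_r <- red$lm$df.residual
  Fst <- ((rss_r - rss_f) / (df_r - df_f)) / (rss_f / df_f)
  p <- pf(Fst, df_r - df_f, df_f, lower.tail = FALSE)
  list(skipped = FALSE, F = Fst, p_value = p, df = c(df_r - df_f, df_f),
       rss_full = rss_f, rss_reduced = rss_r, reduced = red)
}

#' @importFrom stats residuals
NULL

#' Fit and evaluate one clinical-score model end to end
#'
#' Complete cases for the outcome, sex-stratified 75/25 split, 10-fold CV
#' for lambda, negativity-constrained LASSO, post-selection OLS refit and
#' test-set evaluation.
#'
#' @param table biomarker table with the outcome column merged in.
#' @param outcome outcome column name.
#' @param fraction train fraction.
#' @param seed seed for split and folds.
#' @param threshold per-test alpha for the significance flag.
#' @param lambda optional fixed lambda (skips CV).
#' @return list: `split`, `cv`, `lasso`, `refit`, `evaluation`, `retained`.
#' @export
fit_score_model <- function(table, outcome, fraction = 0.75, seed = 1L,
                            threshold = bonferroni_threshold(0.05, 6),
                            lambda = NULL) {
  sp <- split_data(table, outcome, fraction, seed)
  feats <- feature_columns(table)
  Xtr <- as.matrix(sp$train[, feats, drop = FALSE])
  Ztr <- .covariate_design(sp$train)
  ytr <- sp$train[[outcome]]
  cv <- if (is.null(lambda))
    select_lambda_cv(Xtr, Ztr, ytr, seed = seed + 1L) else
      list(lambda = lambda, grid = lambda, cv_mse = NA_real_)
  fit <- fit_neg_lasso(Xtr, Ztr, ytr, cv$lambda)
  retained <- names(fit$beta_std)[fit$beta_std != 0]
  refit <- refit_ols(sp$train, outcome, retained)
  ev <- if (nrow(sp$test) >= 5)
    evaluate_test(refit, sp$test, threshold) else NULL
  list(split = sp, cv = cv, lasso = fit, refit = refit, evaluation = ev,
       retained = retained, outcome = outcome, seed = seed)
}
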