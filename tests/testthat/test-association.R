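# Negativity-constrained LASSO, lambda selection, post-selection refit,
# test-set evaluation, Bonferroni correction and nested-model ANOVA.

test_that("the constrained coordinate descent matches closed forms", {
  withr::with_seed(42, {
    n <- 400
    x <- rnorm(n)
    resid0 <- residuals(lm(rnorm(n) ~ x))
    resid0 <- resid0 / sd(resid0)
  })
  # population-standardized column and an outcome whose partial correlation
  # with it is exactly -0.5
  xs <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- -0.5 * xs + resid0

  # negative-part soft threshold: rho = -0.5, lambda = 0.2 -> beta = -0.3
  f <- fit_neg_lasso(cbind(f1 = x), NULL, y, 0.2)
  expect_equal(unname(f$beta_std), -0.3, tolerance = 1e-9)

  # at lambda >= lambda_max every penalized coefficient is exactly zero
  x <- xs
  lmax <- lambda_max(cbind(f1 = x), NULL, y)
  f0 <- fit_neg_lasso(cbind(f1 = x), NULL, y, lmax)
  expect_lt(abs(f0$beta_std), 1e-10)

  # positively correlated feature is never retained at any lambda
  withr::with_seed(1, yp <- 0.7 * x + rnorm(n, 0, 0.5))
  for (lam in c(0, 0.001, 0.1))
    expect_identical(unname(fit_neg_lasso(cbind(f1 = x), NULL, yp, lam)$beta_std), 0)

  # the objective never increases across sweeps
  withr::with_seed(2, {
    X <- matrix(rnorm(50 * 6), 50, 6)
    yy <- X %*% c(-1, -2, 0, 0, 1, 0) + rnorm(50)
  })
  ff <- fit_neg_lasso(X, NULL, yy, 0.1)
  expect_true(all(diff(ff$objective) <= 1e-10))
  expect_error(fit_neg_lasso(X * NA, NULL, yy, 0.1), "non-finite")
})

test_that("solutions agree with a quadratic-programming oracle on small problems", {
  max_dev <- 0
  max_kkt <- 0
  withr::with_seed(77, {
    for (rep in 1:100) {
      p <- sample(1:4, 1)
      q <- sample(0:2, 1)
      n <- sample(20:60, 1)
      X <- matrix(rnorm(n * p), n, p)
      Z <- if (q > 0) matrix(rnorm(n * q), n, q) else NULL
      y <- rnorm(n) + X %*% rnorm(p) + (if (q > 0) Z %*% rnorm(q) else 0)
      lam <- runif(1, 0.01, 0.5)
      fit <- fit_neg_lasso(X, Z, y, lam)
      b_star <- qp_oracle_neg_lasso(X, Z, y, lam)
      max_dev <- max(max_dev, max(abs(fit$beta_std - b_star)))
      max_kkt <- max(max_kkt, kkt_violation(fit, X, Z, y))
    }
  })
  expect_lt(max_dev, 1e-6)
  expect_lt(max_kkt, 1e-5)
})

test_that("solutions agree with glmnet under an upper-bound-zero constraint", {
  skip_if_not_installed("glmnet")
  withr::with_seed(11, {
    n <- 80; p <- 8
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("f", 1:p)
    y <- as.numeric(X %*% c(-2, -1, 0, 0, 0, 0, 0, 1) + rnorm(n))
  })
  lam <- 0.15
  fit <- fit_neg_lasso(X, NULL, y, lam)
  g <- glmnet::glmnet(X, y, alpha = 1, lambda = lam, upper.limits = 0,
                      standardize = TRUE, intercept = TRUE, thresh = 1e-12)
  expect_equal(unname(fit$beta), as.numeric(coef(g))[-1], tolerance = 5e-3)
})

test_that("cross-validated lambda responds to signal strength", {
  withr::with_seed(5, {
    noise_sparse <- 0
    for (s in 1:10) {
      n <- 60; p <- 10
      X <- matrix(rnorm(n * p), n, p)
      y <- rnorm(n)                      # pure noise
      cv <- select_lambda_cv(X, NULL, y, seed = s)
      fit <- fit_neg_lasso(X, NULL, y, cv$lambda)
      if (sum(fit$beta_std != 0) <= 2) noise_sparse <- noise_sparse + 1
    }
  })
  expect_gte(noise_sparse, 8)

  withr::with_seed(6, {
    hits <- 0
    for (s in 1:10) {
      n <- 80; p <- 10
      X <- matrix(rnorm(n * p), n, p)
      lp <- X %*% c(-2, -1.5, rep(0, 8))
      y <- as.numeric(lp + rnorm(n, 0, sd(lp) / 3))   # strong signal
      cv <- select_lambda_cv(X, NULL, y, seed = s)
      fit <- fit_neg_lasso(X, NULL, y, cv$lambda)
      if (all(fit$beta_std[1:2] < 0)) hits <- hits + 1
    }
  })
  expect_gte(hits, 8)

  # same seed -> identical lambda
  withr::with_seed(7, {
    X <- matrix(rnorm(50 * 5), 50, 5)
    y <- rnorm(50)
  })
  expect_identical(select_lambda_cv(X, NULL, y, seed = 3)$lambda,
                   select_lambda_cv(X, NULL, y, seed = 3)$lambda)
})

test_that("the train/test split is seeded, stratified and exhaustive", {
  withr::with_seed(9, tab <- data.frame(
    subject_id = 1:100, age = runif(100, 5, 17),
    sex = sample(c("M", "F"), 100, TRUE),
    sequence = sample(c("A", "B"), 100, TRUE),
    z_a_thick = abs(rnorm(100)), AHA = rnorm(100, 80, 10)))
  sp <- split_data(tab, "AHA", seed = 1)
  expect_equal(nrow(sp$train), 75)
  expect_equal(nrow(sp$test), 25)
  expect_equal(sort(c(sp$train$subject_id, sp$test$subject_id)), 1:100)
  sp2 <- split_data(tab, "AHA", seed = 1)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)

  # fraction 1.0 leaves nothing to evaluate; the evaluation refuses
  sp1 <- split_data(tab, "AHA", fraction = 1.0, seed = 1)
  expect_equal(nrow(sp1$test), 0)
  rf <- refit_ols(sp1$train, "AHA", "z_a_thick")
  expect_error(evaluate_test(rf, sp1$test), "too small")

  expect_error(split_data(tab[1:10, ], "AHA", seed = 1), "too few")
})

test_that("the OLS refit reproduces closed forms and recovers generator weights", {
  # x = (1,2,3), y = (2,4,6): slope 2, intercept 0, R^2 = 1
  d <- data.frame(x = c(1, 2, 3), AHA = c(2, 4, 6))
  rf <- suppressWarnings(refit_ols(d, "AHA", "x", covariates = character(0)))
  expect_equal(unname(coef(rf$lm)), c(0, 2), tolerance = 1e-12)
  expect_equal(rf$r2, 1)
  expect_lt(max(abs(residuals(rf$lm))), 1e-12)

  # coefficients within 2 SE of the generating weights in >= 90% of cells
  withr::with_seed(15, {
    ok <- 0; total <- 0
    for (s in 1:20) {
      n <- 150
      d <- data.frame(f1 = abs(rnorm(n)), f2 = abs(rnorm(n)),
                      age = runif(n, 5, 17))
      d$AHA <- 100 - 4 * d$f1 - 2 * d$f2 + 0.3 * d$age + rnorm(n, 0, 1)
      rf <- refit_ols(d, "AHA", c("f1", "f2"), covariates = "age")
      cf <- rf$coefficients
      truth <- c(f1 = -4, f2 = -2)
      for (nm in rownames(cf)[2:3]) {
        total <- total + 1
        key <- gsub("`", "", nm)
        if (abs(cf[nm, "Estimate"] - truth[[key]]) < 2 * cf[nm, "Std. Error"])
          ok <- ok + 1
      }
    }
  })
  expect_gte(ok / total, 0.90)
})

test_that("test-set evaluation computes Pearson r with a Fisher-z interval", {
  d <- data.frame(x = 1:20, AHA = 2 * (1:20) + 1)
  rf <- suppressWarnings(refit_ols(d, "AHA", "x", covariates = character(0)))
  ev <- evaluate_test(rf, d)
  expect_equal(ev$r, 1)
  expect_equal(ev$relative_mean_error_pct, 0)

  # r = 0.6, n = 42: interval from atanh(0.6) +- 1.96/sqrt(39)
  withr::with_seed(33, {
    repeat {
      x <- rnorm(42)
      e <- residuals(lm(rnorm(42) ~ x))
      y <- 0.6 * scale(x)[, 1] * sd(e) / sqrt(1 - 0.36) + e
      if (abs(cor(x, y) - 0.6) < 0.02) break
    }
  })
  r <- cor(x, y)
  ci_expect <- tanh(atanh(r) + c(-1, 1) * 1.96 / sqrt(42 - 3))
  d2 <- data.frame(x = x, AHA = y)
  rf2 <- refit_ols(d2, "AHA", "x", covariates = character(0))
  ev2 <- evaluate_test(rf2, d2)
  expect_equal(ev2$ci, ci_expect, tolerance = 1e-6)
  expect_true(ev2$ci[1] <= ev2$r && ev2$r <= ev2$ci[2])

  # anti-correlated predictions give r = -1
  d3 <- data.frame(pred_x = 1:20, AHA = 2 * (1:20))
  rf3 <- suppressWarnings(refit_ols(d3, "AHA", "pred_x", covariates = character(0)))
  d3_test <- data.frame(pred_x = 1:20, AHA = -2 * (1:20))
  ev3 <- evaluate_test(rf3, d3_test)
  expect_equal(ev3$r, -1)

  # zero-variance predictions are undefined
  d4 <- data.frame(xc = rep(1, 10), AHA = rnorm(10))
  rf4 <- refit_ols(d4, "AHA", character(0), covariates = character(0))
  expect_error(evaluate_test(rf4, d4), "zero-variance")
})

test_that("the Bonferroni threshold is alpha over m", {
  expect_equal(round(bonferroni_threshold(0.05, 6), 3), 0.008)
  expect_equal(bonferroni_threshold(0.37, 1), 0.37)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "m must")
  expect_error(bonferroni_threshold(1.2, 6), "alpha")
})

test_that("nested-model ANOVA is calibrated under the null and powered under signal", {
  mkdat <- function(n, w_les, sd = 5, seed = 1) {
    withr::with_seed(seed, {
      d <- data.frame(z_a_thick = abs(rnorm(n)), z_b_curv = abs(rnorm(n)),
                      leswm_wm_01 = rexp(n), age = runif(n, 5, 17),
                      sex = sample(c("M", "F"), n, TRUE),
                      sequence = sample(c("A", "B"), n, TRUE))
      d$AHA <- 100 - 5 * d$z_a_thick - 3 * d$z_b_curv + w_les * d$leswm_wm_01 +
        rnorm(n, 0, sd)
    })
    d
  }

  # reduced = full -> 0 numerator df -> skipped with a flag
  d <- mkdat(80, w_les = 0)
  full_c <- refit_ols(d, "AHA", c("z_a_thick", "z_b_curv"))
  cmp0 <- compare_models_anova(full_c, "cortical", d)
  expect_true(cmp0$skipped)
  # family with nothing retained -> skipped
  cmp1 <- compare_models_anova(full_c, "lesion", d)
  expect_true(cmp1$skipped)

  # agreement with stats::anova on a genuine nested pair
  full <- refit_ols(d, "AHA", c("z_a_thick", "z_b_curv", "leswm_wm_01"))
  cmp <- compare_models_anova(full, "cortical", d)
  ref <- anova(cmp$reduced$lm, full$lm)
  expect_equal(cmp$F, ref$F[2], tolerance = 1e-10)
  expect_equal(cmp$p_value, ref$`Pr(>F)`[2], tolerance = 1e-10)
  expect_gte(cmp$rss_reduced, cmp$rss_full)

  # null calibration: dropping a pure-noise feature gives uniform p-values
  withr::with_seed(55, {
    pvals <- replicate(200, {
      n <- 60
      d0 <- data.frame(z_a_thick = abs(rnorm(n)), leswm_wm_01 = rexp(n),
                       age = runif(n, 5, 17),
                       sex = sample(c("M", "F"), n, TRUE),
                       sequence = sample(c("A", "B"), n, TRUE))
      d0$AHA <- 100 - 5 * d0$z_a_thick + rnorm(n, 0, 5)
      fullr <- refit_ols(d0, "AHA", c("z_a_thick", "leswm_wm_01"))
      compare_models_anova(fullr, "cortical", d0)$p_value
    })
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)

  # power: a truly informative dropped feature is detected in >= 90% of seeds
  hits <- sum(sapply(1:20, function(s) {
    d1 <- mkdat(80, w_les = -10, sd = 2, seed = 100 + s)
    fullp <- refit_ols(d1, "AHA", c("z_a_thick", "z_b_curv", "leswm_wm_01"))
    compare_models_anova(fullp, "cortical", d1)$p_value < 0.05
  }))
  expect_gte(hits, 18)
})

test_that("the per-score orchestrator retains true features end to end", {
  # tabular cohort with known sparse negative weights at moderate noise
  withr::with_seed(19, {
    n <- 139
    tab <- data.frame(subject_id = 1:n, age = runif(n, 5, 17),
                      sex = sample(c("M", "F"), n, TRUE),
                      sequence = sample(c("A", "B"), n, TRUE),
                      z_ctx_01_thick = abs(rnorm(n)),
                      z_ctx_02_thick = abs(rnorm(n)),
                      leswm_wm_01 = rexp(n, 0.5),
                      enl_dgm_left_ant = rexp(n, 1))
    lp <- 100 - 6 * tab$z_ctx_01_thick - 2 * tab$leswm_wm_01 + 0.3 * tab$age
    tab$AHA <- lp + rnorm(n, sd(lp) * sqrt(1 / 0.7 - 1))
  })
  m <- fit_score_model(tab, "AHA", seed = 2)
  expect_true(all(c("z_ctx_01_thick", "leswm_wm_01") %in% m$retained))
  expect_gt(m$evaluation$r, 0.5)
  # every penalized coefficient obeys the sign constraint
  expect_true(all(m$lasso$beta_std <= 0))
})

test_that("lasso prefers direct causes over redundant enlargement proxies", {
  # enlargement generated as a noisy linear function of lesion load: the
  # lesion feature should be retained in preference in >= 70% of seeds
  wins <- sum(sapply(1:10, function(s) {
    withr::with_seed(400 + s, {
      n <- 139
      les <- rexp(n, 0.4)
      enl <- 0.8 * les + rnorm(n, 0, 0.8)
      tab <- data.frame(subject_id = 1:n, age = runif(n, 5, 17),
                        sex = sample(c("M", "F"), n, TRUE),
                        sequence = sample(c("A", "B"), n, TRUE),
                        leswm_wm_01 = les, enl_dgm_left_ant = pmax(enl, 0))
      tab$AHA <- 100 - 2 * les + rnorm(n, 0, 2)
    })
    m <- fit_score_model(tab, "AHA", seed = s)
    ("leswm_wm_01" %in% m$retained) && !("enl_dgm_left_ant" %in% m$retained)
  }))
  expect_gte(wins, 7)
})
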