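test_that("noiseless linear outcome gives exact coefficients and perfect proxy", {
  zc <- rep(seq(-2, 2, length.out = 10), 2)
  d <- trial_dataset(arm = rep(0:1, each = 10), outcome = 2 + 3 * zc,
                     covariates = matrix(zc, ncol = 1, dimnames = list(NULL, "z")))
  pm <- fit_proxy_models(d)
  for (mod in pm) {
    expect_equal(unname(mod$coefficients), c(2, 3), tolerance = 1e-10)
    expect_lt(mod$residual_variance, 1e-20)
    expect_equal(mod$fitted_proxy, d$outcome[d$arm == mod$arm_label], tolerance = 1e-10)
  }
  ps <- population_summary(mean = 0, cov = matrix(1))
  s <- suppressWarnings(arm_summary(pm$control, d, ps))
  expect_equal(s$rho, 1, tolerance = 1e-7)
})

test_that("OLS coefficients match the normal-equations oracle on a toy set", {
  z <- c(0, 1, 2, 3, 4)
  y <- c(1, 3, 4, 7, 8)
  # independent oracle: explicit matrix-inverse normal equations
  X <- cbind(1, z)
  beta_oracle <- solve(t(X) %*% X) %*% t(X) %*% y
  d <- trial_dataset(arm = rep(0:1, each = 5), outcome = c(y, y),
                     covariates = matrix(c(z, z), ncol = 1, dimnames = list(NULL, "z")))
  pm <- fit_proxy_models(d)
  expect_equal(unname(pm$control$coefficients), unname(drop(beta_oracle)),
               tolerance = 1e-10)
})

test_that("degenerate designs error with actionable messages", {
  set.seed(1)
  zc <- cbind(z = rnorm(20), flat = rep(1.5, 20))
  d <- trial_dataset(arm = rep(0:1, each = 10), outcome = rnorm(20), covariates = zc)
  expect_error(fit_proxy_models(d), "flat")
  # too-few participants per arm relative to covariate dimension
  expect_error(trial_dataset(arm = rep(0:1, each = 3), outcome = rnorm(6),
                             covariates = matrix(rnorm(12), 6, 2)),
               "at least p \\+ 2")
  expect_error(trial_dataset(arm = rep(2, 10), outcome = rnorm(10),
                             covariates = matrix(rnorm(10))),
               "0.*1|arm")
})

test_that("population proxy mean is the plug-in linear predictor", {
  st <- sim_trial(seed = 42)
  fit <- rct_ppmm(y ~ z + w, data = st$df, popsum = st$popsum)
  mod <- fit$proxies$treatment
  # hand arithmetic: intercept 2, slopes (1,1), mean (0.5, -0.5) -> 2.0
  fake <- mod
  fake$coefficients <- c(`(Intercept)` = 2, z = 1, w = 1)
  ps <- population_summary(mean = c(0.5, -0.5), cov = diag(2))
  expect_equal(proxy_population_mean(fake, ps)$mean, 2.0, tolerance = 1e-12)
  # popsum mean at the trial-arm covariate mean recovers the in-sample proxy mean
  idx <- st$df$arm == 1
  ps_arm <- population_summary(mean = colMeans(st$df[idx, c("z", "w")]), cov = diag(2))
  expect_equal(proxy_population_mean(mod, ps_arm)$mean, mean(mod$fitted_proxy),
               tolerance = 1e-10)
  # dimension mismatch
  expect_error(proxy_population_mean(mod, population_summary(mean = 0, cov = matrix(1))),
               "covariates")
})

test_that("plug-in variance contribution matches a Monte-Carlo resampling oracle", {
  st <- sim_trial(seed = 7)
  fit <- rct_ppmm(y ~ z + w, data = st$df, popsum = st$popsum)
  mod <- fit$proxies$control
  Sig <- matrix(c(1.2, 0.3, 0.3, 0.8), 2)
  ps <- population_summary(mean = c(0.2, -0.1), cov = Sig, count = 500)
  v <- proxy_population_mean(mod, ps)$var
  # oracle: empirical variance of the plug-in mean over resampled mean vectors
  set.seed(99)
  L <- t(chol(Sig / 500))
  draws <- replicate(20000, {
    m <- c(0.2, -0.1) + L %*% rnorm(2)
    mod$coefficients[1] + sum(mod$coefficients[-1] * m)
  })
  expect_equal(v, var(draws), tolerance = 0.05)
  # no count -> summaries treated as fixed
  ps0 <- population_summary(mean = c(0.2, -0.1), cov = Sig)
  expect_identical(proxy_population_mean(mod, ps0)$var, 0)
})

test_that("proxy strength equals the regression R-squared in sample", {
  st <- sim_trial(seed = 11)
  fit <- rct_ppmm(y ~ z + w, data = st$df, popsum = st$popsum)
  for (side in c("treatment", "control")) {
    mod <- fit$proxies[[side]]
    idx <- st$df$arm == mod$arm_label
    y <- st$df$y[idx]
    sse <- sum((y - mod$fitted_proxy)^2)
    sst <- sum((y - mean(y))^2)
    r2_oracle <- 1 - sse / sst
    s <- fit[[if (side == "treatment") "treat" else "ctrl"]]
    expect_equal(s$rho^2, r2_oracle, tolerance = 1e-10)
    expect_gt(s$rho, 0)
  }
})

test_that("null and negative proxies are flagged", {
  set.seed(3)
  n <- 400
  df <- data.frame(z = rnorm(n), arm = rep(0:1, n / 2), y = rnorm(n))
  ps <- population_summary(mean = 0, cov = matrix(1))
  # outcome independent of the covariate: rho near 0 triggers the
  # weak-proxy warning in both arms
  w <- capture_warnings(rct_ppmm(y ~ z, data = df, popsum = ps))
  expect_length(w, 2)
  expect_match(w, "weak", all = TRUE)
  # hand-built external proxy anti-correlated with the outcome errors loudly
  d <- trial_dataset(arm = df$arm, outcome = df$y, covariates = matrix(df$z))
  mod <- fit_proxy_models(d)$treatment
  mod$fitted_proxy <- -df$y[df$arm == 1]
  expect_error(arm_summary(mod, d, ps), "<= 0")
})
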