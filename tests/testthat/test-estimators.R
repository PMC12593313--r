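test_that("adjusted mean matches hand evaluation of the closed form", {
  s <- make_arm_summary(ybar1 = 10, xbar1 = 0, xbar0 = 1, syy = 4, sxx = 1, rho = 0.5)
  # g(1) = 1/rho = 2, sqrt(syy/sxx) = 2, shift = 1
  expect_equal(adjusted_mean(s, 1), 14.0, tolerance = 1e-12)
  # g(0.5) = 1 when numerator and denominator coincide
  expect_equal(adjusted_mean(s, 0.5), 12.0, tolerance = 1e-12)
  # g(0) = rho: regression estimator
  expect_equal(adjusted_mean(s, 0), 11.0, tolerance = 1e-12)
  expect_error(adjusted_mean(s, 1.2), "\\[0, 1\\]")
  expect_error(adjusted_mean(s, -0.1), "\\[0, 1\\]")
})

test_that("no proxy shift and perfect proxies are fixed points", {
  s <- make_arm_summary(ybar1 = 5, xbar1 = 2, xbar0 = 2, syy = 3, sxx = 1.5, rho = 0.6)
  expect_equal(adjusted_mean(s, 0), 5)
  # perfect proxy: g(phi) = 1 for every phi, no sensitivity
  s1 <- make_arm_summary(ybar1 = 5, xbar1 = 0, xbar0 = 1, syy = 4, sxx = 4, rho = 1)
  vals <- adjusted_mean(s1, seq(0, 1, by = 0.1))
  expect_equal(vals, rep(vals[1], length(vals)), tolerance = 1e-12)
})

test_that("g is monotone from rho to 1/rho and drives a monotone curve", {
  for (rho in c(0.3, 0.55, 0.9)) {
    phis <- seq(0, 1, length.out = 1000)
    g <- ppmm_g(phis, rho)
    expect_equal(g[1], rho, tolerance = 1e-12)
    expect_equal(g[1000], 1 / rho, tolerance = 1e-12)
    expect_true(all(diff(g) > 0))
  }
  s <- make_arm_summary(10, 0, 0.7, 4, 1, 0.55)
  am <- adjusted_mean(s, seq(0, 1, by = 0.01))
  expect_true(all(diff(am) > 0))      # direction = sign of xbar0 - xbar1
  s_neg <- make_arm_summary(10, 0, -0.7, 4, 1, 0.55)
  expect_true(all(diff(adjusted_mean(s_neg, seq(0, 1, by = 0.01))) < 0))
})

test_that("adjusted mean is invariant to rescaling the proxy", {
  s <- make_arm_summary(ybar1 = 8, xbar1 = 1, xbar0 = 2.5, syy = 9, sxx = 2, rho = 0.45)
  for (c0 in c(0.1, 3, 40)) {
    sc <- make_arm_summary(ybar1 = 8, xbar1 = 1 * c0, xbar0 = 2.5 * c0,
                           syy = 9, sxx = 2 * c0^2, rho = 0.45)
    expect_equal(adjusted_mean(sc, c(0, 0.3, 0.7, 1)),
                 adjusted_mean(s, c(0, 0.3, 0.7, 1)), tolerance = 1e-12)
  }
})

test_that("phi = 0 reproduces the regression-of-outcome-on-proxy estimator", {
  # independent oracle: regress Y on the proxy X directly, shift by the slope
  set.seed(202)
  for (rep in 1:50) {
    st <- sim_trial(n = 200)
    fit <- suppressWarnings(rct_ppmm(y ~ z + w, data = st$df, popsum = st$popsum))
    for (side in c("treatment", "control")) {
      mod <- fit$proxies[[side]]
      s <- fit[[if (side == "treatment") "treat" else "ctrl"]]
      y <- st$df$y[st$df$arm == mod$arm_label]
      slope <- coef(lm(y ~ mod$fitted_proxy))[2]
      oracle <- mean(y) + slope * (s$xbar0 - s$xbar1)
      expect_equal(adjusted_mean(s, 0), unname(oracle), tolerance = 1e-10)
    }
  }
})

test_that("treatment effect composes adjusted means and flips under relabeling", {
  treat <- make_arm_summary(10, 0, 1, 4, 1, 0.5, arm_label = 1)
  ctrl <- make_arm_summary(9, 2, 2, 4, 1, 0.5, arm_label = 0)
  e <- treatment_effect(treat, ctrl, phi1 = 1, phi0 = 0)
  expect_equal(e$effect, 5.0, tolerance = 1e-12)        # 14 - 9
  expect_identical(e$effect, e$mu_treat - e$mu_ctrl)
  # relabel arms, swap (phi1, phi0): sign flips
  treat2 <- treat; treat2$arm_label <- 0
  ctrl2 <- ctrl; ctrl2$arm_label <- 1
  e2 <- treatment_effect(ctrl2, treat2, phi1 = 0, phi0 = 1)
  expect_equal(e2$effect, -e$effect, tolerance = 1e-12)
  # phi1 = phi0 = 0 with zero proxy shifts returns the raw difference
  t0 <- make_arm_summary(10, 1, 1, 4, 1, 0.5, arm_label = 1)
  c0 <- make_arm_summary(9, 2, 2, 4, 1, 0.5, arm_label = 0)
  expect_equal(treatment_effect(t0, c0)$effect, 1)
})

test_that("marginal effect is the participation-weighted average", {
  expect_equal(marginal_effect(1.5, 1.0, n = 200, N0 = 4800), 1.02, tolerance = 1e-12)
  expect_equal(marginal_effect(2, 2, 10, 1000), 2)
  expect_equal(marginal_effect(1.5, 1.0, 200, 1e9), 1.0, tolerance = 1e-6)
  expect_error(marginal_effect(1, 1, 10, NULL), "count")
})

test_that("sensitivity grid covers the three varying modes consistently", {
  treat <- make_arm_summary(10, 0, 1, 4, 1, 0.5, arm_label = 1)
  ctrl <- make_arm_summary(9, 1, 2.2, 5, 1.4, 0.6, arm_label = 0)
  g <- seq(0, 1, by = 0.05)
  ct <- sensitivity_grid(treat, ctrl, "treatment", g)
  cc <- sensitivity_grid(treat, ctrl, "control", g)
  cb <- sensitivity_grid(treat, ctrl, "both", g)
  # single point 0 reproduces the ignorable estimate
  one <- sensitivity_grid(treat, ctrl, "treatment", 0)
  expect_equal(one$effect, treatment_effect(treat, ctrl)$effect)
  # monotone in phi when the proxy shift is nonzero and 0 < rho < 1
  expect_true(all(diff(ct$effect) > 0))
  # equal-phi curve pairs the one-sided group means at each phi
  expect_equal(cb$mu_treat, ct$mu_treat, tolerance = 1e-12)
  expect_equal(cb$mu_ctrl, cc$mu_ctrl, tolerance = 1e-12)
  expect_error(sensitivity_grid(treat, ctrl, "treatment", numeric(0)), "non-empty")
  expect_error(sensitivity_grid(treat, ctrl, "treatment", c(0.5, 0.2)), "increasing")
})

test_that("flat curve when proxy means agree (zero-information collapse)", {
  treat <- make_arm_summary(10, 1, 1, 4, 1, 0.5, arm_label = 1)
  ctrl <- make_arm_summary(9, 2, 2, 4, 1, 0.5, arm_label = 0)
  cb <- sensitivity_grid(treat, ctrl, "both")
  expect_equal(cb$effect, rep(1, nrow(cb)), tolerance = 1e-12)
})

test_that("tipping points interpolate the zero crossing", {
  treat <- make_arm_summary(10, 0, 1, 4, 1, 0.5, arm_label = 1)
  ctrl <- make_arm_summary(9, 1, 2.2, 5, 1.4, 0.6, arm_label = 0)
  # same sign across [0,1] -> no tipping point
  ct <- sensitivity_grid(treat, ctrl, "treatment")
  expect_true(is.na(tipping_points(ct)$estimate))
  # planted crossing: build a control-varying curve that crosses between 0.8 and 0.9
  ctrl2 <- make_arm_summary(9, 0, 0.331, 16, 1, 0.55, arm_label = 0)
  cc <- sensitivity_grid(treat, ctrl2, "control", seq(0, 1, by = 0.1))
  tp <- tipping_points(cc)$estimate
  expect_true(tp > 0.8 && tp < 0.9)
  # fine-grid oracle: the dense evaluation pins the true crossing
  fine <- sensitivity_grid(treat, ctrl2, "control", seq(0, 1, length.out = 1001))
  oracle <- fine$phi[which(diff(sign(fine$effect)) != 0)[1]]
  expect_lt(abs(tp - oracle), 0.02)
  # interval containing zero already at phi = 0
  lo <- rep(-1, nrow(cc)); hi <- rep(1, nrow(cc))
  expect_equal(tipping_points(cc, lower = lo, upper = hi)$interval, 0)
  expect_error(tipping_points(cc[1, , drop = FALSE]), "at least 2")
})
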