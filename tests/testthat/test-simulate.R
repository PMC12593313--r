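test_that("the generative model matches its moment structure", {
  cfg <- population_config(N = 200000, gamma_z = 0, gamma_w = 0, gamma_u = 0,
                           sigma2 = 4, rho_uw = 0)
  pop <- generate_population(cfg, seed = 1)
  # additive effect 1 when no effect modification
  expect_equal(mean(pop$y1 - pop$y0), 1, tolerance = 0.03)
  # variance decomposition: Var(Y0) = 1 + 1 + 1 + sigma2
  expect_equal(var(pop$y0), 7, tolerance = 0.1)
  expect_equal(var(pop$w), 1, tolerance = 0.02)
  expect_lt(abs(cor(pop$w, pop$u)), 0.02)
  cfg2 <- population_config(N = 200000, rho_uw = 0.3)
  pop2 <- generate_population(cfg2, seed = 2)
  expect_equal(cor(pop2$w, pop2$u), 0.3, tolerance = 0.02)
  expect_equal(var(pop2$w), 1, tolerance = 0.02)
  expect_lt(abs(cor(pop2$z, pop2$u)), 0.02)
  expect_error(population_config(sigma2 = 0), "positive")
  expect_error(population_config(rho_uw = 1), "inside")
})

test_that("selection probabilities follow the logistic link", {
  pop <- data.frame(z = c(0, 1, 0), w = c(0, 0, 0), u = c(0, 0, 2))
  sel <- selection_config(beta_z = 1, beta_w = 0, beta_u = 0)
  p <- selection_probabilities(pop, sel, beta0 = 0)
  expect_equal(p[1], 0.5)
  expect_equal(p[2], plogis(1), tolerance = 1e-12)   # expit(1) = 0.7311
  sel0 <- selection_config(beta_z = 0, beta_w = 0, beta_u = 0)
  expect_equal(selection_probabilities(pop, sel0, 0), rep(0.5, 3))
  # monotone in u when beta_u > 0
  selu <- selection_config(beta_u = 2)
  pu <- selection_probabilities(data.frame(z = 0, w = 0, u = sort(rnorm(50))), selu, 0)
  expect_true(all(diff(pu) > 0))
})

test_that("intercept calibration solves the expected-size equation", {
  set.seed(3)
  eta <- rnorm(5000)
  b0 <- calibrate_intercept(eta, 200)
  expect_lt(abs(sum(plogis(b0 + eta)) - 200), 1e-6)
  # symmetric case: target N/2 with eta = 0 gives beta0 = 0
  expect_equal(calibrate_intercept(rep(0, 100), 50), 0, tolerance = 1e-6)
  # dense grid-search oracle
  grid <- seq(-6, -2, by = 1e-4)
  sums <- vapply(grid, function(b) sum(plogis(b + eta)), 0)
  expect_equal(b0, grid[which.min(abs(sums - 200))], tolerance = 2e-4)
  # monotone in the target size
  expect_gt(calibrate_intercept(eta, 400), b0)
  expect_error(calibrate_intercept(eta, 0), "target_n")
})

test_that("Brewer sampling is fixed-size and honours inclusion probabilities", {
  set.seed(4)
  prob <- plogis(rnorm(5000, -3))
  for (i in 1:10) {
    s <- brewer_sample(prob, 200)
    expect_length(s, 200)
    expect_false(any(duplicated(s)))
  }
  expect_identical(brewer_sample(rep(0.5, 30), 30), 1:30)
  expect_error(brewer_sample(c(0.9, 0.01, 0.01), 2), "smaller n|flatter")
  # equal probabilities reduce to simple random sampling: empirical inclusion
  # frequencies approach n/N for every unit
  set.seed(5)
  N <- 60; n <- 12; reps <- 4000
  counts <- integer(N)
  for (r in seq_len(reps)) {
    s <- brewer_sample(rep(0.2, N), n)
    counts[s] <- counts[s] + 1L
  }
  freq <- counts / reps
  se <- sqrt((n / N) * (1 - n / N) / reps)
  expect_true(all(abs(freq - n / N) < 4 * se))
})

test_that("unequal probabilities shift inclusion toward high-probability units", {
  set.seed(6)
  N <- 40
  prob <- rep(c(1, 3), each = N / 2)    # second half 3x more likely
  counts <- integer(N)
  reps <- 3000; n <- 8
  for (r in seq_len(reps)) {
    s <- brewer_sample(prob, n)
    counts[s] <- counts[s] + 1L
  }
  pik <- n * prob / sum(prob)
  freq <- counts / reps
  expect_equal(mean(freq[1:(N/2)]), mean(pik[1:(N/2)]), tolerance = 0.02)
  expect_equal(mean(freq[(N/2 + 1):N]), mean(pik[(N/2 + 1):N]), tolerance = 0.03)
})

test_that("arm assignment is an even random half-split", {
  set.seed(7)
  a <- assign_treatment(1:200)
  expect_equal(sum(a == 1), 100)
  expect_equal(sum(a == 0), 100)
  expect_error(assign_treatment(1:7), "even")
  # assignment frequencies are uniform across positions
  tot <- integer(20)
  for (r in 1:2000) tot <- tot + assign_treatment(1:20)
  expect_true(all(abs(tot / 2000 - 0.5) < 4 * sqrt(0.25 / 2000)))
})

test_that("nonselected summaries match direct computation and drop microdata", {
  cfg <- population_config(N = 500)
  pop <- generate_population(cfg, seed = 8)
  sel <- sort(sample(500, 100))
  ps <- summarize_nonselected(pop, sel)
  expect_s3_class(ps, "population_summary")
  expect_equal(ps$count, 400)
  ns <- pop[-sel, c("z", "w")]
  expect_equal(ps$mean, unname(colMeans(ns)), ignore_attr = TRUE)
  expect_equal(ps$cov, cov(ns), ignore_attr = TRUE, tolerance = 1e-12)
  # the unobserved modifier u never enters the summary
  expect_false(any(grepl("u", names(unlist(ps[c("mean", "cov")])))))
  expect_equal(ps$p, 2)
})

test_that("the true nonselected effect matches a brute-force loop", {
  cfg <- population_config(N = 300, gamma_u = 1)
  pop <- generate_population(cfg, seed = 9)
  sel <- 1:60
  acc <- 0
  for (i in setdiff(1:300, sel)) acc <- acc + (pop$y1[i] - pop$y0[i])
  expect_equal(true_nonselected_effect(pop, sel), acc / 240, tolerance = 1e-12)
  # invariant to how selected units would be assigned
  expect_equal(true_nonselected_effect(pop, sel), true_nonselected_effect(pop, rev(sel)))
  # no effect modification: approaches the additive effect 1
  cfg0 <- population_config(N = 50000, gamma_u = 0)
  pop0 <- generate_population(cfg0, seed = 10)
  expect_equal(true_nonselected_effect(pop0, 1:100), 1, tolerance = 0.05)
})
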