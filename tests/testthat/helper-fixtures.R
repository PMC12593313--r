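# Shared in-code fixtures: small simulated trials and hand-built summaries.

# Arm summary with moments set directly (for closed-form checks).
make_arm_summary <- function(ybar1, xbar1, xbar0, syy, sxx, rho,
                             arm_label = 1, n_arm = 100, xbar0_var = 0) {
  structure(list(ybar1 = ybar1, xbar1 = xbar1, xbar0 = xbar0,
                 xbar0_var = xbar0_var, syy = syy, sxx = sxx, rho = rho,
                 n_arm = n_arm, arm_label = arm_label, weak_proxy = FALSE),
            class = "arm_summary")
}

# Simulated two-arm trial with linear outcome model; returns the data frame
# and a population summary for two covariates.
sim_trial <- function(n = 200, sigma = 1, pop_mean = c(0.5, -0.3),
                      count = 4800, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(z = rnorm(n), w = rnorm(n), arm = rep(0:1, n / 2))
  df$y <- 1 + df$z + 0.5 * df$w + df$arm * (1 + 0.5 * df$z) + rnorm(n, sd = sigma)
  ps <- population_summary(mean = pop_mean, cov = diag(2), count = count)
  list(df = df, popsum = ps)
}
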