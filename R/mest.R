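#' Sandwich (M-estimation) standard error of the RCT-PPMM effect
#'
#' Frequentist standard error and Wald interval for the nonparticipant
#' treatment effect at fixed sensitivity values, by stacking per-arm
#' estimating equations for the proxy-regression coefficients, the
#' outcome/proxy means and second moments, and applying the delta method
#' through the pattern-mixture transformation.
#'
#' @details The stacked parameter vector holds, for each arm: regression
#' coefficients \eqn{\beta_a}, outcome mean \eqn{\mu_{y,a}}, proxy mean
#' \eqn{\mu_{x,a}}, and the second moments
#' \eqn{\sigma_{yy,a}, \sigma_{xx,a}, \sigma_{xy,a}} (moment equations,
#' divisor \eqn{n_a}).  The effect is a smooth function of this vector
#' plus the fixed population covariate mean; its point value is identical
#' to [treatment_effect()] because the transformation depends only on
#' scale-invariant ratios of the second moments.  The bread is computed by
#' central finite differences of the summed estimating function, the meat
#' is the empirical outer product, and the delta-method gradient is also a
#' central difference.  When the population summary carries a count, the
#' sampling variance of the nonparticipant proxy means is added
#' analytically (otherwise the summary is treated as fixed).
#'
#' @param fit an [rct_ppmm()] fit.
#' @param phi1,phi0 fixed sensitivity values in \[0,1\].
#' @param level Wald interval level (default 0.95).
#' @param popsum_uncertainty add the population-mean variance term;
#'   defaults to `TRUE` when the summary has a `count`.
#' @return An object of class `"ppmm_mest"`: list with `effect`, `se`,
#'   `ci`, `level`, `phi1`, `phi0`, `vcov_theta` (sandwich covariance of
#'   the stacked parameters).
#' @examples
#' set.seed(2)
#' df <- data.frame(z = rnorm(200), arm = rep(0:1, 100))
#' df$y <- df$z + df$arm + rnorm(200)
#' ps <- population_summary(mean = 0.3, cov = matrix(1), count = 4800)
#' fit <- rct_ppmm(y ~ z, data = df, popsum = ps)
#' ppmm_mest(fit, phi1 = 0, phi0 = 0)
#' @export
ppmm_mest <- function(fit, phi1 = 0, phi0 = 0, level = 0.95,
                      popsum_uncertainty = NULL) {
  stopifnot(inherits(fit, "rct_ppmm"))
  if (any(c(phi1, phi0) < 0) || any(c(phi1, phi0) > 1) ||
      length(phi1) != 1L || length(phi0) != 1L)
    stop("phi1 and phi0 must be single values in [0, 1]", call. = FALSE)
  if (is.null(popsum_uncertainty)) popsum_uncertainty <- !is.null(fit$popsum$count)

  trial <- fit$trial
  y <- trial$outcome
  A <- trial$arm
  X <- cbind(1, trial$covariates)   # shared design, intercept first
  k <- ncol(X)
  n <- trial$n
  m <- fit$popsum$mean

  # theta layout per arm: beta (k), mu_y, mu_x, s_yy, s_xx, s_xy
  d_arm <- k + 5L
  theta_hat <- c(arm_theta_hat(y, X, A, 1), arm_theta_hat(y, X, A, 0))

  psi_mat <- function(theta) {
    cbind(arm_psi(theta[seq_len(d_arm)], y, X, A, 1),
          arm_psi(theta[d_arm + seq_len(d_arm)], y, X, A, 0))
  }
  effect_fun <- function(theta) {
    mest_adjusted_mean(theta[seq_len(d_arm)], k, m, phi1) -
      mest_adjusted_mean(theta[d_arm + seq_len(d_arm)], k, m, phi0)
  }

  d <- 2L * d_arm
  psi_hat <- psi_mat(theta_hat)
  meat <- crossprod(psi_hat) / n
  sum_psi <- function(theta) colSums(psi_mat(theta))
  J <- num_jacobian(sum_psi, theta_hat)                 # d x d
  bread <- -J / n
  Ainv <- tryCatch(solve(bread), error = function(e)
    stop("singular bread matrix in the sandwich variance; the stacked system is degenerate",
         call. = FALSE))
  vcov_theta <- Ainv %*% meat %*% t(Ainv) / n

  grad <- num_gradient(effect_fun, theta_hat)
  v <- drop(t(grad) %*% vcov_theta %*% grad)

  if (popsum_uncertainty) {
    if (is.null(fit$popsum$count))
      stop("popsum_uncertainty = TRUE needs a population count in the summary", call. = FALSE)
    # effect depends on the population mean through k_a * slopes_a' m;
    # d effect / d m = k1 * slopes1 - k0 * slopes0
    kfac <- function(th, phi) {
      sm <- mest_second_moments(th, k)
      ppmm_g(phi, sm$rho) * sqrt(sm$syy / sm$sxx)
    }
    s1 <- theta_hat[2:k]
    s0 <- theta_hat[d_arm + (2:k)]
    gm <- kfac(theta_hat[seq_len(d_arm)], phi1) * s1 -
      kfac(theta_hat[d_arm + seq_len(d_arm)], phi0) * s0
    v <- v + drop(t(gm) %*% fit$popsum$cov %*% gm) / fit$popsum$count
  }

  se <- sqrt(max(v, 0))
  eff <- unname(effect_fun(theta_hat))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(effect = eff, se = se,
                 ci = c(lower = eff - zq * se, upper = eff + zq * se),
                 level = level, phi1 = phi1, phi0 = phi0,
                 vcov_theta = vcov_theta),
            class = "ppmm_mest")
}

#' @export
print.ppmm_mest <- function(x, ...) {
  cat(sprintf("RCT-PPMM effect at (phi1 = %.3g, phi0 = %.3g): %.5g (se %.4g)\n",
              x$phi1, x$phi0, x$effect, x$se))
  cat(sprintf("  %.0f%% Wald CI [%.5g, %.5g]\n", 100 * x$level, x$ci[1], x$ci[2]))
  invisible(x)
}

arm_theta_hat <- function(y, X, A, a) {
  idx <- A == a
  ya <- y[idx]; Xa <- X[idx, , drop = FALSE]
  na <- length(ya)
  beta <- qr.coef(qr(Xa), ya)
  x <- drop(Xa %*% beta)
  muy <- mean(ya); mux <- mean(x)
  c(beta, muy, mux,
    sum((ya - muy)^2) / na, sum((x - mux)^2) / na, sum((ya - muy) * (x - mux)) / na)
}

# n x d_arm matrix of per-unit estimating functions for one arm
# (rows for units in the other arm are zero)
arm_psi <- function(th, y, X, A, a) {
  k <- ncol(X)
  beta <- th[seq_len(k)]
  muy <- th[k + 1]; mux <- th[k + 2]
  syy <- th[k + 3]; sxx <- th[k + 4]; sxy <- th[k + 5]
  ind <- as.numeric(A == a)
  r <- y - drop(X %*% beta)
  x <- drop(X %*% beta)
  cbind(X * (ind * r),
        ind * (y - muy),
        ind * (x - mux),
        ind * ((y - muy)^2 - syy),
        ind * ((x - mux)^2 - sxx),
        ind * ((y - muy) * (x - mux) - sxy))
}

mest_second_moments <- function(th, k) {
  syy <- th[k + 3]; sxx <- th[k + 4]; sxy <- th[k + 5]
  list(syy = syy, sxx = sxx, rho = sxy / sqrt(syy * sxx))
}

mest_adjusted_mean <- function(th, k, m, phi) {
  beta <- th[seq_len(k)]
  muy <- th[k + 1]; mux <- th[k + 2]
  sm <- mest_second_moments(th, k)
  if (!(sm$rho > 0))
    stop("non-positive proxy-outcome correlation in the stacked system", call. = FALSE)
  xbar0 <- beta[1] + sum(beta[-1] * m)
  muy + ppmm_g(phi, sm$rho) * sqrt(sm$syy / sm$sxx) * (xbar0 - mux)
}

# central-difference jacobian / gradient; step scaled to parameter magnitude
num_jacobian <- function(f, x, eps = 1e-6) {
  d <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), d)
  for (j in seq_len(d)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

num_gradient <- function(f, x, eps = 1e-6) {
  drop(num_jacobian(function(z) f(z), x, eps))
}
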