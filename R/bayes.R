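#' Bayesian inference for the RCT-PPMM
#'
#' Posterior draws of the nonparticipant adjusted means and treatment
#' effect under noninformative (Jeffreys) priors on the pattern-mixture
#' parameters and fixed values or uniform priors on the sensitivity
#' parameters.  All draws are direct conjugate draws -- no MCMC, no
#' resampling -- so runtime is linear in `n_draws`.
#'
#' @details Per draw and per arm, independently:
#' \enumerate{
#'   \item residual variance of the proxy regression from its scaled
#'     inverse-chi-square posterior, then coefficients from their
#'     conditional normal posterior (Jeffreys prior on the normal linear
#'     model) -- this propagates uncertainty in the construction of the
#'     proxies;
#'   \item proxies and their arm moments rebuilt from the drawn
#'     coefficients;
#'   \item if `popsum_uncertainty`, the nonparticipant covariate mean drawn
#'     from \eqn{N(\bar z^{(0)}, \Sigma_z / N_0)};
#'   \item the arm's bivariate (outcome, proxy) covariance from its
#'     Jeffreys posterior via the standard factorization (proxy marginal
#'     variance, then the outcome-on-proxy regression), with
#'     \eqn{n_a - 1} degrees of freedom, and the mean vector from its
#'     conditional normal at \eqn{\Sigma/n_a};
#'   \item \eqn{\phi_a} from its prior (fixed value or uniform);
#'   \item the pattern-mixture transformation applied to the drawn
#'     quantities, and the effect recorded as the difference of the two
#'     adjusted-mean draws.
#' }
#' Draws in which the implied proxy-outcome correlation is not positive are
#' redrawn (up to 100 rounds); persistent failure signals a proxy too weak
#' for the analysis and raises an error rather than silently truncating.
#'
#' @param fit an [rct_ppmm()] fit.
#' @param phi1,phi0 sensitivity-parameter priors: a single fixed value in
#'   \[0,1\] or an interval `c(lo, hi)` for a Uniform(lo, hi) prior.
#'   Defaults: `phi1 = c(0, 1)` (full uniform), `phi0 = 0` (ignorable).
#' @param n_draws number of posterior draws (default 10000).
#' @param seed optional integer seed for reproducible draws.
#' @param popsum_uncertainty propagate sampling uncertainty in the
#'   nonparticipant proxy mean using the population count; defaults to
#'   `TRUE` when the [population_summary()] has a `count`, else `FALSE`.
#' @return An object of class `"ppmm_draws"`: list with `draws` (data frame
#'   with columns `phi1`, `phi0`, `mu_treat`, `mu_ctrl`, `effect`),
#'   `n_draws`, `prior` (the [sensitivity_setting()]), `seed`.
#' @examples
#' set.seed(7)
#' df <- data.frame(z = rnorm(200), arm = rep(0:1, 100))
#' df$y <- df$z + df$arm + rnorm(200)
#' ps <- population_summary(mean = 0.5, cov = matrix(1), count = 4800)
#' fit <- rct_ppmm(y ~ z, data = df, popsum = ps)
#' dr <- ppmm_bayes(fit, phi1 = c(0, 1), phi0 = 0, n_draws = 500, seed = 1)
#' credible_interval(dr)
#' @export
ppmm_bayes <- function(fit, phi1 = c(0, 1), phi0 = 0, n_draws = 10000,
                       seed = NULL, popsum_uncertainty = NULL) {
  stopifnot(inherits(fit, "rct_ppmm"))
  prior <- sensitivity_setting(phi1 = phi1, phi0 = phi0)
  if (length(n_draws) != 1L || is.na(n_draws) || n_draws < 1)
    stop("n_draws must be a positive integer", call. = FALSE)
  n_draws <- as.integer(n_draws)
  if (is.null(popsum_uncertainty)) popsum_uncertainty <- !is.null(fit$popsum$count)
  if (popsum_uncertainty && is.null(fit$popsum$count))
    stop("popsum_uncertainty = TRUE needs a population count in the summary", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  a1 <- arm_posterior_draws(fit$proxies$treatment, fit$trial, fit$popsum,
                            prior$phi1, n_draws, popsum_uncertainty)
  a0 <- arm_posterior_draws(fit$proxies$control, fit$trial, fit$popsum,
                            prior$phi0, n_draws, popsum_uncertainty)
  draws <- data.frame(phi1 = a1$phi, phi0 = a0$phi,
                      mu_treat = a1$mu0, mu_ctrl = a0$mu0,
                      effect = a1$mu0 - a0$mu0)
  structure(list(draws = draws, n_draws = n_draws, prior = prior,
                 seed = seed, popsum_uncertainty = popsum_uncertainty),
            class = "ppmm_draws")
}

# Conjugate posterior draws of one arm's nonparticipant adjusted mean.
# Vectorized over draws; redraws any draw whose implied rho <= 0.
arm_posterior_draws <- function(model, trial, popsum, phi_spec, D, popsum_uncertainty) {
  idx <- trial$arm == model$arm_label
  y <- trial$outcome[idx]
  Z <- trial$covariates[idx, , drop = FALSE]
  X <- cbind(1, Z)
  n <- length(y)
  k <- ncol(X)
  qx <- qr(X)
  bhat <- qr.coef(qx, y)
  sse <- sum((y - X %*% bhat)^2)
  XtXinv <- chol2inv(qr.R(qx))
  L <- t(chol(XtXinv))            # beta | sigma2 ~ N(bhat, sigma2 * XtXinv)
  ybar <- mean(y)
  syy <- stats::var(y)
  Lpop <- if (popsum_uncertainty) t(chol(popsum$cov / popsum$count + diag(1e-12, popsum$p))) else NULL

  draw_block <- function(m) {
    sigma2 <- sse / stats::rchisq(m, df = n - k)
    beta <- bhat + L %*% matrix(stats::rnorm(k * m), k, m) *
      rep(sqrt(sigma2), each = k)
    P <- X %*% beta                                  # n x m proxies
    xbar <- colMeans(P)
    sxx <- (colSums(P^2) - n * xbar^2) / (n - 1)
    sxy <- (colSums(P * y) - n * xbar * ybar) / (n - 1)
    # population proxy mean with the same drawn coefficients
    pm <- matrix(popsum$mean, popsum$p, m)
    if (popsum_uncertainty)
      pm <- pm + Lpop %*% matrix(stats::rnorm(popsum$p * m), popsum$p, m)
    xbar0 <- beta[1, ] + colSums(beta[-1, , drop = FALSE] * pm)
    # Jeffreys draws of the bivariate (Y, X) covariance: factorize as the
    # proxy marginal variance then the Y-on-X regression; df = n - 1
    Sxx <- (n - 1) * sxx / stats::rchisq(m, df = n - 1)
    se2_hat <- pmax(syy - sxy^2 / sxx, .Machine$double.eps)
    Se2 <- (n - 1) * se2_hat / stats::rchisq(m, df = n - 1)
    byx <- sxy / sxx + stats::rnorm(m) * sqrt(Se2 / ((n - 1) * sxx))
    Syy <- Se2 + byx^2 * Sxx
    rho <- byx * sqrt(Sxx / Syy)
    mux <- xbar + stats::rnorm(m) * sqrt(Sxx / n)
    muy <- ybar + byx * (mux - xbar) + stats::rnorm(m) * sqrt(Se2 / n)
    list(rho = rho, mux = mux, muy = muy, Sxx = Sxx, Syy = Syy, xbar0 = xbar0)
  }

  d <- draw_block(D)
  tries <- 0
  repeat {
    bad <- which(!(d$rho > 0))
    if (!length(bad)) break
    tries <- tries + 1
    if (tries > 100)
      stop(sprintf("arm %d proxy too weak: posterior proxy-outcome correlation repeatedly non-positive",
                   model$arm_label), call. = FALSE)
    r <- draw_block(length(bad))
    for (nm in names(d)) d[[nm]][bad] <- r[[nm]]
  }
  phi <- if (phi_is_fixed(phi_spec)) rep(phi_spec, D) else
    stats::runif(D, phi_spec[1], phi_spec[2])
  mu0 <- d$muy + ppmm_g(phi, d$rho) * sqrt(d$Syy / d$Sxx) * (d$xbar0 - d$mux)
  list(phi = phi, mu0 = mu0, rho = d$rho)
}

#' @export
print.ppmm_draws <- function(x, ...) {
  ci <- credible_interval(x)
  cat(sprintf("RCT-PPMM posterior (%d draws)\n", x$n_draws))
  cat(sprintf("  phi1 prior: %s; phi0 prior: %s\n",
              fmt_phi_prior(x$prior$phi1), fmt_phi_prior(x$prior$phi0)))
  cat(sprintf("  effect: mean %.5g, median %.5g, 95%% CrI [%.5g, %.5g]\n",
              mean(x$draws$effect), stats::median(x$draws$effect), ci[1], ci[2]))
  invisible(x)
}

fmt_phi_prior <- function(phi) {
  if (phi_is_fixed(phi)) sprintf("fixed at %.3g", phi)
  else sprintf("Uniform(%.3g, %.3g)", phi[1], phi[2])
}

#' @export
summary.ppmm_draws <- function(object, level = 0.95, ...) {
  d <- object$draws
  stat <- function(v) c(mean = mean(v), median = stats::median(v),
                        lower = unname(stats::quantile(v, (1 - level) / 2)),
                        upper = unname(stats::quantile(v, 1 - (1 - level) / 2)))
  out <- rbind(effect = stat(d$effect),
               mu_treat = stat(d$mu_treat),
               mu_ctrl = stat(d$mu_ctrl))
  structure(list(table = out, level = level, n_draws = object$n_draws),
            class = "summary.ppmm_draws")
}

#' @export
print.summary.ppmm_draws <- function(x, ...) {
  cat(sprintf("Posterior summaries (%d draws, %.0f%% equal-tailed intervals)\n",
              x$n_draws, 100 * x$level))
  print(signif(x$table, 5))
  invisible(x)
}

#' Equal-tailed credible interval of the effect draws
#'
#' @param draws a `"ppmm_draws"` object or a numeric vector of draws.
#' @param level interval level in (0, 1); default 0.95 (at least 100 draws
#'   recommended at the default level).
#' @return length-2 numeric `c(lower, upper)`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  v <- if (inherits(draws, "ppmm_draws")) draws$draws$effect else as.numeric(draws)
  alpha <- (1 - level) / 2
  unname(stats::quantile(v, c(alpha, 1 - alpha)))
}

#' Multi-scenario Bayesian sensitivity report
#'
#' Runs the Bayesian RCT-PPMM under a list of sensitivity-parameter
#' scenarios (e.g. selection on the control outcome,
#' \eqn{\phi_1 = 0,\ \phi_0 \sim U(0,1)}, and selection on the treatment
#' outcome) and summarizes each: posterior mean/median and credible
#' interval for the effect, a \eqn{\phi}-binned posterior curve for
#' plotting (bins of width 0.05, within-bin medians and percentile
#' intervals), and the two tipping points (effect crosses zero; interval
#' first contains zero).
#'
#' @param fit an [rct_ppmm()] fit.
#' @param scenarios named list of [sensitivity_setting()] objects (or
#'   `list(phi1 =, phi0 =)` pairs).  Default: the two one-arm scenarios
#'   with Uniform(0,1) priors.
#' @param n_draws,seed,level,popsum_uncertainty passed to [ppmm_bayes()] /
#'   [credible_interval()].
#' @param bin_width width of the phi bins for the posterior curve.
#' @return named list, one element per scenario, each with `prior`,
#'   `posterior` (mean/median/CI of effect and group means), `curve`
#'   (binned data frame), `tipping`, `draws`.
#' @export
bayes_sensitivity_report <- function(fit,
                                     scenarios = list(
                                       control_selection = list(phi1 = 0, phi0 = c(0, 1)),
                                       treatment_selection = list(phi1 = c(0, 1), phi0 = 0)),
                                     n_draws = 10000, seed = NULL, level = 0.95,
                                     popsum_uncertainty = NULL, bin_width = 0.05) {
  if (!length(scenarios)) stop("scenarios must be non-empty", call. = FALSE)
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  out <- list()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    if (!inherits(sc, "sensitivity_setting"))
      sc <- sensitivity_setting(phi1 = sc$phi1, phi0 = sc$phi0)
    dr <- ppmm_bayes(fit, phi1 = sc$phi1, phi0 = sc$phi0, n_draws = n_draws,
                     seed = if (is.null(seed)) NULL else seed + i - 1L,
                     popsum_uncertainty = popsum_uncertainty)
    post <- summary(dr, level = level)$table
    # bin by whichever phi is random (if both fixed: a single degenerate bin)
    vphi <- if (!phi_is_fixed(sc$phi1)) dr$draws$phi1 else
      if (!phi_is_fixed(sc$phi0)) dr$draws$phi0 else rep(0, n_draws)
    curve <- bin_posterior_curve(vphi, dr$draws, bin_width, level)
    tp <- if (nrow(curve) >= 2)
      tipping_points(curve, lower = curve$lower, upper = curve$upper)
    else list(estimate = NA_real_, interval = NA_real_)
    out[[names(scenarios)[i]]] <- list(prior = sc, posterior = post,
                                       curve = curve, tipping = tp, draws = dr)
  }
  out
}

bin_posterior_curve <- function(vphi, draws, bin_width, level) {
  alpha <- (1 - level) / 2
  if (diff(range(vphi)) < 1e-12) {
    q <- stats::quantile(draws$effect, c(alpha, 1 - alpha))
    return(data.frame(phi = vphi[1], effect = stats::median(draws$effect),
                      mu_treat = stats::median(draws$mu_treat),
                      mu_ctrl = stats::median(draws$mu_ctrl),
                      lower = unname(q[1]), upper = unname(q[2]), n_bin = nrow(draws)))
  }
  breaks <- seq(floor(min(vphi) / bin_width) * bin_width,
                ceiling(max(vphi) / bin_width) * bin_width, by = bin_width)
  bin <- cut(vphi, breaks = breaks, include.lowest = TRUE)
  keep <- !is.na(bin)
  agg <- function(v, f) as.numeric(tapply(v[keep], bin[keep], f))
  df <- data.frame(phi = agg(vphi, mean),
                   effect = agg(draws$effect, stats::median),
                   mu_treat = agg(draws$mu_treat, stats::median),
                   mu_ctrl = agg(draws$mu_ctrl, stats::median),
                   lower = agg(draws$effect, function(v) stats::quantile(v, alpha)),
                   upper = agg(draws$effect, function(v) stats::quantile(v, 1 - alpha)),
                   n_bin = agg(vphi, length))
  df[!is.na(df$phi), , drop = FALSE]
}
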