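#' Fit per-arm proxy regressions
#'
#' Regresses the observed outcome on the baseline covariates separately
#' within each treatment arm by ordinary least squares.  The in-sample
#' fitted values are the *proxies* \eqn{X_a}: the best observed-covariate
#' predictions of the potential outcome \eqn{Y_a} within arm \eqn{a}.
#'
#' @param data a [trial_dataset()].
#' @return A list with components `treatment` and `control`, each a
#'   `"proxy_model"`: list with `arm_label`, `coefficients` (intercept
#'   first), `residual_variance` (divisor \eqn{n_a - p - 1}),
#'   `fitted_proxy`, `lm` (the underlying [stats::lm] fit), `n_arm`.
#' @examples
#' d <- trial_dataset(rep(0:1, each = 20), rnorm(40), matrix(rnorm(80), 40, 2))
#' pm <- fit_proxy_models(d)
#' coef(pm$control$lm)
#' @export
fit_proxy_models <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  list(treatment = fit_one_proxy(data, 1),
       control   = fit_one_proxy(data, 0))
}

fit_one_proxy <- function(data, a) {
  idx <- data$arm == a
  y <- data$outcome[idx]
  Z <- data$covariates[idx, , drop = FALSE]
  # rank check with named columns so the error is actionable
  X <- cbind(`(Intercept)` = 1, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop(sprintf("proxy design matrix is rank deficient in arm %d; collinear column(s): %s",
                 a, paste(bad, collapse = ", ")), call. = FALSE)
  }
  df <- data.frame(y = y, Z, check.names = FALSE)
  fit <- stats::lm(stats::reformulate(colnames(Z), response = "y"), data = df)
  n_a <- length(y)
  rv <- sum(stats::residuals(fit)^2) / max(n_a - ncol(X), 1)
  structure(list(arm_label = a,
                 coefficients = stats::coef(fit),
                 residual_variance = rv,
                 fitted_proxy = unname(stats::fitted(fit)),
                 lm = fit,
                 n_arm = n_a),
            class = "proxy_model")
}

#' @export
print.proxy_model <- function(x, ...) {
  cat("Proxy model (arm", x$arm_label, ",", x$n_arm, "participants )\n")
  print(signif(x$coefficients, 4))
  cat("residual variance:", signif(x$residual_variance, 4), "\n")
  invisible(x)
}

#' Population proxy mean from a fitted proxy model
#'
#' The average proxy value for nonparticipants, obtained by plugging the
#' population covariate mean vector into the fitted arm regression:
#' \eqn{\bar x_a^{(0)} = \hat\beta_0 + \hat\beta' \bar z^{(0)}}.  When the
#' summary carries a nonparticipant count, the design-based variance of
#' this plug-in mean, \eqn{\hat\beta' \Sigma_z \hat\beta / N_0}, is also
#' returned (0 otherwise).
#'
#' @param model a `"proxy_model"` from [fit_proxy_models()].
#' @param popsum a [population_summary()].
#' @return list with `mean` (\eqn{\bar x_a^{(0)}}) and `var` (its variance
#'   contribution).
#' @export
proxy_population_mean <- function(model, popsum) {
  stopifnot(inherits(model, "proxy_model"), inherits(popsum, "population_summary"))
  slopes <- model$coefficients[-1]
  if (length(slopes) != popsum$p)
    stop(sprintf("population summary has %d covariates but the proxy model has %d",
                 popsum$p, length(slopes)), call. = FALSE)
  m <- unname(model$coefficients[1] + sum(slopes * popsum$mean))
  v <- if (is.null(popsum$count)) 0 else
    drop(t(slopes) %*% popsum$cov %*% slopes) / popsum$count
  list(mean = m, var = v)
}

#' Sufficient statistics of one arm for the pattern-mixture estimator
#'
#' Collects the arm-level moments that the adjusted-mean formula needs:
#' trial outcome mean and variance, trial proxy mean and variance, the
#' proxy-outcome sample correlation \eqn{\hat\rho_a^{(1)}} (the *proxy
#' strength*), and the nonparticipant proxy mean with its variance
#' contribution.  Sample variances use divisor \eqn{n_a - 1}; the
#' correlation is the Pearson sample correlation.
#'
#' @param model a `"proxy_model"`.
#' @param data the [trial_dataset()] the model was fitted on.
#' @param popsum a [population_summary()].
#' @return An object of class `"arm_summary"`: list with `ybar1`, `xbar1`,
#'   `xbar0`, `xbar0_var`, `syy`, `sxx`, `rho`, `n_arm`, `arm_label`,
#'   `weak_proxy` (TRUE when the proxy carries no covariate signal).
#' @details For OLS in-sample proxies \eqn{\hat\rho \ge 0} always holds and
#'   \eqn{\hat\rho^2} equals the regression \eqn{R^2}.  A user-supplied
#'   external proxy with \eqn{\hat\rho \le 0} is rejected: the
#'   pattern-mixture factor is undefined or sign-flipping there, and
#'   failing loudly beats silently producing a wrong-signed adjustment.
#'   When the proxy variance is exactly 0 (no covariate signal) a
#'   weak-proxy flag is recorded and the sensitivity analysis collapses to
#'   a flat, zero-width band rather than erroring.
#' @export
arm_summary <- function(model, data, popsum) {
  stopifnot(inherits(model, "proxy_model"), inherits(data, "trial_dataset"))
  idx <- data$arm == model$arm_label
  y <- data$outcome[idx]
  x <- model$fitted_proxy
  pp <- proxy_population_mean(model, popsum)
  syy <- stats::var(y)
  sxx <- stats::var(x)
  weak <- sxx <= .Machine$double.eps * max(1, syy)
  if (weak) {
    warning(sprintf("arm %d proxy has (near-)zero variance: covariates carry no outcome signal; sensitivity analysis will be flat",
                    model$arm_label), call. = FALSE)
    rho <- NA_real_
  } else {
    rho <- stats::cor(x, y)
    if (rho <= 0)
      stop(sprintf("arm %d proxy-outcome correlation is %.3f <= 0; the pattern-mixture adjustment is undefined for non-positive proxy strength",
                   model$arm_label, rho), call. = FALSE)
    if (rho < 0.2)
      warning(sprintf("arm %d proxy is weak (rho = %.3f < 0.2); sensitivity intervals will be wide and poorly informative",
                      model$arm_label, rho), call. = FALSE)
  }
  structure(list(ybar1 = mean(y), xbar1 = mean(x),
                 xbar0 = pp$mean, xbar0_var = pp$var,
                 syy = syy, sxx = if (weak) 0 else sxx,
                 rho = rho, n_arm = length(y),
                 arm_label = model$arm_label, weak_proxy = weak),
            class = "arm_summary")
}

#' @export
print.arm_summary <- function(x, ...) {
  cat(sprintf("Arm %d summary (n = %d)\n", x$arm_label, x$n_arm))
  cat(sprintf("  outcome mean %.4g (var %.4g); proxy mean %.4g (var %.4g)\n",
              x$ybar1, x$syy, x$xbar1, x$sxx))
  cat(sprintf("  nonparticipant proxy mean %.4g; proxy strength rho = %.3f%s\n",
              x$xbar0, x$rho, if (isTRUE(x$weak_proxy)) "  [weak proxy]" else ""))
  invisible(x)
}
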