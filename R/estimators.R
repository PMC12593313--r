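#' Sensitivity multiplier of the pattern-mixture adjusted mean
#'
#' \eqn{g(\phi, \rho) = (\phi + (1-\phi)\rho) / (\phi\rho + 1 - \phi)}.
#' At \eqn{\phi = 0} it equals \eqn{\rho} (ignorable selection, regression
#' estimator); at \eqn{\phi = 1} it equals \eqn{1/\rho}; for
#' \eqn{0 < \rho < 1} it is strictly increasing in \eqn{\phi}.
#'
#' @param phi sensitivity parameter(s) in \[0,1\].
#' @param rho proxy-outcome correlation(s) in (0,1\].
#' @return numeric vector.
#' @keywords internal
#' @export
ppmm_g <- function(phi, rho) (phi + (1 - phi) * rho) / (phi * rho + 1 - phi)

#' Pattern-mixture adjusted mean for one arm
#'
#' The maximum-likelihood estimate of the nonparticipant potential-outcome
#' mean \eqn{\mu_y^{(a)(0)}} at sensitivity value \eqn{\phi_a}:
#' \deqn{\hat\mu_y^{(a)(0)} = \bar y_a^{(1)} +
#'   \frac{\phi_a + (1-\phi_a)\hat\rho}{\phi_a\hat\rho + (1-\phi_a)}
#'   \sqrt{\hat\sigma_{yy}/\hat\sigma_{xx}}\,
#'   (\bar x_a^{(0)} - \bar x_a^{(1)}).}
#' At \eqn{\phi_a = 0} this reduces to the standard regression estimator
#' \eqn{\bar y + \hat\beta_{y.x}(\bar x^{(0)} - \bar x^{(1)})} assumed by
#' ignorable-selection generalizability methods.
#'
#' @param s an [arm_summary()].
#' @param phi sensitivity parameter in \[0,1\] (vectorized).
#' @return adjusted mean(s), one per `phi`.
#' @examples
#' s <- structure(list(ybar1 = 10, xbar1 = 0, xbar0 = 1, xbar0_var = 0,
#'                     syy = 4, sxx = 1, rho = 0.5, n_arm = 100,
#'                     arm_label = 1, weak_proxy = FALSE),
#'                class = "arm_summary")
#' adjusted_mean(s, c(0, 0.5, 1))  # 12 at phi = 0.5, 14 at phi = 1
#' @export
adjusted_mean <- function(s, phi) {
  stopifnot(inherits(s, "arm_summary"))
  phi <- as.numeric(phi)
  if (anyNA(phi) || any(phi < 0) || any(phi > 1))
    stop("phi must lie in [0, 1]", call. = FALSE)
  dx <- s$xbar0 - s$xbar1
  if (isTRUE(s$weak_proxy) || s$sxx == 0) {
    # no covariate signal: zero-width, flat sensitivity band
    if (abs(dx) > sqrt(.Machine$double.eps) * max(1, abs(s$ybar1)))
      stop("proxy variance is 0 but the proxy means differ; inputs are inconsistent",
           call. = FALSE)
    return(rep(s$ybar1, length(phi)))
  }
  s$ybar1 + ppmm_g(phi, s$rho) * sqrt(s$syy / s$sxx) * dx
}

#' RCT-PPMM treatment effect for nonparticipants at fixed sensitivity values
#'
#' Difference of the two adjusted means,
#' \eqn{\hat\mu_y^{(1)(0)} - \hat\mu_y^{(0)(0)}}, at a fixed pair
#' \eqn{(\phi_1, \phi_0)}.
#'
#' @param treat,ctrl [arm_summary()] objects for the treatment and control
#'   arm.
#' @param setting a [sensitivity_setting()] with both values fixed, or a
#'   numeric pair may be given via `phi1`/`phi0`.
#' @param phi1,phi0 fixed sensitivity values, used when `setting` is NULL.
#' @return An object of class `"ppmm_estimate"`: list with `mu_treat`,
#'   `mu_ctrl`, `effect` (`= mu_treat - mu_ctrl`), `phi1`, `phi0`.
#' @export
treatment_effect <- function(treat, ctrl, setting = NULL, phi1 = 0, phi0 = 0) {
  if (!is.null(setting)) {
    stopifnot(inherits(setting, "sensitivity_setting"))
    if (!phi_is_fixed(setting$phi1) || !phi_is_fixed(setting$phi0))
      stop("treatment_effect needs fixed phi values; interval settings are for the Bayesian analysis",
           call. = FALSE)
    phi1 <- setting$phi1; phi0 <- setting$phi0
  }
  if (treat$arm_label != 1 || ctrl$arm_label != 0)
    stop("treat must summarize arm 1 and ctrl arm 0", call. = FALSE)
  mu1 <- adjusted_mean(treat, phi1)
  mu0 <- adjusted_mean(ctrl, phi0)
  structure(list(mu_treat = mu1, mu_ctrl = mu0, effect = mu1 - mu0,
                 phi1 = phi1, phi0 = phi0),
            class = "ppmm_estimate")
}

#' @export
print.ppmm_estimate <- function(x, ...) {
  cat(sprintf("RCT-PPMM estimate at (phi1 = %.3g, phi0 = %.3g)\n", x$phi1, x$phi0))
  cat(sprintf("  mu_treat = %.6g, mu_ctrl = %.6g, effect = %.6g\n",
              x$mu_treat, x$mu_ctrl, x$effect))
  invisible(x)
}

#' Marginal (whole-population) treatment effect
#'
#' When the trial sample is a subset of the target population, the marginal
#' effect is the participation-weighted average of the trial effect and the
#' nonparticipant effect: \eqn{(n\,\hat\Delta_{S=1} + N_0\,\hat\Delta_{S=0})/(n + N_0)}.
#'
#' @param trial_effect effect estimate among participants.
#' @param nonselected_effect effect estimate among nonparticipants.
#' @param n number of trial participants.
#' @param N0 number of nonparticipants (from [population_summary()] `count`).
#' @return scalar marginal effect.
#' @export
marginal_effect <- function(trial_effect, nonselected_effect, n, N0) {
  if (is.null(N0) || length(N0) != 1L || is.na(N0))
    stop("the marginal effect needs a nonparticipant population count N0", call. = FALSE)
  if (n < 1 || N0 < 1) stop("n and N0 must be >= 1", call. = FALSE)
  (n * trial_effect + N0 * nonselected_effect) / (n + N0)
}

#' Sensitivity curve over a grid of phi values
#'
#' Evaluates the nonparticipant treatment effect over a grid of sensitivity
#' values, varying one arm's \eqn{\phi} while holding the other at 0
#' (the recommended one-arm-at-a-time analysis), or moving both together
#' (`varying = "both"`, the equal-\eqn{\phi} scenario).
#'
#' @param treat,ctrl [arm_summary()] objects.
#' @param varying one of `"treatment"` (`phi1` varies, `phi0 = 0`),
#'   `"control"` (`phi0` varies, `phi1 = 0`), `"both"`
#'   (`phi1 = phi0 = phi`).
#' @param grid strictly increasing values in \[0,1\]; default
#'   `seq(0, 1, by = 0.05)`.
#' @return An object of class `"sensitivity_curve"`: a data frame with
#'   columns `phi`, `phi1`, `phi0`, `mu_treat`, `mu_ctrl`, `effect`, and
#'   attribute `varying`.
#' @export
sensitivity_grid <- function(treat, ctrl, varying = c("treatment", "control", "both"),
                             grid = seq(0, 1, by = 0.05)) {
  varying <- match.arg(varying)
  grid <- as.numeric(grid)
  if (length(grid) == 0) stop("grid must be non-empty", call. = FALSE)
  if (any(grid < 0) || any(grid > 1)) stop("grid must lie in [0, 1]", call. = FALSE)
  if (length(grid) > 1 && any(diff(grid) <= 0))
    stop("grid must be strictly increasing", call. = FALSE)
  phi1 <- switch(varying, treatment = grid, control = rep(0, length(grid)), both = grid)
  phi0 <- switch(varying, treatment = rep(0, length(grid)), control = grid, both = grid)
  mu1 <- adjusted_mean(treat, phi1)
  mu0 <- adjusted_mean(ctrl, phi0)
  out <- data.frame(phi = grid, phi1 = phi1, phi0 = phi0,
                    mu_treat = mu1, mu_ctrl = mu0, effect = mu1 - mu0)
  attr(out, "varying") <- varying
  class(out) <- c("sensitivity_curve", "data.frame")
  out
}

#' Tipping points of a sensitivity curve
#'
#' Finds (a) the smallest \eqn{\phi} at which the point-estimate effect
#' changes sign (linear interpolation between adjacent grid points) and,
#' when per-\eqn{\phi} intervals are supplied, (b) the smallest \eqn{\phi}
#' at which the interval first contains zero.  Absence of a crossing inside
#' the grid is reported as `NA`, not an error.
#'
#' @param curve a `"sensitivity_curve"` (or any data frame with `phi` and
#'   `effect` columns) on a grid of at least 2 points.
#' @param lower,upper optional per-`phi` interval bounds (same length as
#'   the grid).
#' @return list with `estimate` (phi where the effect crosses zero, rounded
#'   to 2 decimals, or `NA`) and `interval` (phi where \[lower, upper\]
#'   first contains 0, or `NA`; `NULL` when no bounds given).
#' @export
tipping_points <- function(curve, lower = NULL, upper = NULL) {
  phi <- curve$phi
  eff <- curve$effect
  if (length(phi) < 2) stop("tipping-point search needs a grid of at least 2 points", call. = FALSE)
  est <- NA_real_
  sg <- sign(eff)
  if (any(sg == 0)) {
    est <- phi[which(sg == 0)[1]]
  } else {
    flips <- which(sg[-1] != sg[-length(sg)])
    if (length(flips)) {
      i <- flips[1]
      est <- phi[i] + (0 - eff[i]) * (phi[i + 1] - phi[i]) / (eff[i + 1] - eff[i])
    }
  }
  if (!is.na(est)) est <- round(est, 2)
  iv <- NULL
  if (!is.null(lower) && !is.null(upper)) {
    stopifnot(length(lower) == length(phi), length(upper) == length(phi))
    hit <- which(lower <= 0 & upper >= 0)
    iv <- if (length(hit)) phi[hit[1]] else NA_real_
  }
  list(estimate = est, interval = iv)
}
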