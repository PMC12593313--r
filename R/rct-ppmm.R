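#' Fit the RCT proxy pattern-mixture model
#'
#' The single entry point for the sensitivity analysis.  Fits per-arm proxy
#' regressions of the outcome on baseline covariates, computes each arm's
#' sufficient statistics against the target-population covariate summary,
#' and returns a model object from which adjusted means, sensitivity
#' curves, tipping points, Bayesian credible intervals
#' ([ppmm_bayes()]) and sandwich standard errors ([ppmm_mest()]) are
#' derived.
#'
#' @section Model:
#' Within each arm \eqn{a}, the outcome \eqn{Y_a} and its regression proxy
#' \eqn{X_a} are taken to be bivariate normal with pattern-specific
#' parameters for participants (\eqn{S=1}) and nonparticipants
#' (\eqn{S=0}).  The nonparticipant parameters are identified only under
#' an assumption on the selection mechanism, indexed by
#' \eqn{\phi_a \in [0,1]}: selection depends on
#' \eqn{(1-\phi_a) X_a^* + \phi_a Y_a} (proxy standardized to the outcome
#' scale).  \eqn{\phi_a = 0} is ignorable selection; \eqn{\phi_a = 1} is
#' selection entirely on the potential outcome.  See [adjusted_mean()] for
#' the closed form.
#'
#' @param formula model formula `outcome ~ covariates` used for the proxy
#'   regressions, e.g. `y ~ z + w`.
#' @param data data frame holding the outcome, covariates and arm column.
#' @param arm name of the 0/1 treatment-arm column in `data` (default
#'   `"arm"`), or a 0/1 vector of length `nrow(data)`.
#' @param popsum a [population_summary()] of the same covariates, in the
#'   order they enter the model matrix.
#' @return An object of class `"rct_ppmm"`: list with `trial`
#'   ([trial_dataset()]), `popsum`, `proxies` (per-arm proxy models),
#'   `treat`/`ctrl` ([arm_summary()]), `call`, `terms`.
#' @examples
#' set.seed(1)
#' df <- data.frame(z = rnorm(120), w = rnorm(120), arm = rep(0:1, 60))
#' df$y <- 1 + df$z + 0.5 * df$w + df$arm + rnorm(120)
#' ps <- population_summary(mean = c(0.4, -0.2), cov = diag(2), count = 4800)
#' fit <- rct_ppmm(y ~ z + w, data = df, popsum = ps)
#' fit
#' coef(fit)
#' treatment_effect(fit$treat, fit$ctrl, phi1 = 0.5, phi0 = 0)
#' @seealso [sensitivity_grid()], [tipping_points()], [ppmm_bayes()],
#'   [ppmm_mest()]
#' @export
rct_ppmm <- function(formula, data, arm = "arm", popsum, ...) {
  cl <- match.call()
  if (is.character(arm)) {
    if (!arm %in% names(data))
      stop(sprintf("arm column '%s' not found in data", arm), call. = FALSE)
    arm_vec <- data[[arm]]
  } else {
    arm_vec <- arm
  }
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  mt <- attr(mf, "terms")
  X <- stats::model.matrix(mt, mf)
  has_int <- attr(mt, "intercept") == 1
  if (!has_int) stop("the proxy regression must include an intercept", call. = FALSE)
  Z <- X[, -1, drop = FALSE]
  trial <- trial_dataset(arm = arm_vec, outcome = y, covariates = Z)
  stopifnot(inherits(popsum, "population_summary"))
  if (popsum$p != ncol(Z))
    stop(sprintf("population summary covers %d covariates but the model uses %d (%s)",
                 popsum$p, ncol(Z), paste(colnames(Z), collapse = ", ")), call. = FALSE)
  proxies <- fit_proxy_models(trial)
  treat <- arm_summary(proxies$treatment, trial, popsum)
  ctrl <- arm_summary(proxies$control, trial, popsum)
  structure(list(trial = trial, popsum = popsum, proxies = proxies,
                 treat = treat, ctrl = ctrl, call = cl, terms = mt),
            class = "rct_ppmm")
}

#' @export
print.rct_ppmm <- function(x, digits = 4, ...) {
  cat("RCT proxy pattern-mixture model\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Trial: n = %d (%d treatment / %d control), %d covariates\n",
              x$trial$n, x$treat$n_arm, x$ctrl$n_arm, x$trial$p))
  cat(sprintf("Proxy strength: rho1 = %.3f (treatment), rho0 = %.3f (control)\n",
              x$treat$rho, x$ctrl$rho))
  e0 <- treatment_effect(x$treat, x$ctrl, phi1 = 0, phi0 = 0)
  cat(sprintf("Nonparticipant effect at ignorable selection (phi1 = phi0 = 0): %.*g\n",
              digits, e0$effect))
  invisible(x)
}

#' @export
coef.rct_ppmm <- function(object, ...) {
  rbind(treatment = object$proxies$treatment$coefficients,
        control = object$proxies$control$coefficients)
}

#' Predict proxies from a fitted RCT-PPMM
#'
#' Returns the in-sample proxies (per-arm fitted values) or, given
#' `newdata`, predictions from the requested arm's proxy regression.
#'
#' @param object an `"rct_ppmm"` fit.
#' @param newdata optional data frame of covariates.
#' @param which_arm `"assigned"` (in-sample, each participant's own arm) or
#'   `0`/`1` to use that arm's model.
#' @param ... unused.
#' @export
predict.rct_ppmm <- function(object, newdata = NULL, which_arm = "assigned", ...) {
  if (is.null(newdata)) {
    if (identical(which_arm, "assigned")) {
      out <- numeric(object$trial$n)
      out[object$trial$arm == 1] <- object$proxies$treatment$fitted_proxy
      out[object$trial$arm == 0] <- object$proxies$control$fitted_proxy
      return(out)
    }
    newdata <- as.data.frame(object$trial$covariates)
  }
  if (identical(which_arm, "assigned"))
    stop("which_arm must be 0 or 1 when newdata is supplied", call. = FALSE)
  mod <- if (which_arm == 1) object$proxies$treatment$lm else object$proxies$control$lm
  unname(stats::predict(mod, newdata = newdata))
}

#' @export
residuals.rct_ppmm <- function(object, ...) {
  object$trial$outcome - predict(object)
}

#' Summarize an RCT-PPMM sensitivity analysis
#'
#' Evaluates both one-arm-at-a-time sensitivity curves on a grid, reports
#' the effect at \eqn{\phi = \{0, 0.5, 1\}} for each, and the point-estimate
#' tipping points.
#'
#' @param object an `"rct_ppmm"` fit.
#' @param grid phi grid (default steps of 0.05).
#' @param ... unused.
#' @return `"summary.rct_ppmm"` with elements `fit`, `curve_treatment`,
#'   `curve_control`, `tipping`.
#' @export
summary.rct_ppmm <- function(object, grid = seq(0, 1, by = 0.05), ...) {
  ct <- sensitivity_grid(object$treat, object$ctrl, "treatment", grid)
  cc <- sensitivity_grid(object$treat, object$ctrl, "control", grid)
  structure(list(fit = object,
                 curve_treatment = ct, curve_control = cc,
                 tipping = list(treatment = tipping_points(ct)$estimate,
                                control = tipping_points(cc)$estimate)),
            class = "summary.rct_ppmm")
}

#' @export
print.summary.rct_ppmm <- function(x, ...) {
  print(x$fit)
  show <- function(curve, lab) {
    at <- curve[curve$phi %in% c(0, 0.5, 1), c("phi", "mu_treat", "mu_ctrl", "effect")]
    cat(sprintf("\nSelection on the %s outcome (phi_%s varies, other arm ignorable):\n",
                lab, if (lab == "treatment") "1" else "0"))
    print(format(at, digits = 4), row.names = FALSE)
  }
  show(x$curve_treatment, "treatment")
  show(x$curve_control, "control")
  fmt_tp <- function(v) if (is.na(v)) "none in [0, 1]" else sprintf("%.2f", v)
  cat(sprintf("\nTipping points (effect crosses zero): phi1 = %s, phi0 = %s\n",
              fmt_tp(x$tipping$treatment), fmt_tp(x$tipping$control)))
  invisible(x)
}

#' Plot an RCT-PPMM sensitivity analysis
#'
#' Base-graphics plot of the nonparticipant treatment effect against the
#' varying sensitivity parameter for both one-arm scenarios, with a zero
#' reference line.
#'
#' @param x an `"rct_ppmm"` fit.
#' @param grid phi grid.
#' @param ... passed to [graphics::matplot].
#' @export
plot.rct_ppmm <- function(x, grid = seq(0, 1, by = 0.05), ...) {
  ct <- sensitivity_grid(x$treat, x$ctrl, "treatment", grid)
  cc <- sensitivity_grid(x$treat, x$ctrl, "control", grid)
  graphics::matplot(grid, cbind(ct$effect, cc$effect), type = "l", lty = 1:2,
                    col = c("darkgreen", "navy"),
                    xlab = expression(phi[a]), ylab = "Nonparticipant treatment effect",
                    main = "RCT-PPMM sensitivity analysis", ...)
  graphics::abline(h = 0, col = "grey60")
  graphics::legend("topright", lty = 1:2, col = c("darkgreen", "navy"), bty = "n",
                   legend = c(expression(phi[1] ~ "varies," ~ phi[0] == 0),
                              expression(phi[0] ~ "varies," ~ phi[1] == 0)))
  invisible(x)
}
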