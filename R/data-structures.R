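#' Construct a trial dataset
#'
#' Bundles participant-level randomized-trial data: a binary treatment arm
#' indicator, a continuous outcome, and a numeric matrix of baseline
#' covariates.  These are the selected (\eqn{S=1}) units of a target
#' population; everything downstream (proxy construction, sensitivity
#' analysis) starts from this container.
#'
#' @param arm integer/numeric vector of 0 (control) / 1 (treatment).
#' @param outcome numeric vector of continuous outcomes, one per participant.
#' @param covariates numeric matrix or data frame of baseline covariates,
#'   one row per participant.  Column names are kept for reporting.
#' @param ids optional vector of unit labels.
#'
#' @return An object of class `"trial_dataset"`: a list with elements
#'   `arm`, `outcome`, `covariates` (matrix), `ids`, `n`, `p`.
#' @examples
#' d <- trial_dataset(arm = rep(0:1, each = 10),
#'                    outcome = rnorm(20),
#'                    covariates = matrix(rnorm(40), 20, 2,
#'                                        dimnames = list(NULL, c("z", "w"))))
#' d$n
#' @export
trial_dataset <- function(arm, outcome, covariates, ids = NULL) {
  arm <- as.numeric(arm)
  outcome <- as.numeric(outcome)
  if (is.data.frame(covariates)) covariates <- as.matrix(covariates)
  if (!is.matrix(covariates)) covariates <- matrix(covariates, ncol = 1L)
  storage.mode(covariates) <- "double"
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("z", seq_len(ncol(covariates)))
  n <- length(outcome)
  p <- ncol(covariates)
  if (length(arm) != n || nrow(covariates) != n)
    stop("arm, outcome and covariates must describe the same participants", call. = FALSE)
  if (!all(arm %in% c(0, 1)))
    stop("arm must contain only 0 (control) and 1 (treatment)", call. = FALSE)
  if (anyNA(arm) || anyNA(outcome) || anyNA(covariates))
    stop("trial data must not contain missing values", call. = FALSE)
  n1 <- sum(arm == 1); n0 <- sum(arm == 0)
  if (n1 == 0 || n0 == 0)
    stop("both trial arms must be non-empty", call. = FALSE)
  # p+2 per arm so the residual variance and proxy-outcome correlation are estimable
  if (min(n1, n0) < p + 2)
    stop(sprintf("each arm needs at least p + 2 = %d participants (treatment has %d, control has %d)",
                 p + 2, n1, n0), call. = FALSE)
  if (!is.null(ids) && length(ids) != n)
    stop("ids must have one label per participant", call. = FALSE)
  structure(list(arm = arm, outcome = outcome, covariates = covariates,
                 ids = ids, n = n, p = p),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Trial dataset:", x$n, "participants (",
      sum(x$arm == 1), "treatment /", sum(x$arm == 0), "control ),",
      x$p, "baseline covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a target-population covariate summary
#'
#' Aggregate covariate information for the nonparticipant (\eqn{S=0})
#' population: the mean vector and covariance matrix of the baseline
#' covariates, and optionally the number of nonparticipant units.  Only
#' these summaries -- never nonparticipant microdata -- are needed by the
#' sensitivity analysis.
#'
#' @param mean numeric covariate mean vector.
#' @param cov covariate covariance matrix (symmetric positive semi-definite).
#' @param count optional number of nonparticipant units (\eqn{N_0 \ge 1});
#'   enables uncertainty propagation for the population proxy mean and the
#'   marginal (whole-population) treatment effect.
#'
#' @return An object of class `"population_summary"`.
#' @examples
#' population_summary(mean = c(0, 0), cov = diag(2), count = 4800)
#' @export
population_summary <- function(mean, cov, count = NULL) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  storage.mode(cov) <- "double"
  p <- length(mean)
  if (!all(dim(cov) == c(p, p)))
    stop("cov must be a square matrix matching the length of mean", call. = FALSE)
  if (anyNA(mean) || anyNA(cov))
    stop("population summary must not contain missing values", call. = FALSE)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance matrix must be symmetric", call. = FALSE)
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev))))
    stop(sprintf("covariance matrix must be positive semi-definite (smallest eigenvalue %.3g)",
                 min(ev)), call. = FALSE)
  if (!is.null(count)) {
    count <- as.numeric(count)
    if (length(count) != 1L || is.na(count) || count < 1)
      stop("count must be a single number >= 1", call. = FALSE)
  }
  structure(list(mean = mean, cov = (cov + t(cov)) / 2, count = count, p = p),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat("Population covariate summary (", x$p, "covariates",
      if (!is.null(x$count)) paste0(", N0 = ", format(x$count)), ")\n")
  cat("  mean:", paste(signif(x$mean, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Sensitivity-parameter setting for the two trial arms
#'
#' Each arm's sensitivity parameter \eqn{\phi_a \in [0,1]} indexes how much
#' of the selection mechanism acts through the potential outcome \eqn{Y_a}
#' rather than its observed proxy: 0 is ignorable selection (selection at
#' random given covariates), 1 is selection entirely on the outcome.  A
#' setting may fix each \eqn{\phi_a} to a value or give an interval
#' \eqn{[lo, hi] \subseteq [0,1]} to be treated as a uniform prior range.
#'
#' @param phi1,phi0 either a single value in \[0,1\] or a length-2
#'   increasing vector `c(lo, hi)` inside \[0,1\].
#' @return An object of class `"sensitivity_setting"`.
#' @examples
#' sensitivity_setting(phi1 = c(0, 1), phi0 = 0)
#' @export
sensitivity_setting <- function(phi1 = 0, phi0 = 0) {
  chk <- function(phi, nm) {
    phi <- as.numeric(phi)
    if (!length(phi) %in% 1:2 || anyNA(phi))
      stop(nm, " must be one value or an interval c(lo, hi)", call. = FALSE)
    if (any(phi < 0) || any(phi > 1))
      stop(nm, " must lie in [0, 1]", call. = FALSE)
    if (length(phi) == 2L && phi[1] >= phi[2])
      stop(nm, " interval bounds must be increasing", call. = FALSE)
    phi
  }
  structure(list(phi1 = chk(phi1, "phi1"), phi0 = chk(phi0, "phi0")),
            class = "sensitivity_setting")
}

phi_is_fixed <- function(phi) length(phi) == 1L
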