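#' Configuration of the simulated target population
#'
#' Generative model for a finite population of size `N` with one observed
#' covariate `Z`, an unobserved effect modifier `U`, and a partially
#' informative observed covariate `W` correlated with `U`:
#' \deqn{Z \sim N(0,1),\quad U \sim N(0,1),\ Z \perp U,\quad
#'       W \sim N(\rho_{UW} U,\ 1 - \rho_{UW}^2),}
#' \deqn{Y_0 \sim N(Z + W + U,\ \sigma^2),\quad
#'       Y_1 \sim N(1 + (1+\gamma_Z)Z + (1+\gamma_W)W + (1+\gamma_U)U,\ \sigma^2).}
#' The average treatment effect is modified by whichever covariates have
#' \eqn{\gamma > 0}; \eqn{\sigma^2} controls the proxy strength
#' (\eqn{\sigma^2 = \{1, 4, 13\}} give arm proxy correlations of roughly
#' 0.7, 0.55, 0.4).
#'
#' @param N population size (default 5000).
#' @param gamma_z,gamma_w,gamma_u effect-modification coefficients
#'   (defaults 0, 0, 1: modification by the unobserved `U` only).
#' @param sigma2 residual outcome variance (default 4, a moderately strong
#'   proxy).
#' @param rho_uw correlation between `W` and `U` in (-1, 1) (default 0).
#' @return `"population_config"` list.
#' @export
population_config <- function(N = 5000, gamma_z = 0, gamma_w = 0, gamma_u = 1,
                              sigma2 = 4, rho_uw = 0) {
  if (N < 2) stop("N must be at least 2", call. = FALSE)
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  if (abs(rho_uw) >= 1) stop("rho_uw must be inside (-1, 1)", call. = FALSE)
  structure(list(N = as.integer(N), gamma_z = gamma_z, gamma_w = gamma_w,
                 gamma_u = gamma_u, sigma2 = sigma2, rho_uw = rho_uw),
            class = "population_config")
}

#' Configuration of the trial-selection mechanism
#'
#' Logistic selection into the trial,
#' \eqn{\mathrm{logit}\,\Pr(S=1 \mid Z, W, U) = \beta_0 + \beta_Z Z +
#' \beta_W W + \beta_U U}, with the intercept calibrated (not user-set) so
#' the expected sample size equals `n_sample`, and a fixed-size
#' unequal-probability (Brewer) draw of exactly `n_sample` units.
#'
#' @param beta_z,beta_w,beta_u logistic selection coefficients.  A nonzero
#'   `beta_u` makes selection nonignorable given the observed covariates.
#' @param n_sample trial sample size (default 200; must be below `N`).
#' @return `"selection_config"` list.
#' @export
selection_config <- function(beta_z = 0, beta_w = 0, beta_u = 1, n_sample = 200) {
  if (n_sample < 2) stop("n_sample must be at least 2", call. = FALSE)
  structure(list(beta_z = beta_z, beta_w = beta_w, beta_u = beta_u,
                 n_sample = as.integer(n_sample)),
            class = "selection_config")
}

#' Generate a finite population of potential outcomes
#'
#' @param cfg a [population_config()].
#' @param seed optional integer seed.
#' @return data frame with columns `id`, `z`, `w`, `u`, `y0`, `y1`.
#' @export
generate_population <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "population_config"))
  if (!is.null(seed)) set.seed(seed)
  N <- cfg$N
  z <- stats::rnorm(N)
  u <- stats::rnorm(N)
  w <- cfg$rho_uw * u + sqrt(1 - cfg$rho_uw^2) * stats::rnorm(N)
  s <- sqrt(cfg$sigma2)
  y0 <- z + w + u + s * stats::rnorm(N)
  y1 <- 1 + (1 + cfg$gamma_z) * z + (1 + cfg$gamma_w) * w + (1 + cfg$gamma_u) * u +
    s * stats::rnorm(N)
  data.frame(id = seq_len(N), z = z, w = w, u = u, y0 = y0, y1 = y1)
}

#' Per-unit trial-selection probabilities
#'
#' Inverse-logit of \eqn{\beta_0 + \beta_Z Z + \beta_W W + \beta_U U}.
#'
#' @param pop population data frame from [generate_population()].
#' @param sel a [selection_config()].
#' @param beta0 calibrated intercept (see [calibrate_intercept()]).
#' @return numeric vector of probabilities in (0, 1).
#' @export
selection_probabilities <- function(pop, sel, beta0) {
  eta <- beta0 + sel$beta_z * pop$z + sel$beta_w * pop$w + sel$beta_u * pop$u
  stats::plogis(eta)
}

#' Calibrate the selection intercept to a target sample size
#'
#' Solves \eqn{\sum_i \mathrm{expit}(\beta_0 + \eta_i) = n} for
#' \eqn{\beta_0} by monotone bisection (the sum is strictly increasing in
#' \eqn{\beta_0}), to absolute tolerance 1e-6, auto-expanding the bracket
#' when needed.
#'
#' @param eta linear predictor without intercept, one value per unit.
#' @param target_n target expected sample size, `0 < target_n < N`.
#' @param tol absolute tolerance on the expected-size equation.
#' @param max_iter iteration cap (error on exhaustion).
#' @return scalar `beta0`.
#' @export
calibrate_intercept <- function(eta, target_n, tol = 1e-6, max_iter = 200L) {
  N <- length(eta)
  if (target_n <= 0 || target_n >= N)
    stop("target_n must satisfy 0 < target_n < N", call. = FALSE)
  f <- function(b0) sum(stats::plogis(b0 + eta)) - target_n
  lo <- -10; hi <- 10
  it <- 0L
  while (f(lo) > 0) { lo <- lo * 2; it <- it + 1L
    if (it > 60) stop("failed to bracket the selection intercept", call. = FALSE) }
  while (f(hi) < 0) { hi <- hi * 2; it <- it + 1L
    if (it > 60) stop("failed to bracket the selection intercept", call. = FALSE) }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
  stop("intercept calibration did not converge within max_iter bisections", call. = FALSE)
}

#' Fixed-size unequal-probability sampling (Brewer's method)
#'
#' Draws exactly `n` distinct units with inclusion probabilities
#' proportional to the supplied selection probabilities
#' (\eqn{\pi_i = n p_i / \sum_j p_j}, each required to be below 1).
#' Implements Brewer's sequential draw-by-draw procedure: at draw
#' \eqn{k = 1, \dots, n}, a not-yet-selected unit is drawn with probability
#' proportional to
#' \eqn{\pi_i \{n - a - (n - k + 1)\pi_i\} / (1 - \pi_i)},
#' where \eqn{a} is the sum of \eqn{\pi} over the units already selected.
#' The realized inclusion probabilities equal \eqn{\pi_i} exactly for
#' \eqn{n = 2} and to a close approximation for larger \eqn{n}.  Under
#' equal probabilities the procedure reduces to simple random sampling
#' without replacement.
#'
#' @param prob per-unit selection probabilities (any positive scale).
#' @param n sample size.
#' @param seed optional integer seed.
#' @return integer vector of `n` distinct selected indices.
#' @references Brewer, K.R.W. (1975). A simple procedure for sampling
#'   pi-ps-wor. Australian Journal of Statistics 17, 166-172.
#' @export
brewer_sample <- function(prob, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- length(prob)
  if (n > N) stop("n cannot exceed the number of units", call. = FALSE)
  if (any(prob <= 0)) stop("selection probabilities must be positive", call. = FALSE)
  if (n == N) return(seq_len(N))
  pik <- n * prob / sum(prob)
  if (any(pik >= 1))
    stop("some scaled inclusion probabilities reach 1; use a smaller n or flatter probabilities",
         call. = FALSE)
  selected <- integer(n)
  in_s <- logical(N)
  a <- 0
  for (k in seq_len(n)) {
    wt <- ifelse(in_s, 0, pik * (n - a - (n - k + 1) * pik) / (1 - pik))
    # numerical guard: weights can brush zero on late draws
    wt[wt < 0] <- 0
    j <- sample.int(N, 1L, prob = wt)
    selected[k] <- j
    in_s[j] <- TRUE
    a <- a + pik[j]
  }
  sort(selected)
}

#' Randomize selected units to trial arms
#'
#' Uniformly random half-split of the selected units into treatment
#' (`A = 1`) and control (`A = 0`).
#'
#' @param selected vector of selected unit indices (even length).
#' @param seed optional integer seed.
#' @return integer vector of arm labels aligned with `selected`.
#' @export
assign_treatment <- function(selected, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(selected)
  if (n %% 2 != 0) stop("the selected sample size must be even for a half-split", call. = FALSE)
  arm <- integer(n)
  arm[sample.int(n, n / 2)] <- 1L
  arm
}

#' Summarize nonselected units into aggregate covariate data
#'
#' Retains only the mean vector, covariance matrix and count of the
#' observed covariates (`z`, `w`) among nonselected units; all
#' nonparticipant microdata -- including the unobserved `u` -- are
#' discarded, mimicking analyses where only registry-style summary data
#' exist for the target population.
#'
#' @param pop population data frame.
#' @param selected indices of selected units.
#' @return a [population_summary()] over (`z`, `w`).
#' @export
summarize_nonselected <- function(pop, selected) {
  ns <- pop[-selected, c("z", "w"), drop = FALSE]
  if (nrow(ns) < 2) stop("need at least 2 nonselected units", call. = FALSE)
  population_summary(mean = colMeans(ns), cov = stats::cov(ns), count = nrow(ns))
}

#' True nonselected treatment effect
#'
#' Mean of \eqn{Y_1 - Y_0} over the nonselected (\eqn{S = 0}) units -- the
#' estimand of the sensitivity analysis in the simulation.
#'
#' @param pop population data frame.
#' @param selected indices of selected units.
#' @return scalar.
#' @export
true_nonselected_effect <- function(pop, selected) {
  mean(pop$y1[-selected] - pop$y0[-selected])
}
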