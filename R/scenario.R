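#' Fit the RCT-PPMM from prepared containers
#'
#' Variant of [rct_ppmm()] taking an already-built [trial_dataset()] and
#' [population_summary()] instead of a formula and data frame; used by the
#' simulation driver and by file-based workflows ([read_trial_csv()]).
#'
#' @param trial a [trial_dataset()].
#' @param popsum a [population_summary()].
#' @return an `"rct_ppmm"` object (see [rct_ppmm()]).
#' @export
rct_ppmm_fit <- function(trial, popsum) {
  stopifnot(inherits(trial, "trial_dataset"), inherits(popsum, "population_summary"))
  if (popsum$p != trial$p)
    stop(sprintf("population summary covers %d covariates but the trial has %d",
                 popsum$p, trial$p), call. = FALSE)
  proxies <- fit_proxy_models(trial)
  treat <- arm_summary(proxies$treatment, trial, popsum)
  ctrl <- arm_summary(proxies$control, trial, popsum)
  structure(list(trial = trial, popsum = popsum, proxies = proxies,
                 treat = treat, ctrl = ctrl, call = match.call(), terms = NULL),
            class = "rct_ppmm")
}

#' Run one simulation replicate
#'
#' Generates a population, calibrates the selection intercept to the target
#' sample size, draws a fixed-size Brewer sample, randomizes arms, reduces
#' the nonselected units to summary data, and analyses the trial with the
#' RCT-PPMM: MLEs at `mle_phis` for each one-arm scenario, endpoint-interval
#' coverage, and (optionally) Bayesian credible intervals under uniform
#' priors on the varying sensitivity parameter.
#'
#' @param popcfg a [population_config()].
#' @param selcfg a [selection_config()].
#' @param seed integer seed for the replicate (drives every random step).
#' @param mle_phis sensitivity values for the MLE sweep (default 0, 0.5, 1;
#'   the first and last define the endpoint interval).
#' @param bayes run the Bayesian analyses (default TRUE).
#' @param n_draws posterior draws per Bayesian analysis.
#' @param priors named list of Uniform prior supports for the varying
#'   \eqn{\phi} (default `unif01` = (0,1) and `unif005` = (0,0.5)).
#' @param level credible-interval level.
#' @return list with `truth`, `trial_est`, `rho1`, `rho0`, `mle`
#'   (matrix sides x phis), `mle_cover` (per side), and when `bayes`,
#'   `bayes_ci` / `bayes_cover` (per side and prior).
#' @export
run_replicate <- function(popcfg, selcfg, seed = NULL,
                          mle_phis = c(0, 0.5, 1), bayes = TRUE,
                          n_draws = 2000,
                          priors = list(unif01 = c(0, 1), unif005 = c(0, 0.5)),
                          level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  pop <- generate_population(popcfg)
  eta <- selcfg$beta_z * pop$z + selcfg$beta_w * pop$w + selcfg$beta_u * pop$u
  beta0 <- calibrate_intercept(eta, selcfg$n_sample)
  prob <- stats::plogis(beta0 + eta)
  sel <- brewer_sample(prob, selcfg$n_sample)
  arm <- assign_treatment(sel)
  popsum <- summarize_nonselected(pop, sel)
  truth <- true_nonselected_effect(pop, sel)

  y <- ifelse(arm == 1, pop$y1[sel], pop$y0[sel])
  trial <- trial_dataset(arm = arm, outcome = y,
                         covariates = cbind(z = pop$z[sel], w = pop$w[sel]),
                         ids = pop$id[sel])
  fit <- rct_ppmm_fit(trial, popsum)

  mle <- rbind(
    treatment = vapply(mle_phis, function(p)
      treatment_effect(fit$treat, fit$ctrl, phi1 = p, phi0 = 0)$effect, 0),
    control = vapply(mle_phis, function(p)
      treatment_effect(fit$treat, fit$ctrl, phi1 = 0, phi0 = p)$effect, 0))
  colnames(mle) <- paste0("phi", mle_phis)
  ends <- mle[, c(1, ncol(mle))]
  mle_cover <- apply(ends, 1, function(e) truth >= min(e) && truth <= max(e))

  out <- list(truth = truth,
              trial_est = mean(y[arm == 1]) - mean(y[arm == 0]),
              rho1 = fit$treat$rho, rho0 = fit$ctrl$rho,
              beta0 = beta0, mle = mle, mle_cover = mle_cover)

  if (bayes) {
    ci <- list(); cover <- list()
    for (pr in names(priors)) {
      for (side in c("treatment", "control")) {
        dr <- if (side == "treatment")
          ppmm_bayes(fit, phi1 = priors[[pr]], phi0 = 0, n_draws = n_draws)
        else
          ppmm_bayes(fit, phi1 = 0, phi0 = priors[[pr]], n_draws = n_draws)
        iv <- credible_interval(dr, level)
        key <- paste(side, pr, sep = ".")
        ci[[key]] <- iv
        cover[[key]] <- truth >= iv[1] && truth <= iv[2]
      }
    }
    out$bayes_ci <- ci
    out$bayes_cover <- unlist(cover)
  }
  out
}

#' Run a simulation scenario
#'
#' Repeats [run_replicate()] and aggregates coverage percentages (with
#' binomial Monte-Carlo standard errors) and mean estimates across
#' replicates.  One master seed spawns independent per-replicate seeds,
#' which are recorded in the per-replicate table for exact rerun of any
#' replicate.
#'
#' @param popcfg,selcfg configurations as in [run_replicate()].
#' @param n_reps number of replicates.
#' @param seed master seed.
#' @param ... passed to [run_replicate()] (e.g. `bayes`, `n_draws`,
#'   `priors`, `mle_phis`).
#' @return `"ppmm_scenario"`: list with `replicates` (one row per
#'   replicate: seed, truth, trial estimate, proxy strengths, MLEs and
#'   coverage indicators), `coverage` (percent, with `mc_se`), `means`
#'   (column means of the estimates), `n_reps`.
#' @export
run_scenario <- function(popcfg, selcfg, n_reps, seed = 1, ...) {
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, n_reps)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rr <- run_replicate(popcfg, selcfg, seed = rep_seeds[r], ...)
    row <- c(seed = rep_seeds[r], truth = rr$truth, trial_est = rr$trial_est,
             rho1 = rr$rho1, rho0 = rr$rho0)
    mle_flat <- as.vector(t(rr$mle))
    names(mle_flat) <- paste(rep(rownames(rr$mle), each = ncol(rr$mle)),
                             rep(colnames(rr$mle), 2), sep = ".")
    row <- c(row, mle_flat,
             cover.mle.treatment = as.numeric(rr$mle_cover["treatment"]),
             cover.mle.control = as.numeric(rr$mle_cover["control"]))
    if (!is.null(rr$bayes_cover)) {
      bc <- as.numeric(rr$bayes_cover)
      names(bc) <- paste0("cover.bayes.", names(rr$bayes_cover))
      row <- c(row, bc)
    }
    rows[[r]] <- row
  }
  reps <- as.data.frame(do.call(rbind, rows))
  cov_cols <- grep("^cover\\.", names(reps), value = TRUE)
  pct <- 100 * colMeans(reps[cov_cols])
  mc_se <- 100 * sqrt(colMeans(reps[cov_cols]) * (1 - colMeans(reps[cov_cols])) / n_reps)
  est_cols <- setdiff(names(reps), c(cov_cols, "seed"))
  structure(list(replicates = reps,
                 coverage = data.frame(interval = sub("^cover\\.", "", cov_cols),
                                       coverage = unname(pct), mc_se = unname(mc_se)),
                 means = colMeans(reps[est_cols]),
                 n_reps = n_reps, seed = seed,
                 popcfg = popcfg, selcfg = selcfg),
            class = "ppmm_scenario")
}

#' @export
print.ppmm_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario: %d replicates (master seed %d)\n", x$n_reps, x$seed))
  cat(sprintf("  truth (mean) %.4g; trial estimate (mean) %.4g\n",
              x$means["truth"], x$means["trial_est"]))
  cat("  interval coverage (%):\n")
  print(transform(x$coverage, coverage = round(coverage, 1), mc_se = round(mc_se, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Named simulation presets
#'
#' Encodes the study's factorial design as named presets
#' `"sel_<SEL>_em_<EM>_rho<R>_sigma<S>"`, where `<SEL>` is the selection
#' mechanism (`U`: \eqn{\beta_U = 1}; `ZU`: \eqn{\beta_Z = \beta_U = 1};
#' `ZWU`: all three 1; `ZnegU`: \eqn{\beta_Z = 1, \beta_U = -1}; `ZWnegU`:
#' \eqn{\beta_Z = \beta_W = 1, \beta_U = -1}), `<EM>` the effect
#' modification (`U`, `ZU`, or `ZWU` with the corresponding
#' \eqn{\gamma = 1}), `<R>` is `0` or `03` for \eqn{\rho_{UW}}, and `<S>`
#' is \eqn{\sigma^2 \in \{1, 4, 13\}}.  Example:
#' `"sel_U_em_U_rho0_sigma4"`.
#'
#' @param name preset name.
#' @return list with `popcfg` and `selcfg`.
#' @export
scenario_preset <- function(name) {
  m <- regmatches(name, regexec(
    "^sel_(U|ZU|ZWU|ZnegU|ZWnegU)_em_(U|ZU|ZWU)_rho(0|03)_sigma(1|4|13)$", name))[[1]]
  if (!length(m)) stop(sprintf("unknown preset '%s'", name), call. = FALSE)
  sel <- switch(m[2],
                U = c(0, 0, 1), ZU = c(1, 0, 1), ZWU = c(1, 1, 1),
                ZnegU = c(1, 0, -1), ZWnegU = c(1, 1, -1))
  em <- switch(m[3], U = c(0, 0, 1), ZU = c(1, 0, 1), ZWU = c(1, 1, 1))
  rho <- if (m[4] == "0") 0 else 0.3
  list(popcfg = population_config(N = 5000, gamma_z = em[1], gamma_w = em[2],
                                  gamma_u = em[3], sigma2 = as.numeric(m[5]),
                                  rho_uw = rho),
       selcfg = selection_config(beta_z = sel[1], beta_w = sel[2],
                                 beta_u = sel[3], n_sample = 200))
}
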