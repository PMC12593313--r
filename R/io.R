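#' Read trial microdata from CSV
#'
#' Expects a header row with columns `arm` (0/1) and `outcome` (numeric);
#' all remaining columns are treated as covariates unless `covariates`
#' names a subset.  An optional `id` column is carried through as unit
#' labels.  Validation problems (missing columns, non-numeric cells,
#' missing values, arm values outside 0/1) are reported with row/column
#' detail.
#'
#' @param path CSV file path.
#' @param covariates optional character vector of covariate column names.
#' @return a [trial_dataset()].
#' @export
read_trial_csv <- function(path, covariates = NULL) {
  if (!file.exists(path)) stop(sprintf("trial file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  for (col in c("arm", "outcome"))
    if (!col %in% names(df))
      stop(sprintf("trial CSV is missing required column '%s'", col), call. = FALSE)
  ids <- if ("id" %in% names(df)) df$id else NULL
  cov_cols <- covariates %||% setdiff(names(df), c("arm", "outcome", "id"))
  missing_cov <- setdiff(cov_cols, names(df))
  if (length(missing_cov))
    stop(sprintf("covariate column(s) not in file: %s", paste(missing_cov, collapse = ", ")),
         call. = FALSE)
  if (!length(cov_cols)) stop("trial CSV has no covariate columns", call. = FALSE)
  problems <- character(0)
  for (col in c("arm", "outcome", cov_cols)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v) & as.character(v) != "")
      if (length(bad))
        problems <- c(problems, sprintf("column '%s': non-numeric value(s) at row(s) %s",
                                        col, paste(utils::head(bad, 5), collapse = ", ")))
      v <- vn
      df[[col]] <- v
    }
    nas <- which(is.na(df[[col]]))
    if (length(nas))
      problems <- c(problems, sprintf("column '%s': missing value(s) at row(s) %s",
                                      col, paste(utils::head(nas, 5), collapse = ", ")))
  }
  bad_arm <- which(!df$arm %in% c(0, 1) & !is.na(df$arm))
  if (length(bad_arm))
    problems <- c(problems, sprintf("column 'arm': values outside {0,1} at row(s) %s",
                                    paste(utils::head(bad_arm, 5), collapse = ", ")))
  if (length(problems))
    stop(paste(c("invalid trial CSV:", problems), collapse = "\n  "), call. = FALSE)
  trial_dataset(arm = df$arm, outcome = df$outcome,
                covariates = as.matrix(df[cov_cols]), ids = ids)
}

#' Write trial microdata to CSV
#'
#' @param trial a [trial_dataset()].
#' @param path output path.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "trial_dataset"))
  df <- data.frame(arm = trial$arm, outcome = trial$outcome,
                   trial$covariates, check.names = FALSE)
  if (!is.null(trial$ids)) df <- cbind(id = trial$ids, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a target-population covariate summary
#'
#' Accepts JSON or YAML with keys `mean` (vector), `cov` (matrix as list
#' of rows) and optional `count`, chosen by file extension (`.json`,
#' `.yaml`/`.yml`).  Alternatively a pair of CSVs: `path` holding the
#' means (one named column per covariate, single row) and `cov_path`
#' holding the covariance matrix.
#'
#' @param path summary file path.
#' @param cov_path covariance CSV when using the two-CSV form.
#' @return a [population_summary()].
#' @export
read_population_summary <- function(path, cov_path = NULL) {
  if (!file.exists(path)) stop(sprintf("summary file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (!is.null(cov_path)) {
    mn <- utils::read.csv(path, check.names = FALSE)
    cv <- as.matrix(utils::read.csv(cov_path, check.names = FALSE))
    return(population_summary(mean = as.numeric(mn[1, ]), cov = cv))
  }
  obj <- switch(ext,
                json = jsonlite::fromJSON(path),
                yaml = , yml = yaml::read_yaml(path),
                stop(sprintf("unsupported summary format '.%s' (use .json, .yaml or CSV pair)", ext),
                     call. = FALSE))
  if (is.null(obj$mean) || is.null(obj$cov))
    stop("population summary needs 'mean' and 'cov' entries", call. = FALSE)
  cov <- obj$cov
  if (is.list(cov)) cov <- do.call(rbind, lapply(cov, as.numeric))
  population_summary(mean = as.numeric(obj$mean), cov = cov, count = obj$count)
}

#' Write a target-population covariate summary as JSON
#'
#' @param popsum a [population_summary()].
#' @param path output path (`.json`).
#' @export
write_population_summary <- function(popsum, path) {
  stopifnot(inherits(popsum, "population_summary"))
  obj <- list(mean = popsum$mean, cov = apply(popsum$cov, 1, as.numeric, simplify = FALSE))
  if (!is.null(popsum$count)) obj$count <- popsum$count
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a sensitivity curve as tidy CSV
#'
#' Columns: `phi`, `phi1`, `phi0`, `mu_treat`, `mu_ctrl`, `effect`, and
#' `lower`/`upper` when present.
#'
#' @param curve a `"sensitivity_curve"` or binned posterior curve.
#' @param path output path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Generate analysis-ready fixture files from a simulation preset
#'
#' Runs the generative model for a named preset ([scenario_preset()]) and
#' writes three files to `outdir`: `trial.csv` (participant microdata),
#' `popsum.json` (nonselected covariate summary), and `truth.json` (the
#' true nonselected treatment effect and the generating seed).  Output is
#' byte-deterministic given the seed.
#'
#' @param preset preset name, e.g. `"sel_U_em_U_rho0_sigma4"`.
#' @param seed integer seed.
#' @param outdir output directory (created if needed).
#' @return invisibly, named vector of the three file paths.
#' @export
make_fixtures <- function(preset, seed, outdir) {
  cfg <- scenario_preset(preset)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  set.seed(seed)
  pop <- generate_population(cfg$popcfg)
  eta <- cfg$selcfg$beta_z * pop$z + cfg$selcfg$beta_w * pop$w + cfg$selcfg$beta_u * pop$u
  beta0 <- calibrate_intercept(eta, cfg$selcfg$n_sample)
  sel <- brewer_sample(stats::plogis(beta0 + eta), cfg$selcfg$n_sample)
  arm <- assign_treatment(sel)
  y <- ifelse(arm == 1, pop$y1[sel], pop$y0[sel])
  trial <- trial_dataset(arm = arm, outcome = y,
                         covariates = cbind(z = pop$z[sel], w = pop$w[sel]),
                         ids = pop$id[sel])
  popsum <- summarize_nonselected(pop, sel)
  paths <- c(trial = file.path(outdir, "trial.csv"),
             popsum = file.path(outdir, "popsum.json"),
             truth = file.path(outdir, "truth.json"))
  write_trial_csv(trial, paths["trial"])
  write_population_summary(popsum, paths["popsum"])
  jsonlite::write_json(list(preset = preset, seed = seed,
                            true_nonselected_effect = true_nonselected_effect(pop, sel)),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
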