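# Monte-Carlo study harness: size/power of the Stage-I test and
# bias/RMSE/coverage of the Stage-II estimator against a naive complete-case
# least-squares comparator. All studies are deterministic given the master
# seed of each scenario: replication r of scenario s uses cohort seed
# `config$seed + r` and the selection substream derived from it.

rep_config <- function(config, r) {
  config$seed <- config$seed + r
  config
}

#' Size and power study for the Stage-I mechanism test
#'
#' For each scenario, replicates cohort generation + selection + the
#' Stage-I test and records the rejection fraction at level `alpha` with its
#' binomial standard error.
#'
#' @param scenarios named list of `simulation_config` objects.
#' @param alpha nominal level.
#' @param spec Stage-I `model_spec` (baseline covariates only).
#' @param summary,milestone_day cross-section choice passed to [mnar_test()].
#'   The default milestone summary keeps the Gaussian working model
#'   homoscedastic across subjects with unequal reporting counts.
#' @param max_failure_rate a scenario with more failed replications than
#'   this fraction is a study error.
#' @return A `study_report` data.frame: one row per scenario with
#'   `rejection_rate`, `binomial_se`, `replications`, `failures`, `seed`.
#' @export
run_size_power_study <- function(scenarios, alpha = 0.05,
                                 spec = model_spec(covariates = c("age", "sex"),
                                                   center = "age",
                                                   time_unit = 1),
                                 summary = "milestone_day",
                                 milestone_day = 0L,
                                 max_failure_rate = 0.05) {
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios))))
    names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  rows <- lapply(names(scenarios), function(nm) {
    config <- scenarios[[nm]]
    if (config$replications < 100)
      abort_pm("size/power studies need >= 100 replications", "config_error")
    p <- rep(NA_real_, config$replications)
    fails <- 0L
    for (r in seq_len(config$replications)) {
      res <- tryCatch(
        mnar_test(simulate_cohort(rep_config(config, r)), spec,
                  summary = summary, milestone_day = milestone_day),
        error = function(e) e)
      if (inherits(res, "error")) fails <- fails + 1L else p[r] <- res$p_value
    }
    if (fails > max_failure_rate * config$replications)
      abort_pm(sprintf("scenario '%s': %d of %d replications failed",
                       nm, fails, config$replications), "study_error")
    ok <- !is.na(p)
    rate <- mean(p[ok] < alpha)
    data.frame(scenario = nm, mechanism = config$mechanism$kind,
               n_subjects = config$n_subjects, alpha = alpha,
               rejection_rate = rate,
               binomial_se = sqrt(rate * (1 - rate) / sum(ok)),
               replications = sum(ok), failures = fails,
               seed = config$seed, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  class(report) <- c("study_report", class(report))
  report
}

# Naive comparator: complete-case ordinary least squares (with intercept)
# on the stacked observed rows.
naive_ols <- function(table) {
  X <- table$X
  if (!("(Intercept)" %in% colnames(X)))
    X <- cbind("(Intercept)" = 1, X)
  fit <- stats::lm.fit(X, table$y)
  cf <- fit$coefficients
  # subject-clustered (CR0) sandwich for honest naive intervals
  e <- fit$residuals
  bread <- solve(crossprod(X))
  Sg <- rowsum(X * e, table$subject)
  cov <- bread %*% crossprod(Sg) %*% bread
  list(coef = cf, se = sqrt(pmax(diag(cov), 0)))
}

#' Estimator study: pairwise composite likelihood versus naive least squares
#'
#' For each scenario, replicates cohort generation + selection, fits the
#' Stage-II pairwise estimator (tilt scale) and complete-case least squares
#' (mean scale, intercept included) on the identical observed rows, and
#' reports per-coefficient bias, empirical SD, RMSE and 95% Wald coverage
#' against the scenario truth. The pairwise truth is
#' `true_beta / (noise_sd^2 + random_effect_sd^2)`; the least-squares truth
#' is `true_beta` (slopes) and 0 (intercept).
#'
#' @param scenarios named list of `simulation_config` objects.
#' @param spec Stage-II `model_spec`; its intercept is used only by the
#'   naive comparator.
#' @param max_failure_rate as in [run_size_power_study()].
#' @return A `study_report` data.frame: one row per scenario x method x
#'   coefficient with `bias`, `mc_se` (Monte-Carlo SE of the bias),
#'   `empirical_sd`, `rmse`, `coverage_95`, `replications`.
#' @export
run_estimator_study <- function(scenarios, spec = NULL,
                                max_failure_rate = 0.05) {
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios))))
    names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  rows <- list()
  for (nm in names(scenarios)) {
    config <- scenarios[[nm]]
    if (config$replications < 100)
      abort_pm("estimator studies need >= 100 replications", "config_error")
    sp <- spec %||% config$spec
    m <- length(sp$covariates)
    tilt_truth <- config$true_beta /
      (config$noise_sd^2 + config$random_effect_sd^2)
    ols_truth <- c(0, config$true_beta)
    pw_est <- matrix(NA_real_, config$replications, m)
    pw_cov <- matrix(NA_real_, config$replications, m)
    ols_est <- matrix(NA_real_, config$replications, m + 1)
    ols_cov <- matrix(NA_real_, config$replications, m + 1)
    fails <- 0L
    for (r in seq_len(config$replications)) {
      res <- tryCatch({
        data <- simulate_cohort(rep_config(config, r))
        # subjects with no observed rows are expected under selection
        table <- suppressWarnings(build_analysis_table(data, sp))
        pw <- fit_pairwise(table)
        nv <- naive_ols(table)
        list(pw = pw, nv = nv)
      }, error = function(e) e)
      if (inherits(res, "error")) { fails <- fails + 1L; next }
      pw_est[r, ] <- res$pw$beta
      pw_cov[r, ] <- abs(res$pw$beta - tilt_truth) <= 1.96 * res$pw$se
      ols_est[r, ] <- res$nv$coef
      ols_cov[r, ] <- abs(res$nv$coef - ols_truth) <= 1.96 * res$nv$se
    }
    if (fails > max_failure_rate * config$replications)
      abort_pm(sprintf("scenario '%s': %d of %d replications failed",
                       nm, fails, config$replications), "study_error")
    summarise <- function(est, cov, truth, method, names_) {
      ok <- stats::complete.cases(est)
      bias <- colMeans(est[ok, , drop = FALSE]) - truth
      # population-form SD so rmse^2 = bias^2 + sd^2 holds exactly
      sd_ <- sqrt(colMeans(scale(est[ok, , drop = FALSE], scale = FALSE)^2))
      data.frame(scenario = nm, mechanism = config$mechanism$kind,
                 method = method, coefficient = names_,
                 truth = truth, bias = bias,
                 mc_se = sd_ / sqrt(sum(ok)),
                 empirical_sd = sd_,
                 rmse = sqrt(bias^2 + sd_^2),
                 coverage_95 = colMeans(cov[ok, , drop = FALSE]),
                 replications = sum(ok), failures = fails,
                 seed = config$seed,
                 stringsAsFactors = FALSE, row.names = NULL)
    }
    rows[[paste0(nm, "_pw")]] <- summarise(pw_est, pw_cov, tilt_truth,
                                           "pairwise", sp$covariates)
    rows[[paste0(nm, "_nv")]] <- summarise(ols_est, ols_cov, ols_truth,
                                           "complete_case_ols",
                                           c("(Intercept)", sp$covariates))
  }
  report <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(report) <- c("study_report", class(report))
  report
}

#' @export
print.study_report <- function(x, digits = 4, ...) {
  cat("Monte-Carlo study report\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
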