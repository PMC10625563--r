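# Population defaults for the synthetic cohort: a financial-incentive
# weight-loss maintenance trial with daily at-home weighing. Age 49.0 (10.5)
# years, 91.6% female, baseline BMI 36.7 (4.2) kg/m^2 truncated to the 30-45
# eligibility window, baseline weight 198.9 (32.9) lb, arms allocated roughly
# 1:2:2 (control : direct payment : lottery).
COHORT_DEFAULTS <- list(
  age_mean = 49.0, age_sd = 10.5,
  p_female = 0.916,
  bmi_mean = 36.7, bmi_sd = 4.2, bmi_range = c(30, 45),
  weight_mean = 198.9, weight_sd = 32.9,
  arm_prob = c(control = 1, direct_payment = 2, lottery = 2) / 5
)

# Selection covariates are measured as offsets from the population centre so
# the intercept of x_coefs sets the reporting rate of a typical subject.
selection_design <- function(subjects) {
  cbind(1,
        age = subjects$age - COHORT_DEFAULTS$age_mean,
        sex = subjects$sex,
        baseline_bmi = subjects$baseline_bmi - COHORT_DEFAULTS$bmi_mean)
}

#' Describe a missing-data mechanism
#'
#' The reporting (selection) probability of each scheduled subject-day is
#'   * `mcar`: a constant `p_const`;
#'   * `mar`: `plogis(x_coefs' xt_i)` where `xt_i = (1, age_i - 49, sex_i,
#'     bmi_i - 36.7)` holds the subject's baseline covariates;
#'   * `mnar_product`: the MAR factor multiplied by an outcome factor
#'     `plogis(gamma0 + gamma1 * y_ij)`, with `y_ij` the (possibly
#'     unreported) weight change on that day. The product form in (x, y) is
#'     exactly the separability assumption under which the pairwise
#'     composite likelihood of Stage II remains unbiased;
#'   * `mnar_interaction`: a deliberately non-separable mechanism
#'     `plogis(x_coefs' xt_i + gamma0 + gamma1 * y_ij + xy_coef * y_ij *
#'     (age_i - 49))`, provided only for robustness experiments.
#'
#' @param kind one of `"mcar"`, `"mar"`, `"mnar_product"`,
#'   `"mnar_interaction"`.
#' @param p_const reporting probability under MCAR.
#' @param x_coefs numeric length 4: coefficients on `(1, age - 49, sex,
#'   bmi - 36.7)`.
#' @param y_coefs numeric length 2 `(gamma0, gamma1)` for the outcome factor.
#' @param xy_coef scalar interaction coefficient (`mnar_interaction` only).
#' @return An object of class `missingness_mechanism`.
#' @export
missingness_mechanism <- function(kind = c("mcar", "mar", "mnar_product",
                                           "mnar_interaction"),
                                  p_const = NULL, x_coefs = NULL,
                                  y_coefs = NULL, xy_coef = 0) {
  kind <- match.arg(kind)
  if (kind == "mcar") {
    if (is.null(p_const) || !is.finite(p_const) || p_const <= 0 || p_const > 1)
      abort_pm("mcar requires p_const in (0, 1]", "config_error")
  } else {
    if (is.null(x_coefs) || length(x_coefs) != 4 || any(!is.finite(x_coefs)))
      abort_pm(paste0(kind, " requires x_coefs of length 4 over ",
                      "(intercept, age, sex, baseline_bmi)"), "config_error")
  }
  if (kind %in% c("mnar_product", "mnar_interaction")) {
    if (is.null(y_coefs) || length(y_coefs) != 2 || any(!is.finite(y_coefs)))
      abort_pm(paste0(kind, " requires y_coefs = (gamma0, gamma1)"),
               "config_error")
  }
  structure(list(kind = kind, p_const = p_const, x_coefs = x_coefs,
                 y_coefs = y_coefs, xy_coef = xy_coef),
            class = "missingness_mechanism")
}

#' @export
print.missingness_mechanism <- function(x, ...) {
  cat("Missingness mechanism:", toupper(x$kind), "\n")
  if (x$kind == "mcar") cat("  reporting probability:", x$p_const, "\n")
  if (!is.null(x$x_coefs))
    cat("  x_coefs (1, age, sex, bmi):", paste(x$x_coefs, collapse = ", "), "\n")
  if (!is.null(x$y_coefs))
    cat("  y_coefs (gamma0, gamma1):", paste(x$y_coefs, collapse = ", "), "\n")
  invisible(x)
}

#' Simulation scenario configuration
#'
#' @param n_subjects number of subjects (>= 2).
#' @param schedule_length scheduled days per subject (>= 1).
#' @param true_beta named or ordered coefficient vector on the mean scale of
#'   the outcome model, one entry per covariate of `spec` (no intercept; the
#'   generated outcome has mean `x' true_beta`). With `noise_sd = 1` and no
#'   random intercept these equal the density-ratio (tilt) scale
#'   coefficients targeted by the pairwise estimator; in general the tilt
#'   estimand is `true_beta / (noise_sd^2 + random_effect_sd^2)`.
#' @param noise_sd residual day-to-day standard deviation (lb), > 0.
#' @param random_effect_sd subject random-intercept standard deviation (lb).
#'   Defaults to 0: the pairwise estimator only uses cross-subject pairs, so
#'   a random intercept is a robustness knob rather than a requirement.
#' @param mechanism a `missingness_mechanism`.
#' @param seed master seed; cohort generation and selection use documented
#'   substreams derived from it.
#' @param replications replication count for study harnesses.
#' @param spec `model_spec` defining the covariates of the outcome model.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects, schedule_length, true_beta,
                              noise_sd = 1, random_effect_sd = 0,
                              mechanism = missingness_mechanism("mcar", p_const = 1),
                              seed = 1L, replications = 1L,
                              spec = model_spec()) {
  if (n_subjects < 2) abort_pm("n_subjects must be >= 2", "config_error")
  if (schedule_length < 1) abort_pm("schedule_length must be >= 1", "config_error")
  if (!is.finite(noise_sd) || noise_sd <= 0)
    abort_pm("noise_sd must be > 0", "config_error")
  if (random_effect_sd < 0)
    abort_pm("random_effect_sd must be >= 0", "config_error")
  if (replications < 1) abort_pm("replications must be >= 1", "config_error")
  if (length(true_beta) != length(spec$covariates))
    abort_pm("true_beta length must match the covariates of spec", "config_error")
  names(true_beta) <- spec$covariates
  structure(
    list(n_subjects = as.integer(n_subjects),
         schedule_length = as.integer(schedule_length),
         true_beta = true_beta, noise_sd = noise_sd,
         random_effect_sd = random_effect_sd, mechanism = mechanism,
         seed = as.integer(seed), replications = as.integer(replications),
         spec = spec),
    class = "simulation_config"
  )
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  # inverse-CDF draw; bounds are population eligibility limits, not data-driven
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a fully observed synthetic cohort
#'
#' Draws baseline characteristics from the population defaults above, assigns
#' arms 1:2:2, and generates daily weight-change outcomes
#' `y_ij = x_ij' true_beta + b_i + eps_ij` with `b_i ~ N(0, random_effect_sd^2)`
#' and `eps_ij ~ N(0, noise_sd^2)`. The stored daily weight is
#' `baseline_weight + y_ij` and every scheduled day is observed. Centered
#' covariates use the fixed population centres (age 49, BMI 36.7), so
#' generation is a pure function of the seed and does not depend on the
#' realised sample.
#'
#' @param config a `simulation_config`.
#' @return A fully observed `longitudinal_dataset`.
#' @export
simulate_complete_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  d <- COHORT_DEFAULTS
  n <- config$n_subjects
  set.seed(config$seed)
  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    arm = sample(names(d$arm_prob), n, replace = TRUE, prob = d$arm_prob),
    age = pmax(stats::rnorm(n, d$age_mean, d$age_sd), 18),
    sex = stats::rbinom(n, 1, d$p_female),
    baseline_bmi = rtruncnorm1(n, d$bmi_mean, d$bmi_sd,
                               d$bmi_range[1], d$bmi_range[2]),
    baseline_weight = pmax(stats::rnorm(n, d$weight_mean, d$weight_sd), 90),
    stringsAsFactors = FALSE
  )
  subjects$arm <- factor(subjects$arm, levels = ARM_LEVELS)

  days <- rep(seq_len(config$schedule_length) - 1L, times = n)
  sid <- rep(subjects$subject_id, each = config$schedule_length)
  idx <- rep(seq_len(n), each = config$schedule_length)
  spec <- config$spec
  time <- days * spec$time_unit
  arm <- subjects$arm[idx]
  col <- function(v) {
    switch(v,
      "time" = time,
      "direct_payment:time" = as.numeric(arm == "direct_payment") * time,
      "lottery:time" = as.numeric(arm == "lottery") * time,
      "age" = {
        x <- subjects$age[idx]
        if (v %in% spec$center) x - d$age_mean else x
      },
      "baseline_bmi" = {
        x <- subjects$baseline_bmi[idx]
        if (v %in% spec$center) x - d$bmi_mean else x
      },
      "baseline_weight" = {
        x <- subjects$baseline_weight[idx]
        if (v %in% spec$center) x - d$weight_mean else x
      },
      as.numeric(subjects[[v]][idx]))
  }
  X <- vapply(spec$covariates, col, numeric(length(days)))
  X <- matrix(X, nrow = length(days), dimnames = list(NULL, spec$covariates))
  b <- stats::rnorm(n, 0, config$random_effect_sd)
  y <- drop(X %*% config$true_beta) + b[idx] +
    stats::rnorm(length(days), 0, config$noise_sd)
  series <- data.frame(
    subject_id = sid, day = days, observed = TRUE,
    weight = subjects$baseline_weight[idx] + y,
    stringsAsFactors = FALSE
  )
  longitudinal_dataset(subjects, series, config$schedule_length)
}

#' Impose a missing-data mechanism on a fully observed cohort
#'
#' Each scheduled row keeps its weight with the selection probability of the
#' mechanism, independently across rows; unselected rows become
#' `observed = FALSE` with the weight removed. The outcome entering MNAR
#' selection is the weight change from baseline of that row.
#'
#' @param data a fully observed `longitudinal_dataset`.
#' @param mech a `missingness_mechanism`.
#' @param seed integer seed for the selection draw.
#' @return A `longitudinal_dataset` with the same schedule and thinned
#'   observations.
#' @export
apply_missingness <- function(data, mech, seed) {
  stopifnot(inherits(data, "longitudinal_dataset"),
            inherits(mech, "missingness_mechanism"))
  if (!all(data$series$observed))
    abort_pm("apply_missingness expects a fully observed dataset", "value_error")
  idx <- match(data$series$subject_id, data$subjects$subject_id)
  y <- data$series$weight - data$subjects$baseline_weight[idx]
  xt <- selection_design(data$subjects)[idx, , drop = FALSE]
  pi <- switch(mech$kind,
    mcar = rep(mech$p_const, nrow(data$series)),
    mar = stats::plogis(drop(xt %*% mech$x_coefs)),
    mnar_product = stats::plogis(drop(xt %*% mech$x_coefs)) *
      stats::plogis(mech$y_coefs[1] + mech$y_coefs[2] * y),
    mnar_interaction = stats::plogis(
      drop(xt %*% mech$x_coefs) + mech$y_coefs[1] + mech$y_coefs[2] * y +
        mech$xy_coef * y * (data$subjects$age[idx] - COHORT_DEFAULTS$age_mean))
  )
  set.seed(seed)
  keep <- stats::runif(nrow(data$series)) < pi
  series <- data$series
  series$observed <- keep
  series$weight[!keep] <- NA_real_
  longitudinal_dataset(data$subjects, series, data$schedule_length)
}

#' Simulate a cohort and apply its missingness mechanism
#'
#' Convenience wrapper: generates the complete cohort from `config$seed` and
#' applies `config$mechanism` using the derived selection substream seed
#' `config$seed + 1000003`.
#'
#' @param config a `simulation_config`.
#' @return A `longitudinal_dataset` after selection.
#' @export
simulate_cohort <- function(config) {
  complete <- simulate_complete_cohort(config)
  apply_missingness(complete, config$mechanism, seed = config$seed + 1000003L)
}
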