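#' Arm labels recognised by the package
#'
#' Three-arm design with `control` as the reference arm.
#' @keywords internal
ARM_LEVELS <- c("control", "direct_payment", "lottery")

# Covariates that live at the subject (baseline) level.
BASELINE_COVARIATES <- c("sex", "age", "baseline_bmi", "baseline_weight")

# Full covariate vocabulary of the design builder.
ALL_COVARIATES <- c(BASELINE_COVARIATES, "time",
                    "direct_payment:time", "lottery:time")

#' Construct a longitudinal dataset
#'
#' Bundles a subject-level table of baseline characteristics with a
#' long-format series of scheduled daily observations. This container is the
#' single source of truth for both analysis stages: Stage I draws a
#' cross-sectional sample from it and Stage II stacks its observed rows.
#'
#' @param subjects data.frame with columns `subject_id`, `arm` (one of
#'   `control`, `direct_payment`, `lottery`), `age` (years), `sex`
#'   (1 = female), `baseline_bmi` (kg/m^2), `baseline_weight` (lb).
#' @param series data.frame with columns `subject_id`, `day` (integer >= 0,
#'   days since enrollment), `observed` (logical), `weight` (lb, `NA` exactly
#'   when not observed).
#' @param schedule_length number of scheduled days; valid days are
#'   `0, ..., schedule_length - 1`.
#' @return An object of class `longitudinal_dataset`.
#' @export
longitudinal_dataset <- function(subjects, series, schedule_length) {
  subjects <- as.data.frame(subjects)
  series <- as.data.frame(series)
  need_subj <- c("subject_id", "arm", "age", "sex", "baseline_bmi", "baseline_weight")
  need_ser <- c("subject_id", "day", "observed", "weight")
  miss <- setdiff(need_subj, names(subjects))
  if (length(miss))
    abort_pm(paste0("subject table is missing column(s): ",
                    paste(miss, collapse = ", ")), "schema_error")
  miss <- setdiff(need_ser, names(series))
  if (length(miss))
    abort_pm(paste0("series table is missing column(s): ",
                    paste(miss, collapse = ", ")), "schema_error")

  subjects$subject_id <- as.character(subjects$subject_id)
  series$subject_id <- as.character(series$subject_id)
  if (anyDuplicated(subjects$subject_id))
    abort_pm("duplicated subject_id in subject table", "integrity_error")
  bad_arm <- setdiff(unique(as.character(subjects$arm)), ARM_LEVELS)
  if (length(bad_arm))
    abort_pm(paste0("unknown arm label(s): ", paste(bad_arm, collapse = ", "),
                    " (expected ", paste(ARM_LEVELS, collapse = "/"), ")"),
             "value_error")
  subjects$arm <- factor(as.character(subjects$arm), levels = ARM_LEVELS)
  for (v in c("age", "baseline_bmi", "baseline_weight")) {
    if (any(!is.finite(subjects[[v]]) | subjects[[v]] <= 0))
      abort_pm(paste0("subject column '", v, "' must be finite and > 0"),
               "value_error")
  }
  if (any(!subjects$sex %in% c(0, 1)))
    abort_pm("sex must be coded 0/1 (1 = female)", "value_error")

  if (anyDuplicated(series[c("subject_id", "day")]))
    abort_pm("duplicated (subject_id, day) in series", "integrity_error")
  unknown <- setdiff(unique(series$subject_id), subjects$subject_id)
  if (length(unknown))
    abort_pm(paste0("series references unknown subject(s): ",
                    paste(utils::head(unknown, 5), collapse = ", ")),
             "integrity_error")
  schedule_length <- as.integer(schedule_length)
  if (is.na(schedule_length) || schedule_length < 1)
    abort_pm("schedule_length must be a positive integer", "value_error")
  if (any(series$day < 0 | series$day >= schedule_length))
    abort_pm("day outside the schedule range [0, schedule_length)", "value_error")
  series$observed <- as.logical(series$observed)
  if (any(series$observed & !is.finite(series$weight)))
    abort_pm("observed rows must carry a finite weight", "integrity_error")
  if (any(!series$observed & !is.na(series$weight)))
    abort_pm("unobserved rows must have missing weight", "integrity_error")

  structure(
    list(subjects = subjects, series = series, schedule_length = schedule_length),
    class = "longitudinal_dataset"
  )
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  n <- nrow(x$subjects)
  obs <- sum(x$series$observed)
  cat("Longitudinal dataset:", n, "subjects,", nrow(x$series),
      "scheduled subject-days,", obs,
      sprintf("observed (%.1f%%)\n", 100 * obs / max(1, nrow(x$series))))
  cat("Arms:", paste(sprintf("%s=%d", levels(x$subjects$arm),
                             tabulate(x$subjects$arm, 3)), collapse = ", "),
      "| schedule length:", x$schedule_length, "days\n")
  invisible(x)
}

#' Per-subject observed counts
#'
#' @param data a `longitudinal_dataset`.
#' @return Named integer vector `K_i` over all subjects (zeros included).
#' @export
observed_counts <- function(data) {
  k <- integer(nrow(data$subjects))
  names(k) <- data$subjects$subject_id
  tab <- table(data$series$subject_id[data$series$observed])
  k[names(tab)] <- as.integer(tab)
  k
}

#' Model specification for design-matrix assembly
#'
#' Names the covariates entering the linear predictor, which of them are
#' mean-centered, and the unit in which calendar day enters as the `time`
#' covariate. Arm-by-time interaction columns use the control arm as the
#' reference, so control rows carry zeros in both interaction columns.
#'
#' @param covariates ordered character vector drawn from `sex`, `age`,
#'   `baseline_bmi`, `baseline_weight`, `time`, `direct_payment:time`,
#'   `lottery:time`.
#' @param center subset of the baseline covariates to mean-center (one value
#'   per subject, computed over subjects contributing at least one observed
#'   row, so centering does not depend on per-subject reporting frequency).
#' @param intercept include an intercept column in the assembled design.
#' @param time_unit scale factor applied to the day index before use as the
#'   `time` covariate. The default `1/30` expresses time in months.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(covariates = c("sex", "baseline_bmi", "age", "time",
                                      "lottery:time", "direct_payment:time"),
                       center = c("age", "baseline_bmi"),
                       intercept = TRUE,
                       time_unit = 1 / 30) {
  covariates <- as.character(covariates)
  if (!length(covariates))
    abort_pm("covariates must be non-empty", "value_error")
  if (anyDuplicated(covariates))
    abort_pm("duplicated covariate names", "value_error")
  bad <- setdiff(covariates, ALL_COVARIATES)
  if (length(bad))
    abort_pm(paste0("unknown covariate(s): ", paste(bad, collapse = ", ")),
             "value_error")
  center <- as.character(center)
  bad <- setdiff(center, intersect(covariates, BASELINE_COVARIATES))
  if (length(bad))
    abort_pm(paste0("center list must be baseline covariates in the model: ",
                    paste(bad, collapse = ", ")), "value_error")
  if (!is.finite(time_unit) || time_unit <= 0)
    abort_pm("time_unit must be positive", "value_error")
  structure(
    list(covariates = covariates, center = center,
         intercept = isTRUE(intercept), time_unit = time_unit),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec: ", if (x$intercept) "1 + " else "",
      paste(x$covariates, collapse = " + "), "\n", sep = "")
  if (length(x$center))
    cat("  centered:", paste(x$center, collapse = ", "), "\n")
  cat("  time unit:", format(x$time_unit), "(day multiplier)\n")
  invisible(x)
}

#' Read a long-format longitudinal CSV
#'
#' One row per subject-day with the baseline columns repeated on every row.
#' An empty weight cell encodes a day on which no weight was reported.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping the canonical column
#'   names (`subject_id`, `arm`, `age`, `sex`, `baseline_bmi`,
#'   `baseline_weight`, `day`, `weight`) to the names used in the file.
#' @param schedule_length optional; defaults to `max(day) + 1`.
#' @return A `longitudinal_dataset`.
#' @export
read_long_csv <- function(path, schema = NULL, schedule_length = NULL) {
  if (!file.exists(path))
    abort_pm(paste0("file not found: ", path), "value_error")
  canonical <- c("subject_id", "arm", "age", "sex", "baseline_bmi",
                 "baseline_weight", "day", "weight")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(schema)) map[names(schema)] <- schema
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- canonical[!map[canonical] %in% names(df)]
  if (length(miss))
    abort_pm(paste0("required column(s) absent from ", path, ": ",
                    paste(map[miss], collapse = ", ")), "schema_error")
  get <- function(v) df[[map[[v]]]]
  weight <- suppressWarnings(as.numeric(get("weight")))
  series <- data.frame(
    subject_id = as.character(get("subject_id")),
    day = as.integer(get("day")),
    observed = !is.na(weight),
    weight = weight,
    stringsAsFactors = FALSE
  )
  subj <- data.frame(
    subject_id = as.character(get("subject_id")),
    arm = as.character(get("arm")),
    age = as.numeric(get("age")),
    sex = as.numeric(get("sex")),
    baseline_bmi = as.numeric(get("baseline_bmi")),
    baseline_weight = as.numeric(get("baseline_weight")),
    stringsAsFactors = FALSE
  )
  subj <- subj[!duplicated(subj$subject_id), , drop = FALSE]
  rownames(subj) <- NULL
  longitudinal_dataset(subj, series,
                       schedule_length %||% (max(series$day) + 1L))
}

#' Write a longitudinal dataset as long-format CSV
#'
#' Inverse of [read_long_csv()]: numeric fields are written at full precision
#' so a read/write round trip reproduces the dataset exactly.
#'
#' @param data a `longitudinal_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path) {
  idx <- match(data$series$subject_id, data$subjects$subject_id)
  out <- data.frame(
    subject_id = data$series$subject_id,
    arm = as.character(data$subjects$arm[idx]),
    age = data$subjects$age[idx],
    sex = data$subjects$sex[idx],
    baseline_bmi = data$subjects$baseline_bmi[idx],
    baseline_weight = data$subjects$baseline_weight[idx],
    day = data$series$day,
    weight = data$series$weight,
    stringsAsFactors = FALSE
  )
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Subject-level covariate matrix in the order requested (baseline covariates
# only), one row per subject of `data`.
baseline_covariate_matrix <- function(data, covariates) {
  bad <- setdiff(covariates, BASELINE_COVARIATES)
  if (length(bad))
    abort_pm(paste0("not baseline covariate(s): ", paste(bad, collapse = ", ")),
             "value_error")
  m <- sapply(covariates, function(v) as.numeric(data$subjects[[v]]))
  m <- matrix(m, nrow = nrow(data$subjects),
              dimnames = list(data$subjects$subject_id, covariates))
  m
}

#' Build the stacked analysis table
#'
#' Stacks the observed subject-days into rows `(y_ij, x_ij)` where the
#' outcome is the reported daily weight minus that subject's baseline weight
#' (lb change from baseline) and the covariate vector follows the model
#' specification. Baseline covariates listed in `spec$center` are centered on
#' their subject-level mean over subjects contributing at least one observed
#' row, so a subject's influence on the centering constant does not grow with
#' their reporting frequency.
#'
#' @param data a `longitudinal_dataset`.
#' @param spec a `model_spec`.
#' @return An object of class `analysis_table` with elements `y` (outcome
#'   vector), `X` (design matrix, intercept column first when requested),
#'   `subject` (integer subject index per row), `subject_id`, `day`, `K`
#'   (observed counts of contributing subjects), `centers` (the centering
#'   constants used) and `spec`.
#' @export
build_analysis_table <- function(data, spec = model_spec()) {
  stopifnot(inherits(data, "longitudinal_dataset"), inherits(spec, "model_spec"))
  ser <- data$series[data$series$observed, , drop = FALSE]
  if (!nrow(ser))
    abort_pm("no observed rows in the dataset", "empty_data_error")
  idx <- match(ser$subject_id, data$subjects$subject_id)
  base_cov <- intersect(spec$covariates, BASELINE_COVARIATES)
  for (v in c(base_cov, "baseline_weight")) {
    if (any(!is.finite(data$subjects[[v]][unique(idx)])))
      abort_pm(paste0("subject with observed rows has missing baseline ",
                      "covariate '", v, "'"), "value_error")
  }
  k_all <- observed_counts(data)
  if (any(k_all == 0))
    warning(sum(k_all == 0),
            " subject(s) contribute no observed rows and are retained but",
            " excluded from the analysis table", call. = FALSE)

  contributing <- data$subjects$subject_id[k_all[data$subjects$subject_id] > 0]
  centers <- stats::setNames(numeric(length(spec$center)), spec$center)
  for (v in spec$center) {
    centers[v] <- mean(data$subjects[[v]][data$subjects$subject_id %in% contributing])
  }

  y <- ser$weight - data$subjects$baseline_weight[idx]
  time <- ser$day * spec$time_unit
  arm <- data$subjects$arm[idx]
  col <- function(v) {
    switch(v,
      "time" = time,
      "direct_payment:time" = as.numeric(arm == "direct_payment") * time,
      "lottery:time" = as.numeric(arm == "lottery") * time,
      {
        x <- as.numeric(data$subjects[[v]][idx])
        if (v %in% spec$center) x - centers[v] else x
      })
  }
  X <- vapply(spec$covariates, col, numeric(nrow(ser)))
  X <- matrix(X, nrow = nrow(ser),
              dimnames = list(NULL, spec$covariates))
  if (spec$intercept)
    X <- cbind("(Intercept)" = 1, X)

  sub_f <- factor(ser$subject_id, levels = unique(ser$subject_id))
  structure(
    list(y = as.numeric(y), X = X,
         subject = as.integer(sub_f),
         subject_id = ser$subject_id,
         day = as.integer(ser$day),
         K = stats::setNames(as.integer(table(sub_f)), levels(sub_f)),
         centers = centers, spec = spec),
    class = "analysis_table"
  )
}

#' @export
print.analysis_table <- function(x, ...) {
  cat("Analysis table:", length(x$y), "observed rows from",
      length(x$K), "subjects; design columns:",
      paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}
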