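# In-code fixtures shared across test files.

# A tiny deterministic cohort: `k` scheduled days per subject, arms cycled,
# all days observed with weights baseline + drift + small per-day offsets.
toy_dataset <- function(n = 3, k = 3, arms = c("control", "direct_payment", "lottery")) {
  subjects <- data.frame(
    subject_id = sprintf("P%02d", seq_len(n)),
    arm = rep(arms, length.out = n),
    age = seq(40, 60, length.out = n),
    sex = rep(c(1, 0), length.out = n),
    baseline_bmi = seq(32, 40, length.out = n),
    baseline_weight = seq(180, 220, length.out = n),
    stringsAsFactors = FALSE
  )
  series <- expand.grid(subject_id = subjects$subject_id,
                        day = seq_len(k) - 1L, stringsAsFactors = FALSE)
  series <- series[order(series$subject_id, series$day), ]
  idx <- match(series$subject_id, subjects$subject_id)
  series$observed <- TRUE
  series$weight <- subjects$baseline_weight[idx] - 2 - 0.5 * series$day +
    0.3 * idx
  rownames(series) <- NULL
  longitudinal_dataset(subjects, series, k)
}

# Analysis table built directly from raw pieces, for estimator unit tests
# that do not need the CSV/covariate machinery.
raw_table <- function(y, X, subject) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sub_f <- factor(subject, levels = unique(subject))
  structure(
    list(y = as.numeric(y), X = X, subject = as.integer(sub_f),
         subject_id = as.character(subject), day = seq_along(y) - 1L,
         K = stats::setNames(as.integer(table(sub_f)), levels(sub_f)),
         centers = numeric(0), spec = NULL),
    class = "analysis_table"
  )
}

# Cross-sectional Stage-I sample built directly.
raw_stage1_sample <- function(y, x, r = rep(1, length(y))) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  structure(list(y = as.numeric(y), x = x, r = as.numeric(r),
                 subject_id = as.character(seq_along(y))),
            class = "stage1_sample")
}

# Quadruple-loop oracle for the composite pairwise log likelihood: loops
# over subject pairs and their observations, evaluating the pair kernel
# directly. Independent of the blocked implementation.
loop_composite_loglik <- function(table, beta) {
  X <- table$X
  drop_col <- which(colnames(X) == "(Intercept)")
  if (length(drop_col)) X <- X[, -drop_col, drop = FALSE]
  subs <- unique(table$subject)
  ll <- 0; npairs <- 0
  for (a in seq_along(subs)) for (b in seq_along(subs)) {
    if (a >= b) next
    ra <- which(table$subject == subs[a])
    rb <- which(table$subject == subs[b])
    for (i in ra) for (j in rb) {
      u <- sum(beta * (X[i, ] - X[j, ])) * (table$y[i] - table$y[j])
      ll <- ll + (-log(1 + exp(-u)))
      npairs <- npairs + 1
    }
  }
  list(loglik = ll, n_pairs = npairs)
}

# Central finite differences of a scalar function.
fd_gradient <- function(f, beta, h = 1e-6) {
  vapply(seq_along(beta), function(k) {
    e <- numeric(length(beta)); e[k] <- h
    (f(beta + e) - f(beta - e)) / (2 * h)
  }, numeric(1))
}
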