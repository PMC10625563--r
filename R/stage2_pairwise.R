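# Stage II: pairwise composite conditional likelihood for marginal covariate
# effects under an outcome-dependent observation process.
#
# The working model for a single observation is the density-ratio (tilt)
# family f(y | x; beta) = exp(beta' x y) g(y) / C(x), with g the unspecified
# baseline law of the response, which also absorbs any outcome-only
# reporting factor. Conditioning a cross-subject pair of observations on its
# order statistics cancels both g and the normalising constants, leaving the
# conditional probability
#
#   P(observed assignment | order stats, x1, x2)
#     = 1 / (1 + exp(-(beta'(x1 - x2)) (y1 - y2)))
#
# so the composite log likelihood is a sum of logistic terms in the scalar
# u = (beta' dx) dy. The objective is globally concave in beta.

# Stable log(plogis(u)) = -log(1 + exp(-u)).
log_plogis <- function(u) {
  out <- numeric(length(u))
  pos <- u >= 0
  out[pos] <- -log1p(exp(-u[pos]))
  out[!pos] <- u[!pos] - log1p(exp(u[!pos]))
  out
}

#' Log conditional probability of one observation pair
#'
#' For two observations from distinct subjects, the probability of the
#' realised (y, x) assignment given the pair's order statistics and both
#' covariate vectors. The unspecified baseline density of the response (and
#' with it the observation-time process) cancels; only
#' `u = (beta'(x1 - x2)) * (y1 - y2)` remains, giving `-log(1 + exp(-u))`.
#' Ties (`y1 == y2`) contribute `log(1/2)`.
#'
#' @param y1,y2 outcomes of the two observations.
#' @param x1,x2 covariate vectors (no intercept needed; constants cancel in
#'   the difference).
#' @param beta tilt-scale coefficient vector.
#' @return Scalar log probability in `(-Inf, 0]`.
#' @export
pair_log_probability <- function(y1, y2, x1, x2, beta) {
  if (length(x1) != length(beta) || length(x2) != length(beta))
    abort_pm("beta and covariate vectors must have equal length", "value_error")
  if (!all(is.finite(c(y1, y2, x1, x2, beta))))
    abort_pm("non-finite inputs to pair_log_probability", "value_error")
  u <- sum(beta * (x1 - x2)) * (y1 - y2)
  log_plogis(u)
}

#' Enumerate cross-subject observation pairs
#'
#' All pairs of observed rows from distinct subjects, each unordered pair
#' once; within-subject pairs are excluded. The count equals
#' `sum over subject pairs i < i' of K_i * K_i'`.
#'
#' @param table an `analysis_table`.
#' @param subject_pairs optional 2-column matrix of subject-index pairs to
#'   restrict to (used by pair subsampling).
#' @return List with integer row indices `i1`, `i2` and `n_pairs`.
#' @export
enumerate_pairs <- function(table, subject_pairs = NULL) {
  stopifnot(inherits(table, "analysis_table"))
  ns <- length(table$K)
  if (ns < 2)
    abort_pm("pairwise likelihood needs at least 2 subjects with observations",
             "insufficient_data_error")
  rows_of <- split(seq_along(table$y), table$subject)
  if (is.null(subject_pairs)) {
    subject_pairs <- t(utils::combn(ns, 2L))
  }
  k <- lengths(rows_of)
  sizes <- k[subject_pairs[, 1]] * k[subject_pairs[, 2]]
  i1 <- integer(sum(sizes)); i2 <- integer(sum(sizes))
  at <- 0L
  for (p in seq_len(nrow(subject_pairs))) {
    a <- rows_of[[subject_pairs[p, 1]]]
    b <- rows_of[[subject_pairs[p, 2]]]
    nn <- length(a) * length(b)
    i1[at + seq_len(nn)] <- rep(a, times = length(b))
    i2[at + seq_len(nn)] <- rep(b, each = length(a))
    at <- at + nn
  }
  list(i1 = i1, i2 = i2, n_pairs = length(i1))
}

# Design used by Stage II: the analysis-table design without any intercept
# column (constants cancel in pair differences).
stage2_design <- function(table) {
  X <- table$X
  drop <- which(colnames(X) == "(Intercept)")
  if (length(drop)) X <- X[, -drop, drop = FALSE]
  if (!ncol(X))
    abort_pm("no non-constant covariates: intercept-only designs are not identified by pair differences",
             "unidentified_error")
  X
}

#' Composite pairwise log likelihood with analytic derivatives
#'
#' Evaluates `log L(beta) = sum over cross-subject pairs of the pair log
#' probability`, together with its exact gradient and Hessian. Pairs are
#' processed in blocks; results are independent of the block size.
#'
#' @param table an `analysis_table`.
#' @param beta coefficient vector matching the non-intercept design columns.
#' @param pairs optional precomputed result of [enumerate_pairs()].
#' @param block_size pairs per block.
#' @return List `loglik`, `gradient`, `hessian`, `n_pairs`.
#' @export
composite_loglik <- function(table, beta, pairs = NULL, block_size = 200000L) {
  X <- stage2_design(table)
  if (length(beta) != ncol(X))
    abort_pm(sprintf("beta has length %d but the design has %d non-intercept columns",
                     length(beta), ncol(X)), "value_error")
  pairs <- pairs %||% enumerate_pairs(table)
  out <- pm_pair_eval(X, table$y, pairs, beta, block_size)
  dimnames(out$hessian) <- list(colnames(X), colnames(X))
  names(out$gradient) <- colnames(X)
  out
}

# Precompute pair differences when they fit comfortably in memory; the
# evaluation itself is identical either way.
pm_pair_cache <- function(X, y, pairs, max_cells = 4e7) {
  if (as.double(pairs$n_pairs) * ncol(X) > max_cells) return(NULL)
  list(dx = X[pairs$i1, , drop = FALSE] - X[pairs$i2, , drop = FALSE],
       dy = y[pairs$i1] - y[pairs$i2])
}

pm_pair_eval <- function(X, y, pairs, beta, block_size = 200000L,
                         cache = NULL) {
  m <- ncol(X)
  ll <- 0
  grad <- numeric(m)
  hess <- matrix(0, m, m)
  np <- pairs$n_pairs
  one_block <- function(dx, dy) {
    u <- drop(dx %*% beta) * dy
    ll <<- ll + sum(log_plogis(u))
    q <- stats::plogis(-u)            # 1 - p
    grad <<- grad + drop(crossprod(dx, q * dy))
    w <- stats::plogis(u) * q * dy^2  # p (1 - p) dy^2
    hess <<- hess - crossprod(dx, dx * w)
  }
  if (!is.null(cache)) {
    one_block(cache$dx, cache$dy)
  } else {
    for (start in seq(1L, np, by = block_size)) {
      sel <- start:min(np, start + block_size - 1L)
      one_block(X[pairs$i1[sel], , drop = FALSE] -
                  X[pairs$i2[sel], , drop = FALSE],
                y[pairs$i1[sel]] - y[pairs$i2[sel]])
    }
  }
  list(loglik = ll, gradient = grad, hessian = hess, n_pairs = np)
}

# Per-pair score rows at beta: s_p = dx_p * (1 - p_p) * dy_p, plus the
# subject attribution of each pair (computed blockwise).
pair_scores_by_subject <- function(table, beta, pairs, block_size = 200000L,
                                   cache = NULL) {
  X <- stage2_design(table)
  m <- ncol(X)
  ns <- length(table$K)
  S <- matrix(0, ns, m, dimnames = list(names(table$K), colnames(X)))
  np <- pairs$n_pairs
  for (start in seq(1L, np, by = block_size)) {
    sel <- start:min(np, start + block_size - 1L)
    if (is.null(cache)) {
      dx <- X[pairs$i1[sel], , drop = FALSE] - X[pairs$i2[sel], , drop = FALSE]
      dy <- table$y[pairs$i1[sel]] - table$y[pairs$i2[sel]]
    } else {
      dx <- cache$dx[sel, , drop = FALSE]
      dy <- cache$dy[sel]
    }
    u <- drop(dx %*% beta) * dy
    s <- dx * (stats::plogis(-u) * dy)
    # the pair kernel is symmetric in its two members (dx and dy both flip
    # sign under a swap), so each pair contributes +s to both subjects
    s1 <- rowsum(s, table$subject[pairs$i1[sel]])
    s2 <- rowsum(s, table$subject[pairs$i2[sel]])
    S[as.integer(rownames(s1)), ] <- S[as.integer(rownames(s1)), ] + s1
    S[as.integer(rownames(s2)), ] <- S[as.integer(rownames(s2)), ] + s2
  }
  S
}

#' Subject-clustered sandwich covariance for the pairwise estimator
#'
#' Godambe form `H^-1 V H^-1` with `H = -Hessian of log L` at the estimate
#' and `V = sum_i S_i S_i'`, where `S_i` collects the score contribution of
#' every pair containing subject i (each pair counted once into each of its
#' two member subjects, with the sign of its appearance). This is the
#' U-statistic projection that accounts for the dependence between pairs
#' sharing a subject.
#'
#' @param table an `analysis_table`.
#' @param beta the converged pairwise estimate.
#' @param pairs optional precomputed pair enumeration (must match the set the
#'   estimate was fitted on).
#' @return Covariance matrix.
#' @export
sandwich_cov <- function(table, beta, pairs = NULL) {
  pairs <- pairs %||% enumerate_pairs(table)
  obj <- composite_loglik(table, beta, pairs = pairs)
  H <- -obj$hessian
  Hi <- tryCatch(solve(H), error = function(e)
    abort_pm("singular sensitivity matrix in sandwich covariance",
             "singular_information_error"))
  S <- pair_scores_by_subject(table, beta, pairs)
  V <- crossprod(S)
  cov <- Hi %*% V %*% Hi
  (cov + t(cov)) / 2
}

#' Fit the pairwise composite conditional likelihood
#'
#' Newton iterations with step halving on the globally concave composite log
#' likelihood, starting from `beta = 0`. Coefficients are on the
#' density-ratio (tilt) scale: for a Gaussian outcome with total variance
#' `sigma^2`, tilt coefficients equal mean-scale coefficients divided by
#' `sigma^2`. Standard errors are subject-clustered Godambe sandwich values;
#' Wald z tests are reported per coefficient.
#'
#' For large cohorts the full pair set grows quadratically; setting
#' `pair_subsample_fraction < 1` fits on a seeded uniform subsample of
#' subject pairs (all observation pairs of a sampled subject pair are kept),
#' with the sandwich computed on the same subsample.
#'
#' @param table an `analysis_table`. Any intercept column is dropped:
#'   constants cancel in pair differences.
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the gradient max-norm (per pair) and
#'   the relative objective change.
#' @param init optional starting value (defaults to 0).
#' @param pair_subsample_fraction fraction of subject pairs to use.
#' @param seed seed for the subject-pair subsample (required when
#'   `pair_subsample_fraction < 1`).
#' @param block_size pairs per evaluation block.
#' @return An object of class `stage2_result` with elements `beta`, `cov`,
#'   `se`, `z`, `p_value`, `n_pairs`, `loglik`, `converged`, `iterations`,
#'   `pair_subsample_fraction`.
#' @export
fit_pairwise <- function(table, max_iter = 50L, tol = 1e-8, init = NULL,
                         pair_subsample_fraction = 1, seed = NULL,
                         block_size = 200000L) {
  X <- stage2_design(table)
  m <- ncol(X)
  subject_pairs <- NULL
  if (pair_subsample_fraction < 1) {
    ns <- length(table$K)
    all_pairs <- t(utils::combn(ns, 2L))
    if (is.null(seed))
      abort_pm("pair subsampling requires a seed", "config_error")
    set.seed(seed)
    take <- max(2L, ceiling(pair_subsample_fraction * nrow(all_pairs)))
    subject_pairs <- all_pairs[sample.int(nrow(all_pairs), take), , drop = FALSE]
  }
  pairs <- enumerate_pairs(table, subject_pairs)
  cache <- pm_pair_cache(X, table$y, pairs)
  evaluate <- function(b) {
    out <- pm_pair_eval(X, table$y, pairs, b, block_size, cache)
    dimnames(out$hessian) <- list(colnames(X), colnames(X))
    names(out$gradient) <- colnames(X)
    out
  }

  # identification: the pair-difference design must have full column rank;
  # check via the Hessian at 0 (weights are strictly positive for dy != 0)
  obj <- evaluate(numeric(m))
  qr0 <- qr(-obj$hessian)
  if (qr0$rank < m) {
    bad <- colnames(X)[qr0$pivot[(qr0$rank + 1):m]]
    abort_pm(paste0("design not identified over pair differences; offending column(s): ",
                    paste(bad, collapse = ", ")), "unidentified_error")
  }

  beta <- if (is.null(init)) numeric(m) else as.numeric(init)
  if (length(beta) != m) abort_pm("init has wrong length", "value_error")
  if (!is.null(init))
    obj <- evaluate(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(obj$gradient)) / pairs$n_pairs < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(-obj$hessian, obj$gradient), error = function(e)
      abort_pm("singular Hessian during Newton iteration", "unidentified_error"))
    h <- 1
    repeat {
      cand <- beta + h * step
      cand_obj <- evaluate(cand)
      if (cand_obj$loglik >= obj$loglik || h < 1e-8) break
      h <- h / 2
    }
    rel_change <- abs(cand_obj$loglik - obj$loglik) /
      max(1, abs(obj$loglik))
    beta <- cand
    obj <- cand_obj
    if (rel_change < tol && max(abs(obj$gradient)) / pairs$n_pairs < sqrt(tol)) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max(abs(obj$gradient)) / pairs$n_pairs < tol)
    converged <- TRUE
  if (!converged)
    abort_pm(sprintf("Newton did not converge in %d iterations (gradient max-norm %.3g)",
                     max_iter, max(abs(obj$gradient))), "convergence_error")

  H <- -obj$hessian
  Hi <- tryCatch(solve(H), error = function(e)
    abort_pm("singular sensitivity matrix in sandwich covariance",
             "singular_information_error"))
  S <- pair_scores_by_subject(table, beta, pairs, block_size, cache)
  cov <- Hi %*% crossprod(S) %*% Hi
  cov <- (cov + t(cov)) / 2
  se <- sqrt(pmax(diag(cov), 0))
  z <- beta / se
  structure(
    list(beta = stats::setNames(beta, colnames(X)),
         cov = cov, se = stats::setNames(se, colnames(X)),
         z = z, p_value = 2 * stats::pnorm(-abs(z)),
         n_pairs = pairs$n_pairs, loglik = obj$loglik,
         converged = converged, iterations = iter,
         pair_subsample_fraction = pair_subsample_fraction),
    class = "stage2_result"
  )
}

#' @export
print.stage2_result <- function(x, digits = 4, ...) {
  cat("Pairwise composite conditional likelihood fit\n")
  cat(sprintf("  %d observation pairs, log composite likelihood %.4f, %d Newton iterations\n",
              x$n_pairs, x$loglik, x$iterations))
  if (x$pair_subsample_fraction < 1)
    cat(sprintf("  fitted on a %.1f%% subsample of subject pairs\n",
                100 * x$pair_subsample_fraction))
  tab <- data.frame(`Effect size` = x$beta, SE = x$se,
                    z = x$z, `p-value` = x$p_value,
                    check.names = FALSE)
  print(round(tab, digits))
  cat("  (coefficients on the density-ratio/tilt scale; divide mean-scale\n",
      "  effects by the outcome variance to compare)\n", sep = "")
  invisible(x)
}
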