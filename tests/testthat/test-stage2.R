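test_that("pair log probability matches direct evaluation of the conditional ratio", {
  # direct evaluation: p = f1 f2 / (f1 f2 + f1s f2s) reduces to a logistic in
  # (beta (x1 - x2)) (y1 - y2); evaluate the ratio numerically for a Gaussian
  # base to stay independent of the package formula
  f <- function(y, x, beta) exp(beta * x * y) * dnorm(y)
  num <- f(1, 1, 1) * f(0, 0, 1)
  den <- num + f(1, 0, 1) * f(0, 1, 1)
  expect_equal(pair_log_probability(1, 0, 1, 0, 1), log(num / den),
               tolerance = 1e-12)
  expect_equal(pair_log_probability(1, 0, 1, 0, 1), -log(1 + exp(-1)),
               tolerance = 1e-12)
  # ties contribute log(1/2)
  expect_equal(pair_log_probability(2, 2, 1, 0, 3), log(0.5), tolerance = 1e-15)
  # the two orderings are the two outcomes of the same conditional law
  p <- exp(pair_log_probability(1.3, -0.4, c(1, 2), c(0, 1), c(0.7, -0.2)))
  p_swap <- exp(pair_log_probability(-0.4, 1.3, c(1, 2), c(0, 1), c(0.7, -0.2)))
  expect_equal(p + p_swap, 1, tolerance = 1e-12)
  # extreme exponents stay finite
  expect_true(is.finite(pair_log_probability(500, -500, 10, -10, 5)))
  expect_error(pair_log_probability(Inf, 0, 1, 0, 1),
               class = "pairmnar_value_error")
})

test_that("pair enumeration counts cross-subject pairs", {
  tab <- raw_table(y = rnorm(9), X = rnorm(9),
                   subject = rep(c("A", "B"), c(3, 6)))
  expect_equal(enumerate_pairs(tab)$n_pairs, 18L)
  tab3 <- raw_table(y = rnorm(6), X = rnorm(6), subject = rep(1:3, each = 2))
  expect_equal(enumerate_pairs(tab3)$n_pairs, 12L)
  pr <- enumerate_pairs(tab3)
  expect_true(all(tab3$subject[pr$i1] != tab3$subject[pr$i2]))
  tab1 <- raw_table(y = rnorm(4), X = rnorm(4), subject = rep("A", 4))
  expect_error(enumerate_pairs(tab1), class = "pairmnar_insufficient_data_error")
})

test_that("composite likelihood matches the quadruple-loop oracle", {
  set.seed(42)
  tab <- raw_table(y = rnorm(10), X = cbind(a = rnorm(10), b = rnorm(10)),
                   subject = rep(1:3, c(3, 3, 4)))
  for (beta in list(c(0, 0), c(0.5, -0.2), c(-1.2, 0.8))) {
    got <- composite_loglik(tab, beta)
    want <- loop_composite_loglik(tab, beta)
    expect_equal(got$loglik, want$loglik, tolerance = 1e-10)
    expect_equal(got$n_pairs, want$n_pairs)
    fd <- fd_gradient(function(b) loop_composite_loglik(tab, b)$loglik, beta)
    expect_equal(unname(got$gradient), fd, tolerance = 1e-6)
    fd_hess <- vapply(seq_along(beta), function(k) {
      e <- numeric(length(beta)); e[k] <- 1e-5
      (composite_loglik(tab, beta + e)$gradient -
         composite_loglik(tab, beta - e)$gradient) / (2e-5)
    }, numeric(length(beta)))
    expect_equal(unname(got$hessian), unname(fd_hess), tolerance = 1e-5)
  }
})

test_that("analytic identities of the composite objective hold", {
  set.seed(7)
  tab <- raw_table(y = rnorm(12),
                   X = cbind("(Intercept)" = 1, a = rnorm(12), b = rnorm(12)),
                   subject = rep(1:4, each = 3))
  np <- enumerate_pairs(tab)$n_pairs
  at0 <- composite_loglik(tab, c(0, 0))
  expect_equal(at0$loglik, -np * log(2), tolerance = 1e-10)

  # translation invariance: only outcome differences enter
  tab_shift <- tab; tab_shift$y <- tab$y + 123.456
  for (beta in list(c(0.3, -0.4), c(-1, 2))) {
    expect_equal(composite_loglik(tab_shift, beta)$loglik,
                 composite_loglik(tab, beta)$loglik, tolerance = 1e-10)
  }

  # a constant design column contributes exactly zero gradient at any beta:
  # evaluate with the constant kept as an ordinary column
  tab_const <- raw_table(y = tab$y, X = cbind(const = 1, a = tab$X[, "a"]),
                         subject = tab$subject_id)
  g <- composite_loglik(tab_const, c(5, -0.3))$gradient
  expect_equal(unname(g["const"]), 0, tolerance = 1e-10)
})

test_that("blocked evaluation is independent of block size", {
  set.seed(8)
  tab <- raw_table(y = rnorm(20), X = cbind(rnorm(20), rnorm(20)),
                   subject = rep(1:5, each = 4))
  beta <- c(0.4, -0.7)
  ref <- composite_loglik(tab, beta, block_size = 1e6)
  for (bs in c(1L, 7L, 50L)) {
    got <- composite_loglik(tab, beta, block_size = bs)
    expect_equal(got$loglik, ref$loglik, tolerance = 1e-10)
    expect_equal(got$gradient, ref$gradient, tolerance = 1e-10)
    expect_equal(got$hessian, ref$hessian, tolerance = 1e-10)
  }
})

test_that("the objective is concave and invariant to subject relabelling", {
  set.seed(9)
  tab <- raw_table(y = rnorm(15), X = cbind(rnorm(15), rnorm(15)),
                   subject = rep(1:5, each = 3))
  for (i in 1:20) {
    beta <- rnorm(2, 0, 2)
    ev <- eigen(composite_loglik(tab, beta)$hessian, symmetric = TRUE)$values
    expect_lte(max(ev), 1e-8)
  }
  fit <- fit_pairwise(tab)
  perm <- c(3, 1, 5, 2, 4)
  ord <- order(match(tab$subject, perm))
  tab_perm <- raw_table(tab$y[ord], tab$X[ord, ], tab$subject_id[ord])
  fit_perm <- fit_pairwise(tab_perm)
  expect_equal(fit_perm$loglik, fit$loglik, tolerance = 1e-8)
  expect_equal(unname(fit_perm$beta), unname(fit$beta), tolerance = 1e-8)
  expect_equal(unname(fit_perm$se), unname(fit$se), tolerance = 1e-6)
})

test_that("Newton fit maximises the objective and flags unidentified designs", {
  set.seed(10)
  tab <- raw_table(y = rnorm(16), X = cbind(a = rnorm(16), b = rbinom(16, 1, 0.5)),
                   subject = rep(1:4, each = 4))
  fit <- fit_pairwise(tab)
  expect_true(fit$converged)
  expect_lte(fit$loglik, 0)
  # gradient at the optimum is numerically zero
  g <- composite_loglik(tab, fit$beta)$gradient
  expect_lt(max(abs(g)) / fit$n_pairs, 1e-7)
  # a dense grid around the optimum finds no better value
  for (k in 1:2) for (delta in c(-0.05, -0.01, 0.01, 0.05)) {
    b <- fit$beta; b[k] <- b[k] + delta
    expect_lt(composite_loglik(tab, b)$loglik, fit$loglik)
  }

  # intercept-only: constants cancel, nothing identified
  tab_int <- raw_table(y = rnorm(6), X = cbind("(Intercept)" = rep(1, 6)),
                       subject = rep(1:2, each = 3))
  expect_error(fit_pairwise(tab_int), class = "pairmnar_unidentified_error")
  # exactly collinear columns are named
  tab_col <- raw_table(y = rnorm(8), X = cbind(a = 1:8, b = 2 * (1:8)),
                       subject = rep(1:2, each = 4))
  err <- tryCatch(fit_pairwise(tab_col), error = function(e) e)
  expect_s3_class(err, "pairmnar_unidentified_error")
})

test_that("sandwich covariance equals direct enumeration on a small fixture", {
  set.seed(12)
  tab <- raw_table(y = rnorm(9), X = cbind(a = rnorm(9), b = rnorm(9)),
                   subject = rep(1:3, each = 3))
  fit <- fit_pairwise(tab)
  # direct computation: per-pair scores, summed into both member subjects
  X <- tab$X; y <- tab$y
  pr <- enumerate_pairs(tab)
  S <- matrix(0, 3, 2)
  H <- matrix(0, 2, 2)
  for (p in seq_len(pr$n_pairs)) {
    i <- pr$i1[p]; j <- pr$i2[p]
    dx <- X[i, ] - X[j, ]; dy <- y[i] - y[j]
    u <- sum(fit$beta * dx) * dy
    s <- dx * dy * plogis(-u)
    S[tab$subject[i], ] <- S[tab$subject[i], ] + s
    S[tab$subject[j], ] <- S[tab$subject[j], ] + s
    H <- H + outer(dx, dx) * plogis(u) * plogis(-u) * dy^2
  }
  V <- t(S) %*% S
  want <- solve(H) %*% V %*% solve(H)
  expect_equal(unname(fit$cov), unname(want), tolerance = 1e-10)
  got <- sandwich_cov(tab, fit$beta)
  expect_equal(unname(got), unname(want), tolerance = 1e-10)
  # symmetric PSD
  expect_equal(got, t(got), tolerance = 1e-12)
  expect_gte(min(eigen(got, symmetric = TRUE)$values), -1e-10)
})

test_that("pair subsampling reproduces with a seed and scales to large cohorts", {
  sp <- model_spec(covariates = c("sex", "time"), center = character(),
                   time_unit = 1)
  d <- simulate_complete_cohort(simulation_config(
    60, 5, true_beta = c(sex = -0.5, time = 0.3), noise_sd = 1, seed = 44,
    spec = sp))
  tab <- build_analysis_table(d, sp)
  full <- fit_pairwise(tab)
  sub1 <- fit_pairwise(tab, pair_subsample_fraction = 0.3, seed = 7)
  sub2 <- fit_pairwise(tab, pair_subsample_fraction = 0.3, seed = 7)
  expect_identical(sub1$beta, sub2$beta)
  expect_lt(sub1$n_pairs, full$n_pairs)
  # subsampled estimate agrees with the full fit within joint uncertainty
  expect_lt(max(abs(sub1$beta - full$beta) / full$se), 4)
  expect_error(fit_pairwise(tab, pair_subsample_fraction = 0.3),
               class = "pairmnar_config_error")
})

test_that("tilt scale: doubling the noise sd divides the estimand by four", {
  sp <- model_spec(covariates = c("sex", "time"), center = character(),
                   time_unit = 1)
  est <- matrix(NA, 30, 2)
  for (r in 1:30) {
    d <- simulate_complete_cohort(simulation_config(
      120, 4, true_beta = c(sex = -0.8, time = 0.6), noise_sd = 2,
      seed = 500 + r, spec = sp))
    est[r, ] <- fit_pairwise(build_analysis_table(d, sp))$beta
  }
  mc_se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - (-0.8 / 4)), 3 * mc_se[1])
  expect_lt(abs(mean(est[, 2]) - (0.6 / 4)), 3 * mc_se[2])
})
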