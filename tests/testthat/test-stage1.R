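test_that("cross-sectional extraction summarises subjects correctly", {
  subjects <- data.frame(
    subject_id = c("A", "B"), arm = "control", age = c(40, 60), sex = c(1, 0),
    baseline_bmi = 35, baseline_weight = c(200, 180))
  series <- rbind(
    data.frame(subject_id = "A", day = 0:1, observed = TRUE,
               weight = c(197, 195)),                      # outcomes -3, -5
    data.frame(subject_id = "B", day = 0:1, observed = FALSE,
               weight = NA_real_))
  d <- longitudinal_dataset(subjects, series, 2)
  sp <- model_spec(covariates = c("age", "sex"), center = character(),
                   time_unit = 1)
  s <- extract_stage1_sample(d, sp, summary = "subject_mean")
  expect_equal(s$y[s$subject_id == "A"], -4)
  expect_equal(s$r, c(1, 0))
  expect_true(is.na(s$y[s$subject_id == "B"]))

  s0 <- extract_stage1_sample(d, sp, summary = "milestone_day", milestone_day = 1)
  expect_equal(s0$r, c(1, 0))
  expect_equal(s0$y[1], -5)
  expect_error(
    extract_stage1_sample(d, sp, summary = "milestone_day", milestone_day = 2),
    class = "pairmnar_value_error")
  expect_error(extract_stage1_sample(d, model_spec(covariates = c("age", "time"),
                                                   center = character())),
               class = "pairmnar_value_error")
})

test_that("Gaussian MLE reduces to least squares on the natural scale", {
  s <- raw_stage1_sample(y = c(0, 1, 0.5, 0.2), x = c(0, 1, 0.5, 0.3))
  fit <- mle_fit(s, expfam_spec("gaussian_identity", dispersion = 1))
  ls <- lm.fit(cbind(1, s$x), s$y)$coefficients
  expect_equal(unname(fit$beta_nat), unname(ls), tolerance = 1e-12)

  # constant response: zero slope, intercept c / dispersion
  sc <- raw_stage1_sample(y = rep(2, 5), x = c(1, 2, 3, 4, 5))
  fitc <- mle_fit(sc, expfam_spec("gaussian_identity", dispersion = 4))
  expect_equal(unname(fitc$beta_nat), c(2 / 4, 0), tolerance = 1e-12)
})

test_that("Gaussian MLE matches a direct likelihood maximiser", {
  set.seed(31)
  s <- raw_stage1_sample(y = c(-0.2, 1.4, 0.7, -1.1, 0.4),
                         x = c(0.1, 1.2, 0.8, -0.9, 0.2))
  fit <- mle_fit(s)
  # independent oracle: numerical maximisation of the Gaussian log likelihood
  # in (alpha, slope, log dispersion)
  nll <- function(par) {
    mu <- par[1] + par[2] * s$x
    -sum(dnorm(s$y, mu, exp(par[3] / 2), log = TRUE))
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  lambda_opt <- exp(opt$par[3])
  expect_equal(unname(fit$beta_nat), opt$par[1:2] / lambda_opt,
               tolerance = 1e-6)
  expect_equal(fit$lambda, lambda_opt, tolerance = 1e-6)

  # degenerate designs error out
  s2 <- raw_stage1_sample(y = rnorm(5), x = rep(1, 5))
  expect_error(mle_fit(s2), class = "pairmnar_singular_design_error")
  expect_error(mle_fit(raw_stage1_sample(y = 1:2, x = 1:2)),
               class = "pairmnar_insufficient_data_error")
})

test_that("pairwise pseudo-likelihood slope matches a dense grid search", {
  s <- raw_stage1_sample(y = c(0.3, -0.9, 1.7, 0.5),
                         x = c(1.0, -0.5, 2.0, 0.2))
  fit <- pseudo_likelihood_fit(s)
  obj <- function(b) {
    tot <- 0
    for (i in 1:3) for (j in (i + 1):4) {
      u <- b * (s$x[i] - s$x[j]) * (s$y[i] - s$y[j])
      tot <- tot - log(1 + exp(-u))
    }
    tot
  }
  grid <- seq(-3, 3, by = 1e-4)
  best <- grid[which.max(vapply(grid, obj, numeric(1)))]
  expect_equal(unname(fit$beta_nat[2]), best, tolerance = 1e-4)

  # constant response leaves the slope unidentified
  expect_error(
    pseudo_likelihood_fit(raw_stage1_sample(y = rep(1, 4), x = 1:4)),
    class = "pairmnar_unidentified_slope_error")
})

test_that("both estimators agree under MCAR within joint uncertainty", {
  set.seed(33)
  n <- 600
  x <- cbind(age = rnorm(n, 0, 10.5), sex = rbinom(n, 1, 0.916))
  y <- 0.03 * x[, 1] - 0.5 * x[, 2] + rnorm(n)
  r <- as.numeric(runif(n) < 0.8)
  y[r == 0] <- NA
  s <- raw_stage1_sample(y, x, r)
  fh <- mle_fit(s)
  ft <- pseudo_likelihood_fit(s)
  W <- estimate_W(fh, ft)
  d <- ft$beta_nat - fh$beta_nat
  # each coordinate within 3 standard errors of its estimated null scale
  for (k in seq_along(d)) {
    expect_lt(abs(d[k]), 3 * sqrt(W[k, k] / fh$n_complete) + 1e-12)
  }
})

test_that("the weighting matrix is the average outer product of influence gaps", {
  set.seed(34)
  s <- raw_stage1_sample(y = rnorm(8), x = cbind(a = rnorm(8), b = rnorm(8)))
  fh <- mle_fit(s)
  ft <- pseudo_likelihood_fit(s)
  W <- estimate_W(fh, ft)
  dphi <- ft$phi - fh$phi
  want <- matrix(0, 3, 3)
  for (i in 1:8) want <- want + outer(dphi[i, ], dphi[i, ]) / 8
  expect_equal(unname(W), unname(want), tolerance = 1e-12)
  expect_equal(W, t(W), tolerance = 1e-14)
  expect_gte(min(eigen(W, symmetric = TRUE)$values), -1e-10)

  # identical influences give the zero matrix
  ft2 <- ft; ft2$phi <- fh$phi
  expect_equal(max(abs(estimate_W(fh, ft2))), 0, tolerance = 1e-14)
  # mismatched samples are rejected
  fh2 <- fh; fh2$n_complete <- fh$n_complete - 1L
  expect_error(estimate_W(fh2, ft), class = "pairmnar_value_error")
})

test_that("chi-squared upper tail matches a numerical integration oracle", {
  want <- integrate(function(t) dchisq(t, df = 3), 9.12, Inf,
                    rel.tol = 1e-10)$value
  expect_equal(pchisq(9.12, df = 3, lower.tail = FALSE), want,
               tolerance = 1e-8)
  expect_equal(want, 0.02774, tolerance = 1e-4)
})

test_that("the Gaussian test projects the profiled-intercept direction", {
  sp <- model_spec(covariates = c("age", "sex"), center = "age", time_unit = 1)
  cfg <- simulation_config(250, 1, true_beta = c(age = 0.1, sex = -2),
                           noise_sd = 4,
                           mechanism = missingness_mechanism("mcar", p_const = 0.8),
                           seed = 77, spec = sp)
  dat <- simulate_cohort(cfg)
  res <- mnar_test(dat, sp, summary = "milestone_day", milestone_day = 0)
  # the intercept contrast is exactly -xbar' slope contrast, so the
  # carried rank is m
  expect_equal(res$df, 2L)
  expect_gte(res$T, 0)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  s <- extract_stage1_sample(dat, sp, "milestone_day", milestone_day = 0)
  xbar_cc <- colMeans(s$x[s$r == 1, , drop = FALSE])
  d <- res$beta_tilde - res$beta_hat
  expect_equal(unname(d[1]), -sum(xbar_cc * d[-1]), tolerance = 1e-10)
})

test_that("T is invariant to affine rescaling of the covariates", {
  sp <- model_spec(covariates = c("age", "sex"), center = "age", time_unit = 1)
  cfg <- simulation_config(200, 1, true_beta = c(age = 0.1, sex = -2),
                           noise_sd = 4,
                           mechanism = missingness_mechanism("mcar", p_const = 0.9),
                           seed = 78, spec = sp)
  d <- simulate_cohort(cfg)
  res1 <- mnar_test(d, sp, summary = "milestone_day", milestone_day = 0)
  # rescale age by 10 (decades instead of years)
  d2 <- d
  d2$subjects$age <- d$subjects$age / 10
  res2 <- mnar_test(d2, sp, summary = "milestone_day", milestone_day = 0)
  expect_equal(res2$T, res1$T, tolerance = 1e-6)
  expect_equal(res2$df, res1$df)
})

test_that("Bernoulli working family keeps the full contrast rank", {
  set.seed(35)
  n <- 300
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(0.2 + 0.8 * x[, 1] - 0.5 * x[, 2]))
  s <- raw_stage1_sample(y, x)
  fh <- mle_fit(s, expfam_spec("bernoulli_logit"))
  ft <- pseudo_likelihood_fit(s, expfam_spec("bernoulli_logit"))
  W <- estimate_W(fh, ft)
  gi <- pairmnar:::psd_geninv(W)
  expect_equal(gi$rank, 3L)
  # logistic MLE agrees with glm
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(fh$beta_nat), unname(coef(ref)), tolerance = 1e-6)
})
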