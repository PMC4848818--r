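test_that("truncated-normal draws respect extreme bounds without underflow", {
  set.seed(1)
  x <- rtruncnorm(5000, 0, 1, 8, 9)
  expect_true(all(is.finite(x) & x > 8 & x <= 9))
  x2 <- rtruncnorm(5000, 0, 1, -9, -8)
  expect_true(all(is.finite(x2) & x2 > -9 & x2 <= -8))
  expect_equal(rtruncnorm(3, 0, 1, 2, 2), rep(2, 3))
  expect_error(rtruncnorm(1, 0, 1, 1, 0), "exceeds")
  # infinite bounds reduce to the plain normal
  set.seed(2)
  y <- rtruncnorm(50000, 1, 2, -Inf, Inf)
  expect_lt(abs(mean(y) - 1), 0.05)
  expect_lt(abs(sd(y) - 2), 0.05)
  # interior truncation matches the analytic moments
  set.seed(3)
  w <- rtruncnorm(50000, 0, 1, -1, 0.5)
  m_true <- (dnorm(-1) - dnorm(0.5)) / (pnorm(0.5) - pnorm(-1))
  expect_lt(abs(mean(w) - m_true), 0.01)
})

test_that("latent-response updates honour the truncation contract", {
  cfg <- default_hcfc_truth(seed = 4, n_respondents = 100, missing_rate = 0.1)
  rt <- simulate_responses(cfg)$responses
  set.seed(8)
  m <- update_latent_mlv(init_model(rt, cfg$spec), rt)
  rec <- recode_responses(rt, cfg$spec)$responses
  tauext <- cbind(-Inf, m$tau, Inf)
  for (j in seq_len(n_items(cfg$spec))) {
    obs <- which(!is.na(rec[, j]))
    y <- rec[obs, j]
    expect_true(all(m$z[obs, j] > tauext[j, y] & m$z[obs, j] <= tauext[j, y + 1]))
  }
})

test_that("with zero loadings the latent responses are marginally standard normal", {
  spec <- tiny_instrument(2)
  n <- 25000
  y <- matrix(NA_integer_, n, 2, dimnames = list(NULL, c("a", "b")))
  rt <- response_table(y, spec)
  m <- suppressWarnings(init_model(rt, spec))
  m$lambda[] <- 0
  m$tau <- matrix(c(0, 0), 2, 1)  # irrelevant: all cells imputed untruncated
  set.seed(5)
  m <- update_latent_mlv(m, rt)
  expect_lt(abs(mean(m$z)), 0.02)
  expect_lt(abs(sd(m$z) - 1), 0.02)
})

test_that("imputed missing cells carry the model-implied marginal scale", {
  # closed-form moment oracle: sd(z_j) = sqrt(lambda^2 phi + psi)
  spec <- tiny_instrument(2)
  n <- 50000
  phi <- matrix(0.8)
  lam <- c(1, 2.5)
  y <- matrix(NA_integer_, n, 2, dimnames = list(NULL, c("a", "b")))
  rt <- response_table(y, spec)
  m <- suppressWarnings(init_model(rt, spec))
  set.seed(6)
  m$phi <- phi
  m$eta <- matrix(rnorm(n, 0, sqrt(phi[1])), n, 1)
  m$lambda[] <- lam
  m <- update_latent_mlv(m, rt)
  for (j in 1:2) {
    expect_lt(abs(sd(m$z[, j]) / sqrt(lam[j]^2 * phi[1] + 1) - 1), 0.02)
  }
})

test_that("factor updates collapse to the data in the noiseless limit", {
  sim <- binary_sim(500)
  m <- init_model(sim$rt, tiny_instrument())
  m$lambda[] <- c(1, 1)
  m$psi[] <- 1e-8
  m$z <- cbind(sim$z[, 1], sim$z[, 1])  # both items agree exactly
  set.seed(7)
  m2 <- update_factors(m)
  expect_lt(max(abs(m2$eta[, 1] - sim$z[, 1])), 0.01)
})

test_that("loading updates keep markers fixed and recover a known slope", {
  set.seed(9)
  n <- 10000
  spec <- tiny_instrument(2)
  eta <- matrix(rnorm(n), n, 1)
  m <- suppressWarnings(init_model(
    response_table(matrix(NA_integer_, n, 2, dimnames = list(NULL, c("a", "b"))),
                   spec), spec))
  m$eta <- eta
  m$z <- cbind(eta[, 1] + rnorm(n), 2.83 * eta[, 1] + rnorm(n))
  draws <- replicate(50, update_loadings(m)$lambda)
  expect_true(all(draws["a", ] == 1))          # marker never moves
  expect_lt(abs(mean(draws["b", ]) - 2.83), 0.1)
  # a point-mass prior at zero dominates any data
  m$prior$loading_var <- 1e-8
  expect_lt(abs(update_loadings(m)$lambda["b"]), 1e-3)
})

test_that("residual-variance updates respect mode and the truncation bound", {
  sim <- binary_sim(200)
  m <- init_model(sim$rt, tiny_instrument(), mode = "probit")
  expect_identical(update_residual_variances(m)$psi, m$psi)
  mp <- init_model(sim$rt, tiny_instrument(), mode = "anchored")
  set.seed(10)
  for (k in 1:25) {
    mp2 <- update_residual_variances(mp)
    expect_true(all(mp2$psi > 0 & mp2$psi < 100))
  }
})

test_that("factor-covariance updates stay positive definite and consistent", {
  set.seed(11)
  Fk <- 8
  cfg <- default_hcfc_truth(seed = 1)
  n <- 50000
  eta <- MASS::mvrnorm(n, rep(0, Fk), cfg$factor_cov)
  m <- list(eta = eta, phi = diag(Fk), prior = prior_spec(Fk))
  class(m) <- "ordcfa_model"
  m$phi <- diag(Fk)
  m2 <- update_factor_cov(m)
  expect_true(all(eigen(m2$phi, symmetric = TRUE, only.values = TRUE)$values > 0))
  # consistency at large n: single draw concentrates at the truth
  expect_lt(max(abs(m2$phi - cfg$factor_cov) / sqrt(diag(cfg$factor_cov) %o%
                                                      diag(cfg$factor_cov))),
            0.03)
})

test_that("threshold moves preserve ordering and the fixed-threshold contract", {
  cfg <- default_hcfc_truth(seed = 15, n_respondents = 120, missing_rate = 0.03)
  rt <- simulate_responses(cfg)$responses
  set.seed(16)
  m <- init_model(rt, cfg$spec)
  m <- update_latent_mlv(m, rt)
  for (k in 1:30) {
    m <- update_thresholds(m, rt, 0.2)
    expect_true(all(apply(m$tau, 1, function(t) all(diff(t) > 0))))
    m <- update_item_scales(m, rt, 0.1)
    expect_true(all(apply(m$tau, 1, function(t) all(diff(t) > 0))))
    m <- update_latent_mlv(m, rt)
  }
  d_fixed <- fit_ordcfa(rt, cfg$spec,
                        chain_config(n_iterations = 12, burn_in = 2,
                                     n_chains = 1, seed = 1,
                                     sample_thresholds = FALSE))
  tau_draws <- d_fixed$chains[[1]]$tau
  expect_true(all(tau_draws == rep(tau_draws[1, ], each = nrow(tau_draws))))
})

test_that("a binary cut is recovered from its profile-likelihood location", {
  # 2-category items, all structural parameters held at truth: the cut's
  # posterior must sit at the margin-implied probit value (true cut 0.5)
  set.seed(17)
  n <- 20000
  spec <- tiny_instrument(2)
  eta <- rnorm(n)
  z <- cbind(eta + rnorm(n), 1.5 * eta + rnorm(n))
  y <- cbind(a = (z[, 1] > 0.5) + 1L, b = (z[, 2] > 0.7) + 1L)
  rt <- response_table(y, spec)
  m <- init_model(rt, spec)
  m$lambda[] <- c(1, 1.5)
  m$phi <- matrix(1)
  m <- update_latent_mlv(m, rt)
  taus <- numeric(300)
  for (k in seq_len(300)) {
    m <- update_thresholds(m, rt, 0.05)
    m <- update_latent_mlv(m, rt)
    m <- update_factors(m)   # loadings and factor variance stay at truth
    taus[k] <- m$tau[1, 1]
  }
  post_mean <- mean(taus[101:300])
  margin_mle <- qnorm(mean(y[, "a"] == 1)) * sqrt(2)  # sd(z_a) = sqrt(2)
  expect_lt(abs(post_mean - margin_mle), 0.05)
  expect_lt(abs(post_mean - 0.5), 0.05)
})

test_that("chains are reproducible and keep the prescribed number of draws", {
  sim <- binary_sim(40)
  cc <- chain_config(n_iterations = 60, burn_in = 20, thinning = 3,
                     n_chains = 2, seed = 77)
  d1 <- fit_ordcfa(sim$rt, tiny_instrument(), cc)
  d2 <- fit_ordcfa(sim$rt, tiny_instrument(), cc)
  expect_equal(d1$n_kept, floor((60 - 20) / 3))
  expect_identical(d1$chains[[1]]$lambda, d2$chains[[1]]$lambda)
  expect_identical(d1$chains[[2]]$phi, d2$chains[[2]]$phi)
  expect_false(identical(d1$chains[[1]]$lambda, d1$chains[[2]]$lambda))
})

test_that("the complete-data log joint shows no post-burn-in drift", {
  cfg <- default_hcfc_truth(seed = 18, n_respondents = 150, missing_rate = 0)
  rt <- simulate_responses(cfg)$responses
  d <- fit_ordcfa(rt, cfg$spec,
                  chain_config(n_iterations = 900, burn_in = 500,
                               n_chains = 1, seed = 3))
  lj <- d$chains[[1]]$log_joint
  expect_true(all(is.finite(lj)))
  fit <- lm(lj ~ seq_along(lj))
  slope_t <- summary(fit)$coefficients[2, "t value"]
  expect_lt(abs(slope_t), 4)
})

test_that("draws round-trip through the columnar text format", {
  sim <- binary_sim(30)
  d <- fit_ordcfa(sim$rt, tiny_instrument(),
                  chain_config(n_iterations = 30, burn_in = 10, n_chains = 2,
                               seed = 2))
  dir <- withr::local_tempdir()
  write_draws(d, dir)
  d2 <- read_draws(dir)
  expect_equal(d2$chains[[1]]$lambda, d$chains[[1]]$lambda, tolerance = 1e-12)
  expect_equal(d2$chains[[2]]$phi, d$chains[[2]]$phi, tolerance = 1e-12)
  expect_equal(d2$config$seed, d$config$seed)
  expect_equal(summarize_draws(d2)$mean, summarize_draws(d)$mean,
               tolerance = 1e-12)
})
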