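test_that("the default truth encodes the headline structure", {
  cfg <- default_hcfc_truth(seed = 1)
  expect_s3_class(cfg, "synthetic_config")
  expect_equal(unname(cfg$loadings["feeling_tired"]), 2.83)
  expect_equal(unname(cfg$loadings["feeling_abandoned"]), 2.92)
  expect_equal(unname(cfg$loadings["enjoy_caring"]), 1.39)
  expect_true(all(cfg$loadings[is_marker(cfg$spec)] == 1))
  expect_true(all(apply(cfg$thresholds, 1, function(t) all(diff(t) > 0))))
  ev <- eigen(cfg$factor_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # all factor pairs positively correlated, as in the published pattern
  expect_true(all(stats::cov2cor(cfg$factor_cov)[lower.tri(diag(8))] > 0))
})

test_that("simulation is deterministic and honours the missingness rate", {
  cfg0 <- default_hcfc_truth(seed = 5, n_respondents = 120, missing_rate = 0)
  s1 <- simulate_responses(cfg0)
  s2 <- simulate_responses(cfg0)
  expect_identical(s1$responses$responses, s2$responses$responses)
  expect_identical(s1$truth$eta, s2$truth$eta)
  expect_equal(sum(is.na(s1$responses$responses)), 0L)

  cfg2 <- default_hcfc_truth(seed = 5, n_respondents = 2000, missing_rate = 0.1)
  s3 <- simulate_responses(cfg2)
  rate <- mean(is.na(s3$responses$responses))
  expect_lt(abs(rate - 0.1), 0.01)
})

test_that("invalid generative configurations are rejected before sampling", {
  spec <- tiny_instrument(5)
  good_tau <- matrix(rep(qnorm(c(.2, .4, .6, .8)), each = 2), 2)
  bad_cov <- matrix(c(1, 2, 2, 1), 2)  # not PD
  expect_error(synthetic_config(spec, c(1, 1), bad_cov, 1, good_tau, 10),
               "symmetric")
  expect_error(synthetic_config(hcfc8_instrument(), 1,
                                bad_cov %x% diag(4), 1,
                                default_hcfc_truth()$thresholds, 10),
               "positive definite")
  expect_error(synthetic_config(spec, c(1, 1), diag(1), -1, good_tau, 10),
               "residual variances")
  expect_error(synthetic_config(spec, c(1, 1), diag(1), 1,
                                good_tau[, c(2, 1, 3, 4)], 10),
               "strictly increasing")
})

test_that("zero loadings with quintile cuts give uniform categories", {
  # closed-form oracle: with lambda = 0 and psi = 1 the latent response is
  # standard normal, so quintile cuts give 0.2 mass per category
  spec <- hcfc8_instrument()
  tau <- matrix(rep(qnorm(c(.2, .4, .6, .8)), each = 20), 20)
  cfg <- synthetic_config(spec, loadings = 0, factor_cov = diag(8),
                          residual_var = 1, thresholds = tau,
                          n_respondents = 50000, seed = 31)
  freqs <- category_frequencies(simulate_responses(cfg)$responses)
  expect_true(all(abs(freqs - 0.2) < 0.01))
})

test_that("marginal category frequencies match the probit closed form", {
  cfg <- default_hcfc_truth(seed = 8, n_respondents = 50000, missing_rate = 0)
  freqs <- category_frequencies(simulate_responses(cfg)$responses)
  zsd <- sqrt(cfg$loadings^2 * diag(cfg$factor_cov)[item_factor_index(cfg$spec)] +
                cfg$residual_var)
  for (j in seq_len(n_items(cfg$spec))) {
    expected <- diff(c(0, pnorm(cfg$thresholds[j, ] / zsd[j]), 1))
    # reverse-keyed items are emitted raw, i.e. with mirrored categories
    if (cfg$spec$items$reversed[j]) expected <- rev(expected)
    expect_true(all(abs(freqs[j, ] - expected) < 0.01))
  }
})

test_that("raising a loading cannot weaken the item-marker association", {
  spec <- tiny_instrument(5)
  tau <- matrix(rep(qnorm(c(.2, .4, .6, .8)), each = 2), 2)
  assoc <- vapply(c(0.5, 1, 2), function(lam) {
    cfg <- synthetic_config(spec, loadings = c(1, lam), factor_cov = diag(1),
                            residual_var = 1, thresholds = tau,
                            n_respondents = 20000, seed = 13)
    y <- simulate_responses(cfg)$responses$responses
    cor(y[, 1], y[, 2], method = "spearman")
  }, numeric(1))
  expect_true(all(diff(assoc) > 0))
})

test_that("category frequencies normalize and flag missing items", {
  spec <- tiny_instrument(5)
  one <- response_table(matrix(3L, 1, 2, dimnames = list(NULL, c("a", "b"))), spec)
  f <- category_frequencies(one)
  expect_equal(unname(f[1, ]), c(0, 0, 1, 0, 0))
  expect_true(all(abs(rowSums(f) - 1) < 1e-12))
  gone <- response_table(matrix(c(NA, NA, 2L, 3L), 2, 2,
                                dimnames = list(NULL, c("a", "b"))), spec)
  expect_warning(f2 <- category_frequencies(gone), "fully missing: a")
  expect_true(all(is.na(f2["a", ])))
  expect_error(category_frequencies(response_table(
    matrix(NA_integer_, 0, 2, dimnames = list(NULL, c("a", "b"))), spec)),
    "empty")
})

test_that("covariate shifts reproduce known subgroup differences", {
  cfg <- default_hcfc_truth(seed = 21, n_respondents = 2000, missing_rate = 0)
  sim <- simulate_responses(cfg, covariates = default_hcfc_covariates())
  expect_equal(sort(names(sim$responses$covariates)), c("age", "income", "sex"))
  sc <- scale_scores(sim$responses, cfg$spec)
  tab <- subgroup_table(sc, sim$responses$covariates, "sex")
  phys <- tab[tab$factor == "physical", ]
  expect_lt(phys$mean[phys$level == "female"], phys$mean[phys$level == "male"])
  expect_lt(phys$p_value[1], 0.001)
  aget <- subgroup_table(sc, sim$responses$covariates, "age")
  expect_gt(aget$estimate[aget$factor == "self_efficacy"], 0.05)
})

test_that("simulations round-trip through the plain-text format", {
  cfg <- default_hcfc_truth(seed = 14, n_respondents = 40, missing_rate = 0.05)
  sim <- simulate_responses(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  rt <- suppressMessages(read_responses(file.path(dir, "responses.csv"), cfg$spec))
  expect_identical(rt$responses, sim$responses$responses)
  truth <- yaml::read_yaml(file.path(dir, "truth_params.yaml"))
  expect_equal(truth$loadings$feeling_tired, 2.83)
})
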