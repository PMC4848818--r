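test_that("read_responses validates and reports what it read", {
  spec <- hcfc8_instrument()
  sim <- simulate_responses(default_hcfc_truth(seed = 1, n_respondents = 62,
                                               missing_rate = 0.01))
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(sim$responses, path)
  expect_message(rt <- read_responses(path, spec), "missing item cell")
  expect_equal(nrow(rt$responses), 62L)
  expect_equal(colnames(rt$responses), spec$items$item)
  expect_equal(sum(is.na(rt$responses)), sum(is.na(sim$responses$responses)))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(spec$items$item, collapse = ","), empty)
  expect_error(read_responses(empty, spec), "no data rows")

  # out-of-range category is located by row and item
  bad <- as.data.frame(sim$responses$responses)
  bad$self_esteem[3] <- 9
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(suppressMessages(read_responses(path2, spec)),
               "row 3.*self_esteem")
  expect_error(response_table(sim$responses$responses[, -1], spec),
               "lacks item column")
})

test_that("scale scores hit the 0-100 bounds and respect reversal", {
  spec <- two_factor_instrument()
  all1 <- matrix(1L, 4, 5, dimnames = list(NULL, spec$items$item))
  all5 <- matrix(5L, 4, 5, dimnames = list(NULL, spec$items$item))
  # a2 is reversed: raw 1 recodes to 5, so feed reversed items their mirror
  all1[, "a2"] <- 5L; all5[, "a2"] <- 1L
  expect_true(all(scale_scores(response_table(all1, spec), spec) == 0))
  expect_true(all(scale_scores(response_table(all5, spec), spec) == 100))

  # two-item factor at the endpoints averages to the midpoint
  m <- all1; m[, "b1"] <- 1L; m[, "b2"] <- 5L
  expect_true(all(scale_scores(response_table(m, spec), spec)$fb == 50))

  # all items of a factor missing -> missing score, others unaffected
  m2 <- all5; m2[1, c("b1", "b2")] <- NA
  sc <- scale_scores(response_table(m2, spec), spec)
  expect_true(is.na(sc$fb[1]))
  expect_false(anyNA(sc$fa))
})

test_that("scoring a reversed item equals scoring its mirror unflagged", {
  flagged <- instrument(data.frame(item = c("p", "q"), factor = "g",
                                   reversed = c(FALSE, TRUE)))
  unflagged <- instrument(data.frame(item = c("p", "q"), factor = "g"))
  set.seed(4)
  y <- matrix(sample(1:5, 60, TRUE), 30, 2, dimnames = list(NULL, c("p", "q")))
  mirrored <- y
  mirrored[, "q"] <- 6L - mirrored[, "q"]
  expect_equal(scale_scores(response_table(y, flagged), flagged),
               scale_scores(response_table(mirrored, unflagged), unflagged))
})

test_that("cronbach_alpha matches longhand arithmetic and edge cases", {
  # toy matrix evaluated by hand: item variances 5/3 each, sum variance 20/3
  toy <- cbind(x = c(1, 2, 3, 4), y = c(2, 3, 4, 5))
  expect_equal(cronbach_alpha(toy), 2 * (1 - (5 / 3 + 5 / 3) / (20 / 3)))
  expect_equal(cronbach_alpha(toy), 1)
  # k duplicated columns give exactly 1 for any k
  set.seed(9)
  v <- sample(1:5, 40, TRUE)
  for (k in 2:4) {
    expect_equal(cronbach_alpha(matrix(v, 40, k)), 1)
  }
  expect_error(cronbach_alpha(matrix(1:4, 4, 1)), "at least 2 items")
  expect_warning(a <- cronbach_alpha(cbind(c(1, NA, NA), c(NA, 2, NA))),
                 "fewer than 2 complete rows")
  expect_true(is.na(a))
})

test_that("per-factor alphas reflect the instrument's internal consistency", {
  cfg <- default_hcfc_truth(seed = 3, n_respondents = 500, missing_rate = 0)
  rt <- simulate_responses(cfg)$responses
  a <- factor_alphas(rt, cfg$spec)
  expect_length(a, 8)
  expect_true(all(a > 0.2 & a < 1))
})

test_that("subgroup tables handle degenerate and regular groupings", {
  scores <- data.frame(f1 = c(50, 50, 50, 50), f2 = c(0, 0, 100, 100))
  cov <- data.frame(g = c("x", "x", "y", "y"))
  tab <- subgroup_table(scores, cov, "g")
  expect_equal(tab$p_value[tab$factor == "f1"], c(1, 1))
  expect_equal(tab$p_value[tab$factor == "f2"], c(0, 0))
  expect_equal(tab$mean[tab$factor == "f2"], c(0, 100))

  # singleton group: mean kept, sd and p unavailable
  cov2 <- data.frame(g = c("x", "x", "x", "y"))
  tab2 <- subgroup_table(scores, cov2, "g")
  expect_true(is.na(tab2$sd[tab2$level == "y"][1]))
  expect_true(all(is.na(tab2$p_value)))

  # continuous covariate reported as a correlation coefficient
  set.seed(2)
  age <- rnorm(200, 60, 10)
  sc <- data.frame(f1 = 50 + 2 * (age - 60) + rnorm(200, 0, 10))
  tab3 <- subgroup_table(sc, data.frame(age = age), "age")
  expect_true(tab3$estimate > 0.7)
  expect_lt(tab3$p_value, 1e-6)
})

test_that("the two-sample comparison rejects a standardized difference of 1", {
  # Monte-Carlo power oracle: d = 1 at n = 200 per group
  set.seed(77)
  rejections <- replicate(500, {
    scores <- data.frame(f = c(rnorm(200, 0), rnorm(200, 1)))
    cov <- data.frame(g = rep(c("lo", "hi"), each = 200))
    subgroup_table(scores, cov, "g")$p_value[1] < 0.05
  })
  expect_gt(mean(rejections), 0.99)
})

test_that("the descriptive layer round-trips through plain-text files", {
  cfg <- default_hcfc_truth(seed = 44, n_respondents = 120, missing_rate = 0.02)
  sim <- simulate_responses(cfg, covariates = default_hcfc_covariates())
  dir <- withr::local_tempdir()
  write_descriptives(sim$responses, cfg$spec, dir)
  scores <- utils::read.csv(file.path(dir, "scale_scores.csv"))
  expect_equal(dim(scores), c(120L, 8L))
  expect_true(all(scores >= 0 & scores <= 100, na.rm = TRUE))
  alphas <- utils::read.csv(file.path(dir, "alphas.csv"))
  expect_equal(alphas$alpha, unname(factor_alphas(sim$responses, cfg$spec)),
               tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "scores_by_sex.csv")))
  smry <- yaml::read_yaml(file.path(dir, "summary.yaml"))
  expect_equal(smry$n_respondents, 120L)
  expect_equal(smry$factors$physical$mean,
               mean(scale_scores(sim$responses, cfg$spec)$physical, na.rm = TRUE),
               tolerance = 1e-6)
})

test_that("score correlations are symmetric with unit diagonal and calibrated", {
  set.seed(10)
  ind <- data.frame(f1 = rnorm(5000), f2 = rnorm(5000))
  r_ind <- score_correlations(ind)
  expect_equal(diag(r_ind$r), c(f1 = 1, f2 = 1))
  expect_identical(r_ind$r, t(r_ind$r))
  expect_lt(abs(r_ind$r[1, 2]), 0.05)

  # true latent correlation 0.6 with light categorization noise
  set.seed(12)
  lat <- MASS::mvrnorm(2000, c(0, 0), matrix(c(1, .6, .6, 1), 2))
  noisy <- round((lat + matrix(rnorm(4000, 0, 0.3), ncol = 2)) * 2) / 2
  r06 <- score_correlations(as.data.frame(noisy))
  expect_lt(abs(r06$r[1, 2] - 0.6), 0.1)

  # too few complete pairs flags the cell
  few <- data.frame(f1 = c(1, 2, NA, NA), f2 = c(NA, NA, 1, 2))
  expect_true(is.na(score_correlations(few)$r[1, 2]))
  expect_equal(significance_stars(c(0.04, 0.009, 5e-4, 0.2)),
               c("*", "**", "***", ""))
})
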