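# per-chain scalar draw matrices for a parameter block
chain_matrix <- function(draws, block) {
  lapply(draws$chains, function(cc) {
    if (block == "phi") {
      m <- matrix(cc$phi, nrow = dim(cc$phi)[1])
      f <- dimnames(cc$phi)[[2]]
      colnames(m) <- paste("phi", rep(f, times = length(f)),
                           rep(f, each = length(f)), sep = ".")
      m
    } else if (block == "log_joint") {
      matrix(cc$log_joint, ncol = 1, dimnames = list(NULL, "log_joint"))
    } else {
      m <- cc[[block]]
      colnames(m) <- paste(block, colnames(m), sep = ".")
      m
    }
  })
}

#' Split-chain Gelman-Rubin statistic
#'
#' Splits each chain in half and compares between- and within-sequence
#' variance (the split variant detects within-chain drift even with few
#' chains). Values near 1 indicate convergence; a constant parameter
#' returns `NA`.
#'
#' @param x list of per-chain numeric vectors (or a single vector).
#' @return scalar potential-scale-reduction estimate.
#' @export
split_rhat <- function(x) {
  if (is.numeric(x)) x <- list(x)
  halves <- list()
  for (v in x) {
    n2 <- floor(length(v) / 2)
    if (n2 < 2) return(NA_real_)
    halves <- c(halves, list(v[seq_len(n2)], v[n2 + seq_len(n2)]))
  }
  n <- length(halves[[1]])
  m <- length(halves)
  mus <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(mus)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Sums per-chain effective sizes `n / (1 + 2 * sum(rho_t))` with the
#' autocorrelation sum truncated by Geyer's initial positive-sequence rule.
#'
#' @param x list of per-chain numeric vectors (or a single vector).
#' @return scalar effective sample size.
#' @export
ess_draws <- function(x) {
  if (is.numeric(x)) x <- list(x)
  ess1 <- function(v) {
    n <- length(v)
    if (n < 4 || stats::var(v) == 0) return(NA_real_)
    rho <- stats::acf(v, lag.max = min(n - 2, 500), plot = FALSE)$acf[-1]
    # Geyer: stop before the first negative sum of adjacent pairs
    npair <- floor(length(rho) / 2)
    ssum <- 0
    for (k in seq_len(npair)) {
      g <- rho[2 * k - 1] + rho[2 * k]
      if (g < 0) break
      ssum <- ssum + g
    }
    n / (1 + 2 * ssum)
  }
  sum(vapply(x, ess1, numeric(1)))
}

#' Summarize posterior draws
#'
#' Pools retained draws across chains and reports, per scalar parameter, the
#' posterior mean, sd, median, central credible interval at `level`, the
#' split-chain Gelman-Rubin statistic and the effective sample size.
#' With a single chain the Gelman-Rubin column is `NA` (split halves of the
#' one chain would still be available, but the conventional multi-chain
#' diagnostic is reported only when chains >= 2) and a notice is given.
#'
#' @param draws an `"ordcfa_draws"` object.
#' @param level credible-interval level (default 0.95).
#' @param blocks parameter blocks to include, subset of
#'   `c("lambda", "psi", "tau", "phi", "log_joint")`.
#' @return data frame with one row per scalar parameter.
#' @export
summarize_draws <- function(draws, level = 0.95,
                            blocks = c("lambda", "psi", "tau", "phi")) {
  stopifnot(inherits(draws, "ordcfa_draws"))
  if (draws$n_kept < 2) stop("need at least 2 retained draws")
  single <- length(draws$chains) == 1
  if (single) message("single chain: Gelman-Rubin diagnostic omitted")
  alpha <- (1 - level) / 2
  out <- list()
  for (b in blocks) {
    mats <- chain_matrix(draws, b)
    pooled <- do.call(rbind, mats)
    for (k in seq_len(ncol(pooled))) {
      v <- pooled[, k]
      per_chain <- lapply(mats, function(m) m[, k])
      qs <- stats::quantile(v, c(alpha, 0.5, 1 - alpha), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        parameter = colnames(pooled)[k],
        mean = mean(v), sd = stats::sd(v),
        median = qs[2], lower = qs[1], upper = qs[3],
        rhat = if (single) NA_real_ else split_rhat(per_chain),
        ess = ess_draws(per_chain),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "level") <- level
  out
}

#' Posterior tail-probability significance
#'
#' The two-sided posterior tail probability of a scalar parameter against a
#' test value: `2 * min(P(theta > t), P(theta < t))` estimated from the
#' draws — the Bayesian analogue of a two-sided p-value, comparing the test
#' value to the posterior distribution. A returned 0 means the test value
#' lies outside every draw, i.e. below the `1/n_draws` resolution.
#'
#' @param x numeric vector of posterior draws (>= 100).
#' @param test_value the value compared against the posterior (default 0).
#' @return tail probability in `[0, 1]`.
#' @examples
#' bayes_significance(rnorm(1e4, 1, 1), 0)  # about 2 * pnorm(-1) = 0.317
#' @export
bayes_significance <- function(x, test_value = 0) {
  if (length(x) < 100) stop("need at least 100 draws")
  min(1, 2 * min(mean(x > test_value), mean(x < test_value)))
}

#' Posterior factor-correlation report
#'
#' Converts every retained factor-covariance draw to a correlation matrix,
#' reports elementwise posterior means, and stars each pair by the posterior
#' tail probability of its correlation against 0 at the 0.05 / 0.01 / 0.001
#' levels.
#'
#' @param draws an `"ordcfa_draws"` object.
#' @return object of class `"factor_correlation_report"`: list with matrices
#'   `mean` (unit diagonal, symmetric), `p` and `stars`, plus the per-pair
#'   correlation draws.
#' @export
factor_correlation_report <- function(draws) {
  stopifnot(inherits(draws, "ordcfa_draws"))
  f <- draws$spec$factors$factor
  Fk <- length(f)
  corr_draws <- do.call(rbind, lapply(draws$chains, function(cc) {
    t(apply(cc$phi, 1, function(p) stats::cov2cor(matrix(p, Fk, Fk))))
  }))
  mean_r <- matrix(colMeans(corr_draws), Fk, Fk, dimnames = list(f, f))
  mean_r <- (mean_r + t(mean_r)) / 2
  diag(mean_r) <- 1
  p <- matrix(NA_real_, Fk, Fk, dimnames = list(f, f))
  for (i in seq_len(Fk)) for (j in seq_len(Fk)) {
    if (j < i) {
      p[i, j] <- p[j, i] <- bayes_significance(corr_draws[, (j - 1) * Fk + i], 0)
    }
  }
  structure(list(mean = mean_r, p = p, stars = significance_stars(p),
                 corr_draws = corr_draws),
            class = "factor_correlation_report")
}

#' @export
print.factor_correlation_report <- function(x, digits = 3, ...) {
  k <- ncol(x$mean)
  out <- matrix("", k, k, dimnames = dimnames(x$mean))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j < i) out[i, j] <- paste0(format(round(x$mean[i, j], digits)), x$stars[i, j])
    if (i == j) out[i, j] <- "1"
  }
  cat("Posterior-mean latent factor correlations\n")
  print(out[, -k, drop = FALSE], quote = FALSE)
  cat("Stars: posterior tail probability vs 0 < 0.05*, < 0.01**, < 0.001***\n")
  invisible(x)
}

#' Factor-loadings report
#'
#' Per item: posterior mean and central credible interval of the loading
#' (marker items shown as the fixed 1 without an interval); per factor: the
#' posterior mean of the factor standard deviation `sqrt(phi_ff)` (mean of
#' the per-draw square roots) and the maximal-loading item by posterior
#' mean.
#'
#' @param draws an `"ordcfa_draws"` object.
#' @param level credible-interval level.
#' @return object of class `"loadings_report"`: list with data frames
#'   `items` (item, factor, marker, mean, lower, upper) and `factors`
#'   (factor, sd, top_item).
#' @export
loadings_report <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "ordcfa_draws"))
  spec <- draws$spec
  alpha <- (1 - level) / 2
  lam <- do.call(rbind, lapply(draws$chains, `[[`, "lambda"))
  marker <- is_marker(spec)
  items <- data.frame(
    item = spec$items$item,
    factor = spec$items$factor,
    marker = unname(marker),
    mean = colMeans(lam),
    lower = apply(lam, 2, stats::quantile, alpha),
    upper = apply(lam, 2, stats::quantile, 1 - alpha),
    stringsAsFactors = FALSE, row.names = NULL
  )
  items$lower[items$marker] <- NA_real_
  items$upper[items$marker] <- NA_real_
  Fk <- n_factors(spec)
  phi_draws <- do.call(rbind, lapply(draws$chains, function(cc) {
    matrix(cc$phi, nrow = dim(cc$phi)[1])
  }))
  diag_idx <- (seq_len(Fk) - 1) * Fk + seq_len(Fk)
  fsd <- colMeans(sqrt(phi_draws[, diag_idx, drop = FALSE]))
  top <- vapply(spec$factors$factor, function(f) {
    it <- items[items$factor == f, ]
    it$item[which.max(it$mean)]
  }, character(1))
  factors <- data.frame(factor = spec$factors$factor, sd = unname(fsd),
                        top_item = unname(top), stringsAsFactors = FALSE)
  structure(list(items = items, factors = factors, level = level),
            class = "loadings_report")
}

#' @export
print.loadings_report <- function(x, digits = 2, ...) {
  cat(sprintf("Posterior factor loadings (%d%% credible intervals)\n",
              round(100 * x$level)))
  for (f in x$factors$factor) {
    fr <- x$factors[x$factors$factor == f, ]
    cat(sprintf("%s (factor sd %.2f):\n", f, fr$sd))
    it <- x$items[x$items$factor == f, ]
    for (k in seq_len(nrow(it))) {
      if (it$marker[k]) {
        cat(sprintf("  %-24s 1.00 (fixed)\n", it$item[k]))
      } else {
        cat(sprintf("  %-24s %.2f [%.2f, %.2f]%s\n", it$item[k], it$mean[k],
                    it$lower[k], it$upper[k],
                    if (it$item[k] == fr$top_item) "  <- max" else ""))
      }
    }
  }
  invisible(x)
}
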