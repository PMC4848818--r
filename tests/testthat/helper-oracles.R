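# independent grid/quadrature posterior for the 1-factor, 2-item, 2-category
# model with fixed thresholds: the latent factor is integrated out by
# Gauss-Hermite quadrature on each grid point of (free loading, factor
# variance); priors are N(0, loading_sd^2) on the loading and the 1-D
# Wishart(df 10, scale 1) on the precision (an inverse-gamma(5, 1/2) on the
# variance). Deliberately independent of the sampler: direct numerics only.
grid_binary_posterior <- function(y, tau, loading_sd,
                                  lams = seq(-4, 8, length.out = 161),
                                  phis = exp(seq(log(0.03), log(20),
                                                 length.out = 101)),
                                  gh_n = 81) {
  gh <- pracma::gaussHermite(gh_n)
  pat <- table(factor(y[, 1], 1:2), factor(y[, 2], 1:2))
  loglik <- function(lam2, phi) {
    nodes <- sqrt(2 * phi) * gh$x
    w <- gh$w / sqrt(pi)
    ll <- 0
    for (c1 in 1:2) for (c2 in 1:2) {
      if (pat[c1, c2] == 0) next
      p1 <- if (c1 == 1) pnorm(tau[1] - nodes) else
        pnorm(tau[1] - nodes, lower.tail = FALSE)
      p2 <- if (c2 == 1) pnorm(tau[2] - lam2 * nodes) else
        pnorm(tau[2] - lam2 * nodes, lower.tail = FALSE)
      ll <- ll + pat[c1, c2] * log(sum(w * p1 * p2))
    }
    ll
  }
  lp <- matrix(NA_real_, length(lams), length(phis))
  for (i in seq_along(lams)) for (k in seq_along(phis)) {
    lp[i, k] <- loglik(lams[i], phis[k]) +
      dnorm(lams[i], 0, loading_sd, log = TRUE) +
      dgamma(1 / phis[k], shape = 5, rate = 0.5, log = TRUE) - 2 * log(phis[k])
  }
  # log-spaced phi grid: include the d(phi) jacobian
  w2 <- exp(lp - max(lp)) * matrix(rep(phis, each = length(lams)),
                                   length(lams))
  pl <- rowSums(w2); pl <- pl / sum(pl)
  pp <- colSums(w2); pp <- pp / sum(pp)
  m <- sum(lams * pl)
  list(mean_lambda = m,
       sd_lambda = sqrt(sum((lams - m)^2 * pl)),
       mean_phi = sum(phis * pp))
}

# pooled draws of one scalar parameter across chains
pool_draws <- function(draws, block, column) {
  unlist(lapply(draws$chains, function(cc) {
    if (block == "phi") cc$phi[, column[1], column[2]] else cc[[block]][, column]
  }))
}
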