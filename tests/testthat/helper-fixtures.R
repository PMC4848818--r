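# small instruments and data builders shared across tests

tiny_instrument <- function(n_categories = 2) {
  instrument(data.frame(item = c("a", "b"), factor = "f1"),
             n_categories = n_categories)
}

two_factor_instrument <- function(n_categories = 5) {
  instrument(data.frame(
    item = c("a1", "a2", "a3", "b1", "b2"),
    factor = c("fa", "fa", "fa", "fb", "fb"),
    reversed = c(FALSE, TRUE, FALSE, FALSE, FALSE)
  ), n_categories = n_categories)
}

# 1-factor 2-item binary ordinal-probit data (item "a" is the marker)
binary_sim <- function(n, lam2 = 1.5, phi = 1, tau = c(0.2, 0.3), seed = 11) {
  set.seed(seed)
  eta <- rnorm(n, 0, sqrt(phi))
  z <- cbind(eta + rnorm(n), lam2 * eta + rnorm(n))
  y <- cbind(a = (z[, 1] > tau[1]) + 1L, b = (z[, 2] > tau[2]) + 1L)
  list(rt = response_table(y, tiny_instrument()), eta = eta, z = z)
}

# minimal hand-built draws container for posterior-layer tests
make_draws <- function(lambda_chains, spec = tiny_instrument(),
                       phi_chains = NULL, n_factors_override = NULL) {
  Fk <- if (is.null(n_factors_override)) n_factors(spec) else n_factors_override
  chains <- lapply(seq_along(lambda_chains), function(i) {
    lam <- lambda_chains[[i]]
    nk <- nrow(lam)
    phi <- if (is.null(phi_chains)) {
      array(rep(diag(Fk), each = nk), c(nk, Fk, Fk),
            dimnames = list(NULL, spec$factors$factor, spec$factors$factor))
    } else phi_chains[[i]]
    list(lambda = lam,
         psi = matrix(1, nk, ncol(lam), dimnames = list(NULL, colnames(lam))),
         tau = matrix(0, nk, ncol(lam) * (spec$n_categories - 1)),
         phi = phi,
         log_joint = rep(0, nk))
  })
  structure(list(chains = chains, spec = spec,
                 config = chain_config(n_iterations = 2, burn_in = 1,
                                       n_chains = length(chains)),
                 n_kept = nrow(lambda_chains[[1]]),
                 threshold_acceptance = rep(NA_real_, length(chains))),
            class = "ordcfa_draws")
}
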