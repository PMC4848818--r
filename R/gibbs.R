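#' Tail-safe truncated-normal sampling by inverse CDF
#'
#' Draws from `N(mean, sd^2)` truncated to `(lower, upper]` using the
#' inverse-CDF method on log CDF values, with reflection into the left tail
#' so that extreme truncation regions (e.g. beyond 8 standard deviations) do
#' not underflow. Vectorized over all arguments; infinite bounds give the
#' untruncated normal.
#'
#' @param n number of draws.
#' @param mean,sd location and scale (recycled).
#' @param lower,upper truncation bounds (recycled; `-Inf`/`Inf` allowed).
#' @return numeric vector of `n` draws inside the bounds.
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(lower > upper)) stop("lower bound exceeds upper bound")
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  flip <- a > -b          # work in the left tail; a=-Inf,b=Inf gives FALSE
  flip[is.na(flip)] <- FALSE
  aa <- a; bb <- b
  aa[flip] <- -b[flip]
  bb[flip] <- -a[flip]
  lpa <- stats::pnorm(aa, log.p = TRUE)
  lpb <- stats::pnorm(bb, log.p = TRUE)
  u <- stats::runif(n)
  # log(pa + u * (pb - pa)) = lpb + log1p(-(1 - u) * (1 - exp(lpa - lpb)))
  logp <- lpb + log1p(-(1 - u) * (-expm1(lpa - lpb)))
  x <- stats::qnorm(logp, log.p = TRUE)
  x[flip] <- -x[flip]
  # degenerate intervals collapse to the bound
  deg <- lower == upper
  out <- mean + sd * x
  out[deg] <- lower[deg]
  out
}

# log(Phi(b) - Phi(a)) for a < b, stable in both tails
log_pnorm_interval <- function(a, b) {
  flip <- (a + b) > 0
  flip[is.na(flip)] <- FALSE
  aa <- a; bb <- b
  aa[flip] <- -b[flip]
  bb[flip] <- -a[flip]
  lpb <- stats::pnorm(bb, log.p = TRUE)
  lpa <- stats::pnorm(aa, log.p = TRUE)
  lpb + log1p(-exp(lpa - lpb))
}

#' Data-augmentation update of the latent item responses
#'
#' For every observed cell, draws the latent response from its full
#' conditional: `N(lambda_j * eta_{i,f(j)}, psi_j)` truncated to the bracket
#' `(tau_{j,y-1}, tau_{j,y}]` of the observed category. Missing cells are
#' imputed from the same normal without truncation (the data-augmentation
#' treatment of missingness).
#'
#' @param model an `"ordcfa_model"`.
#' @param x the `"response_table"`.
#' @return the model with updated `z`.
#' @export
update_latent_mlv <- function(model, x) {
  x <- recode_responses(x, model$spec)
  y <- x$responses
  n <- nrow(y); J <- ncol(y)
  K <- model$spec$n_categories
  tauext <- cbind(-Inf, model$tau, Inf)
  jj <- rep(seq_len(J), each = n)
  yy <- as.vector(y)
  miss <- is.na(yy)
  yy[miss] <- 1L
  lo <- tauext[cbind(jj, yy)]
  hi <- tauext[cbind(jj, yy + 1L)]
  lo[miss] <- -Inf
  hi[miss] <- Inf
  mu <- as.vector(model$eta[, model$item_factor, drop = FALSE] *
                    matrix(model$lambda, n, J, byrow = TRUE))
  sdv <- rep(sqrt(model$psi), each = n)
  model$z <- matrix(rtruncnorm(n * J, mu, sdv, lo, hi), n, J,
                    dimnames = dimnames(model$z))
  model
}

#' Gibbs update of the latent factors
#'
#' Per respondent, draws the factor vector from its exact Gaussian full
#' conditional with precision `solve(Phi) + t(Lambda) Psi^-1 Lambda` and the
#' standard normal-normal mean, using the complete (augmented) latent
#' responses. The precision is shared across respondents, so a single
#' Cholesky factor serves all draws.
#'
#' @param model an `"ordcfa_model"`.
#' @return the model with updated `eta`.
#' @export
update_factors <- function(model) {
  n <- nrow(model$z)
  J <- length(model$lambda); Fk <- ncol(model$phi)
  Lam <- matrix(0, J, Fk)
  Lam[cbind(seq_len(J), model$item_factor)] <- model$lambda
  PsiInvLam <- Lam / model$psi
  A <- chol2inv(chol(model$phi)) + crossprod(Lam, PsiInvLam)
  A <- (A + t(A)) / 2
  R <- tryCatch(chol(A), error = function(e) {
    stop("singular factor full-conditional precision: ", conditionMessage(e))
  })
  M <- model$z %*% PsiInvLam            # n x F right-hand sides
  M <- t(backsolve(R, forwardsolve(t(R), t(M))))  # A^{-1} t(M)
  U <- matrix(stats::rnorm(n * Fk), Fk, n)
  model$eta <- M + t(backsolve(R, U))
  colnames(model$eta) <- model$spec$factors$factor
  model
}

#' Conjugate update of the free factor loadings
#'
#' Per non-marker item, draws the loading from the normal full conditional
#' combining the diffuse `N(0, loading_var)` prior with the regression of
#' the item's latent responses on its factor. Marker loadings stay fixed at
#' 1. An item whose factor shows zero variance across respondents keeps a
#' prior draw with a warning.
#'
#' @param model an `"ordcfa_model"`.
#' @return the model with updated `lambda`.
#' @export
update_loadings <- function(model) {
  v0 <- model$prior$loading_var
  for (j in which(!model$marker)) {
    xf <- model$eta[, model$item_factor[j]]
    sxx <- sum(xf^2)
    if (sxx == 0) {
      warning("factor of item '", names(model$lambda)[j],
              "' has zero variance; loading drawn from its prior")
      model$lambda[j] <- stats::rnorm(1, model$prior$loading_mean, sqrt(v0))
      next
    }
    prec <- 1 / v0 + sxx / model$psi[j]
    mu <- (model$prior$loading_mean / v0 +
             sum(xf * model$z[, j]) / model$psi[j]) / prec
    model$lambda[j] <- stats::rnorm(1, mu, sqrt(1 / prec))
  }
  model
}

#' Update of the latent-response residual variances (anchored mode)
#'
#' Draws each residual variance from its full conditional under the flat
#' `Uniform(0, psi_upper)` prior: an inverse-gamma kernel with shape
#' `n/2 - 1` and rate `SS/2` truncated to `(0, psi_upper)`, sampled by
#' inverse CDF on the precision scale. In `"probit"` mode this is the
#' identity (residual variances stay fixed at 1).
#'
#' @param model an `"ordcfa_model"`.
#' @return the model with updated `psi`.
#' @export
update_residual_variances <- function(model) {
  if (model$mode == "probit") return(model)
  n <- nrow(model$z)
  upper <- model$prior$psi_upper
  mu <- model$eta[, model$item_factor, drop = FALSE] *
    matrix(model$lambda, n, length(model$lambda), byrow = TRUE)
  SS <- colSums((model$z - mu)^2)
  shape <- n / 2 - 1
  if (shape <= 0) stop("too few respondents to update residual variances")
  for (j in seq_along(model$psi)) {
    if (SS[j] <= 0) {
      warning("zero residual sum of squares for item '",
              names(model$psi)[j], "'; variance floored")
      model$psi[j] <- 1e-8
      next
    }
    # precision theta = 1/psi ~ Gamma(shape, rate = SS/2) truncated to theta > 1/upper
    plo <- stats::pgamma(1 / upper, shape, rate = SS[j] / 2)
    u <- stats::runif(1, plo, 1)
    model$psi[j] <- 1 / stats::qgamma(u, shape, rate = SS[j] / 2)
  }
  model
}

#' Conjugate Wishart update of the factor covariance
#'
#' Draws the factor precision from
#' `Wishart(df0 + n, solve(solve(S0) + crossprod(eta)))` where the prior is
#' `Wishart(df0, S0)` with `S0 = I/df0` (prior expectation of the precision
#' equal to the identity), and inverts it to the covariance. The draw is
#' re-symmetrized; a non-positive-definite result raises an error.
#'
#' @param model an `"ordcfa_model"`.
#' @return the model with updated `phi`.
#' @export
update_factor_cov <- function(model) {
  n <- nrow(model$eta)
  S0inv <- solve(model$prior$wishart_scale)
  Spost <- S0inv + crossprod(model$eta)
  Spost <- (Spost + t(Spost)) / 2
  scale <- chol2inv(chol(Spost))
  P <- stats::rWishart(1, df = model$prior$wishart_df + n, Sigma = scale)[, , 1]
  P <- (P + t(P)) / 2
  phi <- tryCatch(chol2inv(chol(P)), error = function(e) NULL)
  if (is.null(phi)) stop("factor precision draw not positive definite")
  phi <- (phi + t(phi)) / 2
  dimnames(phi) <- dimnames(model$phi)
  model$phi <- phi
  model
}

# indices of the free (sampled) cuts for the current identification mode
free_cuts <- function(model) {
  K <- model$spec$n_categories
  setdiff(seq_len(K - 1L), model$tau_anchor)
}

#' Collapsed per-item scale move for thresholds and loading
#'
#' Jointly rescales an item's cut-point vector and (for non-marker items)
#' its loading by `c = exp(eps)`, `eps ~ N(0, prop_sd^2)`, with both the
#' item's latent responses and the latent factors integrated out:
#' conditional on the *other* items' latent responses, the item's latent
#' response is Gaussian with closed-form moments
#' (`mean = lambda_j * mu_i`, `var = lambda_j^2 * v + psi_j`, where `mu_i`
#' and `v` are the leave-one-item-out factor posterior moments), so the
#' acceptance ratio is the observed ordinal-probit likelihood ratio times
#' the loading prior ratio and the multiplicative-move Jacobian `c^d`
#' (`d` = number of scaled parameters). Collapsing the factors breaks the
#' feedback between a large loading and factors inferred from that same
#' item, which otherwise traps chains on the loading/threshold scale ridge.
#' On acceptance the item's latent responses are re-imputed from their
#' collapsed conditional. The factors must be redrawn
#' ([update_factors()]) before any later update conditions on them;
#' [fit_ordcfa()] orders the sweep accordingly. Skipped when thresholds are
#' anchored (`"anchored"` mode leaves no free per-item scale).
#'
#' @param model an `"ordcfa_model"`.
#' @param x the `"response_table"`.
#' @param prop_sd proposal standard deviation on the log scale.
#' @return the model with possibly rescaled `tau` rows, `lambda` and
#'   refreshed `z` columns.
#' @export
update_item_scales <- function(model, x, prop_sd = 0.05) {
  x <- recode_responses(x, model$spec)
  y <- x$responses
  bound <- model$prior$threshold_bound
  if (length(model$tau_anchor)) return(model)   # anchored cuts: no free scale
  if (is.null(model$scale_accept)) {
    model$scale_accept <- c(accepted = 0, proposed = 0)
  }
  n <- nrow(y); J <- ncol(y); Fk <- ncol(model$phi)
  K <- model$spec$n_categories
  Lam <- matrix(0, J, Fk)
  Lam[cbind(seq_len(J), model$item_factor)] <- model$lambda
  A <- chol2inv(chol(model$phi)) + crossprod(Lam, Lam / model$psi)
  M <- model$z %*% (Lam / model$psi)          # n x F working sums
  for (j in seq_len(J)) {
    f <- model$item_factor[j]
    lam_old <- model$lambda[j]; psij <- model$psi[j]
    # mixture proposal: occasional wide steps keep the heavy upper ridge
    # traversable instead of quasi-absorbing (the mixture is fixed, so the
    # proposal stays symmetric in eps)
    wide <- stats::runif(1) < 0.1
    eps <- stats::rnorm(1, 0, if (wide) 10 * prop_sd else prop_sd)
    cc <- exp(eps)
    model$scale_accept["proposed"] <- model$scale_accept["proposed"] + 1
    tau_new <- model$tau[j, ] * cc
    if (max(abs(tau_new)) >= bound) next
    scale_lambda <- !model$marker[j]
    lam_new <- if (scale_lambda) lam_old * cc else lam_old
    # leave-one-item-out factor posterior moments
    Aj <- A
    Aj[f, f] <- Aj[f, f] - lam_old^2 / psij
    Ainv_col <- tryCatch(solve(Aj)[, f], error = function(e) NULL)
    if (is.null(Ainv_col)) next
    Mj_f <- M[, f] - model$z[, j] * (lam_old / psij)
    Mj <- M; Mj[, f] <- Mj_f
    mu <- as.numeric(Mj %*% Ainv_col)
    v <- Ainv_col[f]
    yj <- y[, j]
    obs <- which(!is.na(yj))
    te_old <- c(-Inf, model$tau[j, ], Inf)
    te_new <- c(-Inf, tau_new, Inf)
    sd_old <- sqrt(lam_old^2 * v + psij)
    sd_new <- sqrt(lam_new^2 * v + psij)
    mo <- lam_old * mu[obs]; mn <- lam_new * mu[obs]
    yo <- yj[obs]
    ll_old <- sum(log_pnorm_interval((te_old[yo] - mo) / sd_old,
                                     (te_old[yo + 1L] - mo) / sd_old))
    ll_new <- sum(log_pnorm_interval((te_new[yo] - mn) / sd_new,
                                     (te_new[yo + 1L] - mn) / sd_new))
    d <- length(tau_new) + as.integer(scale_lambda)
    lr <- ll_new - ll_old + d * eps
    if (scale_lambda) {
      lr <- lr +
        stats::dnorm(lam_new, model$prior$loading_mean,
                     sqrt(model$prior$loading_var), log = TRUE) -
        stats::dnorm(lam_old, model$prior$loading_mean,
                     sqrt(model$prior$loading_var), log = TRUE)
    }
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      model$tau[j, ] <- tau_new
      model$lambda[j] <- lam_new
      model$scale_accept["accepted"] <- model$scale_accept["accepted"] + 1
      # re-impute the item's latent responses from the collapsed conditional
      yj2 <- ifelse(is.na(yj), 1L, yj)
      lo <- te_new[yj2]; hi <- te_new[yj2 + 1L]
      lo[is.na(yj)] <- -Inf; hi[is.na(yj)] <- Inf
      znew <- rtruncnorm(n, lam_new * mu, sd_new, lo, hi)
      model$z[, j] <- znew
      # refresh the working sums for the next items
      A[f, f] <- Aj[f, f] + lam_new^2 / psij
      M[, f] <- Mj_f + znew * (lam_new / psij)
    }
  }
  model
}

#' Metropolis-Hastings update of the thresholds
#'
#' Single-cut random-walk proposals with the item's latent responses
#' collapsed out: the acceptance ratio is the product of ordinal-probit
#' cell-probability ratios over the observed cells of the two adjacent
#' categories. This collapsed move traverses the threshold posterior in O(1)
#' steps per iteration where the latent-conditional uniform step moves only
#' O(1/n). Because the move marginalizes the latent responses, it must be
#' followed by [update_latent_mlv()] before any update conditions on them
#' again; [fit_ordcfa()] orders the sweep accordingly. The ordered-region
#' constraint (and the prior support box) is enforced by rejection. In
#' `"anchored"` mode each item's first and last interior cuts are anchored and
#' skipped. Acceptance counts are accumulated on the model.
#'
#' @param model an `"ordcfa_model"`.
#' @param x the `"response_table"`.
#' @param prop_sd random-walk proposal standard deviation.
#' @return the model with updated `tau` (and `z` on accepted moves).
#' @export
update_thresholds <- function(model, x, prop_sd = 0.1) {
  x <- recode_responses(x, model$spec)
  y <- x$responses
  K <- model$spec$n_categories
  bound <- model$prior$threshold_bound
  cuts <- free_cuts(model)
  if (is.null(model$mh_accept)) {
    model$mh_accept <- c(accepted = 0, proposed = 0)
  }
  if (is.null(model$cat_idx)) {
    # observed-cell indices per item and category never change over the run
    model$cat_idx <- lapply(seq_len(ncol(y)), function(j) {
      lapply(seq_len(K), function(c) which(!is.na(y[, j]) & y[, j] == c))
    })
  }
  for (j in seq_len(ncol(y))) {
    muj <- model$lambda[j] * model$eta[, model$item_factor[j]]
    sdj <- sqrt(model$psi[j])
    for (c in cuts) {
      tau_c <- model$tau[j, c]
      lo_nb <- if (c == 1) -bound else model$tau[j, c - 1]
      hi_nb <- if (c == K - 1) bound else model$tau[j, c + 1]
      prop <- tau_c + stats::rnorm(1, 0, prop_sd)
      model$mh_accept["proposed"] <- model$mh_accept["proposed"] + 1
      if (prop <= lo_nb || prop >= hi_nb) next
      in_lo <- model$cat_idx[[j]][[c]]        # category below the cut
      in_hi <- model$cat_idx[[j]][[c + 1L]]   # category above the cut
      lr <- 0
      if (length(in_lo)) {
        a <- (if (c == 1) -Inf else model$tau[j, c - 1])
        lr <- lr + sum(log_pnorm_interval((a - muj[in_lo]) / sdj,
                                          (prop - muj[in_lo]) / sdj) -
                       log_pnorm_interval((a - muj[in_lo]) / sdj,
                                          (tau_c - muj[in_lo]) / sdj))
      }
      if (length(in_hi)) {
        b <- (if (c == K - 1) Inf else model$tau[j, c + 1])
        lr <- lr + sum(log_pnorm_interval((prop - muj[in_hi]) / sdj,
                                          (b - muj[in_hi]) / sdj) -
                       log_pnorm_interval((tau_c - muj[in_hi]) / sdj,
                                          (b - muj[in_hi]) / sdj))
      }
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        model$tau[j, c] <- prop
        model$mh_accept["accepted"] <- model$mh_accept["accepted"] + 1
      }
    }
  }
  model
}

#' Configure an MCMC run
#'
#' @param n_iterations sweeps per chain.
#' @param burn_in discarded initial sweeps (`< n_iterations`).
#' @param thinning keep every `thinning`-th post-burn-in state.
#' @param n_chains number of independent chains.
#' @param seed root seed; each chain uses a seed derived deterministically
#'   from it.
#' @param mode identification mode, `"probit"` (residual variances fixed at
#'   1, all thresholds free; the default) or `"anchored"` (residual variances
#'   free on `(0, 100)`, outer interior cuts anchored).
#' @param sample_thresholds sample thresholds (`TRUE`) or keep them fixed at
#'   their frequency-based initial values (`FALSE`).
#' @param threshold_prop_sd random-walk proposal sd for single-cut moves.
#' @param scale_prop_sd log-scale proposal sd for the per-item scale move.
#' @return list of class `"chain_config"`.
#' @export
chain_config <- function(n_iterations = 10000, burn_in = 5000, thinning = 1,
                         n_chains = 2, seed = 1L,
                         mode = c("probit", "anchored"),
                         sample_thresholds = TRUE, threshold_prop_sd = 0.1,
                         scale_prop_sd = 0.05) {
  mode <- match.arg(mode)
  if (burn_in >= n_iterations) stop("burn_in must be < n_iterations")
  if (thinning < 1) stop("thinning must be >= 1")
  if (n_chains < 1) stop("n_chains must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 mode = mode, sample_thresholds = sample_thresholds,
                 threshold_prop_sd = threshold_prop_sd,
                 scale_prop_sd = scale_prop_sd),
            class = "chain_config")
}

#' Fit the Bayesian ordinal CFA by Gibbs sampling
#'
#' Runs the data-augmentation Gibbs sampler: thresholds (optional,
#' collapsed move), latent responses, factors, loadings, residual variances
#' (`"anchored"` mode only), factor covariance, in that fixed sweep order, for
#' each chain;
#' retains thinned post-burn-in states of the loadings, residual variances,
#' thresholds, factor covariance and the complete-data log joint.
#' Reproducible from `config$seed`.
#'
#' @param x a `"response_table"`.
#' @param spec an `"instrument"` object.
#' @param config a `"chain_config"`.
#' @param prior a `"prior_spec"`. The default depends on the identification
#'   mode: `"anchored"` mode uses the literal diffuse priors (loading variance
#'   `1e6`), which its anchored cuts make harmless; probit mode with sampled
#'   thresholds uses a weakly informative `N(0, 25)` loading prior, because
#'   with free thresholds the observed likelihood flattens to a positive
#'   constant in each loading and under a flat prior the posterior mean of a
#'   high-communality loading diverges (see the methods vignette).
#' @return an object of class `"ordcfa_draws"`: list with `chains` (per
#'   chain: matrices `lambda`, `psi`, `tau`, array `phi`, vector
#'   `log_joint`), `spec`, `config`, `n_kept` and per-chain threshold
#'   acceptance rates.
#' @export
fit_ordcfa <- function(x, spec, config = chain_config(), prior = NULL) {
  stopifnot(inherits(x, "response_table"))
  validate_instrument(spec)
  x <- recode_responses(x, spec)   # the latent model lives on the recoded scale
  J <- n_items(spec); K <- spec$n_categories; Fk <- n_factors(spec)
  if (is.null(prior)) {
    prior <- if (config$mode == "probit" && config$sample_thresholds) {
      prior_spec(Fk, loading_var = 25)
    } else {
      prior_spec(Fk)
    }
  }
  kept <- floor((config$n_iterations - config$burn_in) / config$thinning)
  tau_names <- paste(rep(spec$items$item, each = K - 1),
                     rep(seq_len(K - 1), J), sep = ".")
  chains <- vector("list", config$n_chains)
  accept <- numeric(config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 1000003L * (ch - 1L))
    model <- init_model(x, spec, mode = config$mode, prior = prior)
    lam <- matrix(NA_real_, kept, J, dimnames = list(NULL, spec$items$item))
    psi <- matrix(NA_real_, kept, J, dimnames = list(NULL, spec$items$item))
    tau <- matrix(NA_real_, kept, J * (K - 1), dimnames = list(NULL, tau_names))
    phi <- array(NA_real_, c(kept, Fk, Fk),
                 dimnames = list(NULL, spec$factors$factor, spec$factors$factor))
    lj <- numeric(kept)
    s <- 0L
    for (it in seq_len(config$n_iterations)) {
      model <- tryCatch({
        # partially collapsed sweep: the scale moves marginalize the factors,
        # so the factors are redrawn immediately after; the single-cut moves
        # marginalize the latent responses, so those are redrawn before any
        # later update conditions on them
        m <- model
        if (config$sample_thresholds) {
          m <- update_item_scales(m, x, config$scale_prop_sd)
        }
        m <- update_factors(m)
        if (config$sample_thresholds) {
          m <- update_thresholds(m, x, config$threshold_prop_sd)
        }
        m <- update_latent_mlv(m, x)
        m <- update_loadings(m)
        if (config$mode == "anchored") m <- update_residual_variances(m)
        m <- update_factor_cov(m)
        m
      }, error = function(e) {
        stop("chain ", ch, " failed at iteration ", it, ": ",
             conditionMessage(e), call. = FALSE)
      })
      if (it > config$burn_in &&
          (it - config$burn_in) %% config$thinning == 0L) {
        s <- s + 1L
        lam[s, ] <- model$lambda
        psi[s, ] <- model$psi
        tau[s, ] <- as.vector(t(model$tau))
        phi[s, , ] <- model$phi
        lj[s] <- log_joint(model, x)
      }
    }
    acc <- model$mh_accept
    accept[ch] <- if (!is.null(acc) && acc["proposed"] > 0) {
      unname(acc["accepted"] / acc["proposed"])
    } else NA_real_
    chains[[ch]] <- list(lambda = lam, psi = psi, tau = tau, phi = phi,
                         log_joint = lj)
  }
  structure(list(chains = chains, spec = spec, config = config,
                 n_kept = kept, threshold_acceptance = accept),
            class = "ordcfa_draws")
}

#' @export
print.ordcfa_draws <- function(x, ...) {
  cat(sprintf("<ordcfa_draws> %d chain(s) x %d retained draws (%s mode, seed %d)\n",
              length(x$chains), x$n_kept, x$config$mode, x$config$seed))
  if (x$config$sample_thresholds) {
    cat("  threshold MH acceptance:",
        paste(sprintf("%.2f", x$threshold_acceptance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read posterior draws as columnar delimited text
#'
#' One CSV per chain (columns `lambda.<item>`, `psi.<item>`,
#' `tau.<item>.<cut>`, `phi.<f1>.<f2>`, `log_joint`; one row per retained
#' draw), plus `instrument.yaml` and `metadata.yaml` carrying the chain
#' configuration and provenance. `read_draws(write_draws(d, dir))`
#' round-trips the draws.
#'
#' @param draws an `"ordcfa_draws"` object.
#' @param dir output directory.
#' @return `write_draws` returns `dir` invisibly; `read_draws` an
#'   `"ordcfa_draws"`.
#' @export
write_draws <- function(draws, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- draws$spec
  Fk <- n_factors(spec)
  for (ch in seq_along(draws$chains)) {
    cc <- draws$chains[[ch]]
    phi_flat <- matrix(cc$phi, nrow = dim(cc$phi)[1])
    colnames(phi_flat) <- paste("phi",
                                rep(spec$factors$factor, times = Fk),
                                rep(spec$factors$factor, each = Fk), sep = ".")
    df <- data.frame(
      stats::setNames(as.data.frame(cc$lambda), paste0("lambda.", colnames(cc$lambda))),
      stats::setNames(as.data.frame(cc$psi), paste0("psi.", colnames(cc$psi))),
      stats::setNames(as.data.frame(cc$tau), paste0("tau.", colnames(cc$tau))),
      as.data.frame(phi_flat),
      log_joint = cc$log_joint,
      check.names = FALSE
    )
    utils::write.csv(df, file.path(dir, sprintf("chain%d.csv", ch)),
                     row.names = FALSE)
  }
  write_instrument(spec, file.path(dir, "instrument.yaml"))
  yaml::write_yaml(c(unclass(draws$config),
                     list(n_kept = draws$n_kept,
                          threshold_acceptance = draws$threshold_acceptance)),
                   file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' @rdname write_draws
#' @export
read_draws <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  spec <- read_instrument(file.path(dir, "instrument.yaml"))
  J <- n_items(spec); K <- spec$n_categories; Fk <- n_factors(spec)
  chains <- list()
  ch <- 1L
  while (file.exists(file.path(dir, sprintf("chain%d.csv", ch)))) {
    df <- utils::read.csv(file.path(dir, sprintf("chain%d.csv", ch)),
                          check.names = FALSE)
    pick <- function(prefix) {
      m <- as.matrix(df[startsWith(names(df), prefix)])
      colnames(m) <- sub(prefix, "", colnames(m), fixed = TRUE)
      m
    }
    phi_flat <- pick("phi.")
    phi <- array(phi_flat, c(nrow(df), Fk, Fk),
                 dimnames = list(NULL, spec$factors$factor, spec$factors$factor))
    chains[[ch]] <- list(lambda = pick("lambda."), psi = pick("psi."),
                         tau = pick("tau."), phi = phi,
                         log_joint = df$log_joint)
    ch <- ch + 1L
  }
  cfg <- chain_config(meta$n_iterations, meta$burn_in, meta$thinning,
                      meta$n_chains, meta$seed, meta$mode,
                      meta$sample_thresholds, meta$threshold_prop_sd)
  structure(list(chains = chains, spec = spec, config = cfg,
                 n_kept = meta$n_kept,
                 threshold_acceptance = unlist(meta$threshold_acceptance)),
            class = "ordcfa_draws")
}
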