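#' Prior specification for the ordinal CFA
#'
#' The diffuse priors of the model: `N(0, 1e6)` on free factor loadings,
#' `Uniform(0, 100)` on latent-response residual variances (sampled only in
#' the `"anchored"` identification mode), a `Wishart(df = 10, scale = I)` prior
#' on the factor precision matrix — the BUGS `dwish(I, 10)` convention,
#' under which the prior expectation of the factor covariance is exactly the
#' identity at 8 factors — and a flat prior on the ordered threshold region
#' intersected with `[-threshold_bound, threshold_bound]` (the box keeps the
#' conditional proper when a response category is empty).
#'
#' @param n_factors dimension of the factor covariance.
#' @param loading_var prior variance of free loadings.
#' @param psi_upper upper bound of the uniform residual-variance prior.
#' @param wishart_df Wishart degrees of freedom (must be >= `n_factors`).
#' @param threshold_bound half-width of the threshold support box.
#' @return list of class `"prior_spec"`.
#' @export
prior_spec <- function(n_factors, loading_var = 1e6, psi_upper = 100,
                       wishart_df = 10, threshold_bound = 30) {
  if (wishart_df < n_factors) {
    stop("Wishart degrees of freedom (", wishart_df,
         ") must be >= the number of factors (", n_factors, ")")
  }
  structure(list(loading_mean = 0, loading_var = loading_var,
                 psi_upper = psi_upper, wishart_df = wishart_df,
                 wishart_scale = diag(n_factors),
                 threshold_bound = threshold_bound),
            class = "prior_spec")
}

#' Initialize thresholds from empirical category frequencies
#'
#' Sets each item's cut-points at the standard-normal quantiles of the
#' cumulative category frequencies (treating the latent response as standard
#' normal). Cumulative frequencies are clipped away from 0 and 1 and
#' adjacent cuts separated by `eps` when cumulative frequencies coincide, so
#' the cuts are strictly increasing even with empty interior categories.
#'
#' @param freqs `n_items x n_categories` matrix of category frequencies
#'   (rows sum to 1), e.g. from [category_frequencies()].
#' @param eps minimal separation between adjacent cuts.
#' @return `n_items x (n_categories - 1)` matrix of strictly increasing
#'   cut-points.
#' @examples
#' init_thresholds(matrix(rep(0.2, 5), 1))  # qnorm(c(.2, .4, .6, .8))
#' @export
init_thresholds <- function(freqs, eps = 1e-3) {
  freqs <- as.matrix(freqs)
  K <- ncol(freqs)
  if (K < 2) stop("need at least 2 categories")
  one_cat <- apply(freqs, 1, function(f) any(!is.na(f) & f >= 1 - 1e-12))
  if (any(one_cat)) {
    stop("item(s) with all responses in a single category: ",
         paste(rownames(freqs)[one_cat], collapse = ", "),
         "; merge categories before fitting")
  }
  out <- apply(freqs, 1, function(f) {
    cum <- pmin(pmax(cumsum(f)[-K], 5e-4), 1 - 5e-4)
    tau <- stats::qnorm(cum)
    for (c in seq_along(tau)[-1]) {
      if (tau[c] <= tau[c - 1] + eps) tau[c] <- tau[c - 1] + eps
    }
    tau
  })
  # apply() collapses the single-cut case to a vector; keep items as rows
  if (is.matrix(out)) t(out) else matrix(out, ncol = 1,
                                         dimnames = list(rownames(freqs), NULL))
}

#' Initialize the ordinal CFA model state
#'
#' Builds the starting state of the sampler: thresholds from
#' [init_thresholds()] on the observed frequencies, all loadings 1, residual
#' variances 1, identity factor covariance, zero factors, and latent
#' responses at the mid-point of their observed category's bracket (extreme
#' categories at half a unit beyond the outer cut; missing cells at 0).
#' Initialization is deterministic given the data.
#'
#' @param x a `"response_table"`.
#' @param spec an `"instrument"` object.
#' @param mode identification mode: `"probit"` fixes every residual variance
#'   at 1 with all thresholds free; `"anchored"` leaves residual variances free
#'   on `(0, 100)` and anchors each item's first and last interior cuts at
#'   their initial values for identifiability.
#' @param prior a `"prior_spec"`; default [prior_spec()] for the instrument.
#' @return an object of class `"ordcfa_model"`.
#' @export
init_model <- function(x, spec, mode = c("probit", "anchored"), prior = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "response_table"))
  validate_instrument(spec)
  x <- recode_responses(x, spec)
  if (is.null(prior)) prior <- prior_spec(n_factors(spec))
  J <- n_items(spec); K <- spec$n_categories; n <- nrow(x$responses)
  Fk <- n_factors(spec)
  freqs <- suppressWarnings(category_frequencies(x))
  fidx <- item_factor_index(spec)
  for (f in seq_len(Fk)) {
    it <- which(fidx == f)
    obs <- x$responses[, it, drop = FALSE]
    if (all(is.na(obs)) || length(unique(obs[!is.na(obs)])) < 2) {
      warning("factor '", spec$factors$factor[f],
              "' has no observed variability across its items")
    }
  }
  # fully missing items get neutral uniform frequencies for initialization
  freqs[is.na(freqs)] <- 1 / K
  tau <- init_thresholds(freqs)
  rownames(tau) <- spec$items$item
  tauext <- cbind(-Inf, tau, Inf)
  z <- matrix(0, n, J, dimnames = list(NULL, spec$items$item))
  for (j in seq_len(J)) {
    yj <- x$responses[, j]
    yj2 <- ifelse(is.na(yj), 1L, yj)   # placeholder; missing z set to 0 below
    lo <- tauext[j, yj2]
    hi <- tauext[j, yj2 + 1L]
    mid <- (lo + hi) / 2
    mid[!is.finite(lo) & is.finite(hi)] <- hi[!is.finite(lo) & is.finite(hi)] - 0.5
    mid[is.finite(lo) & !is.finite(hi)] <- lo[is.finite(lo) & !is.finite(hi)] + 0.5
    mid[!is.finite(lo) & !is.finite(hi)] <- 0
    mid[is.na(yj)] <- 0
    z[, j] <- mid
  }
  model <- structure(list(
    spec = spec, mode = mode, prior = prior,
    lambda = stats::setNames(rep(1, J), spec$items$item),
    psi = stats::setNames(rep(1, J), spec$items$item),
    tau = tau,
    phi = diag(Fk),
    eta = matrix(0, n, Fk, dimnames = list(NULL, spec$factors$factor)),
    z = z,
    item_factor = fidx,
    marker = is_marker(spec),
    tau_anchor = if (mode == "anchored" && K >= 3) c(1L, K - 1L) else integer(0)
  ), class = "ordcfa_model")
  model
}

#' @export
print.ordcfa_model <- function(x, ...) {
  cat(sprintf("<ordcfa_model> %s mode: %d respondents, %d items, %d factors\n",
              x$mode, nrow(x$z), length(x$lambda), ncol(x$phi)))
  invisible(x)
}

#' Check the structural invariants of a model state
#'
#' Markers exactly 1, thresholds strictly increasing per item, factor
#' covariance symmetric positive definite, residual variances inside
#' `(0, psi_upper)` (`"anchored"` mode) or exactly 1 (`"probit"` mode).
#'
#' @param model an `"ordcfa_model"`.
#' @return `TRUE`, or an error describing the violated invariant.
#' @export
check_model_invariants <- function(model) {
  if (any(model$lambda[model$marker] != 1)) stop("marker loading differs from 1")
  if (any(apply(model$tau, 1, function(t) any(diff(t) <= 0)))) {
    stop("thresholds not strictly increasing")
  }
  ev <- tryCatch(chol(model$phi), error = function(e) NULL)
  if (is.null(ev)) stop("factor covariance not positive definite")
  if (model$mode == "probit") {
    if (any(model$psi != 1)) stop("residual variance differs from 1 in probit mode")
  } else {
    if (any(model$psi <= 0 | model$psi >= model$prior$psi_upper)) {
      stop("residual variance outside (0, ", model$prior$psi_upper, ")")
    }
  }
  TRUE
}

# log inverse-Wishart density of Sigma with df nu and scale S (prior
# expectation of the precision equal to solve(S)/... ; matches a Wishart
# prior on the precision with scale solve(S))
ldinvwishart <- function(Sigma, nu, S) {
  p <- nrow(Sigma)
  cS <- chol(S); cSig <- chol(Sigma)
  lmg <- (p * (p - 1) / 4) * log(pi) +
    sum(lgamma((nu + 1 - seq_len(p)) / 2))
  (nu / 2) * 2 * sum(log(diag(cS))) - (nu * p / 2) * log(2) - lmg -
    ((nu + p + 1) / 2) * 2 * sum(log(diag(cSig))) -
    0.5 * sum(diag(chol2inv(cSig) %*% S))
}

# rows of x ~ MVN(0, Sigma): total log density
ldmvnorm0 <- function(x, Sigma) {
  R <- chol(Sigma)
  q <- backsolve(R, t(x), transpose = TRUE)
  -0.5 * ncol(Sigma) * log(2 * pi) * nrow(x) - nrow(x) * sum(log(diag(R))) -
    0.5 * sum(q^2)
}

#' Log joint density of the complete-data model state
#'
#' Sum of the log priors (free loadings, residual variances in `"anchored"`
#' mode, inverse-Wishart on the factor covariance) and the complete-data log
#' likelihood: the factor density, the latent-response density over observed
#' cells, and the bracket indicator tying each observed latent response to
#' its category (`-Inf` when violated). Missing cells contribute nothing.
#' Used for testing and as a stationarity diagnostic along the chain.
#'
#' @param model an `"ordcfa_model"`.
#' @param x the `"response_table"` the state refers to.
#' @return scalar log density (possibly `-Inf`).
#' @export
log_joint <- function(model, x) {
  spec <- model$spec
  K <- spec$n_categories
  x <- recode_responses(x, spec)
  y <- x$responses
  n <- nrow(y); J <- ncol(y)
  tauext <- cbind(-Inf, model$tau, Inf)
  obs <- !is.na(y)
  yy <- ifelse(obs, y, 1L)
  jj <- rep(seq_len(J), each = n)
  lo <- matrix(tauext[cbind(jj, as.vector(yy))], n, J)
  hi <- matrix(tauext[cbind(jj, as.vector(yy) + 1L)], n, J)
  zo <- model$z
  if (any(obs & (zo <= lo | zo > hi))) return(-Inf)
  mu <- model$eta[, model$item_factor, drop = FALSE] *
    matrix(model$lambda, n, J, byrow = TRUE)
  sdm <- matrix(sqrt(model$psi), n, J, byrow = TRUE)
  ll <- sum(stats::dnorm(zo[obs], mu[obs], sdm[obs], log = TRUE))
  ll <- ll + ldmvnorm0(model$eta, model$phi)
  free <- !model$marker
  lp <- sum(stats::dnorm(model$lambda[free], model$prior$loading_mean,
                         sqrt(model$prior$loading_var), log = TRUE))
  if (model$mode == "anchored") {
    lp <- lp + sum(stats::dunif(model$psi, 0, model$prior$psi_upper, log = TRUE))
  }
  lp <- lp + ldinvwishart(model$phi, model$prior$wishart_df,
                          solve(model$prior$wishart_scale))
  ll + lp
}
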