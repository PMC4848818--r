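---
title: "Bayesian ordinal confirmatory factor analysis with ordcfa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian ordinal confirmatory factor analysis with ordcfa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ordcfa` fits confirmatory factor analysis models to ordinal Likert-scale
questionnaire data. Each of the $J$ items carries a continuous latent
response $z_{ij}$, normal around a one-factor regression,

$$z_{ij} = \lambda_j \,\eta_{i,f(j)} + \varepsilon_{ij},
  \qquad \varepsilon_{ij} \sim N(0, \psi_j),$$

and the observed category arises by thresholding,
$y_{ij} = c \iff \tau_{j,c-1} < z_{ij} \le \tau_{j,c}$ with
$\tau_{j,0} = -\infty < \tau_{j,1} < \dots < \tau_{j,K-1} < \tau_{j,K} =
\infty$. The latent factors $\eta_i \in \mathbb{R}^F$ are multivariate
normal with mean zero and free covariance $\Phi$, so factors are allowed to
correlate. Latent-response means are fixed at 0 and each factor's *marker
item* has its loading fixed at 1, which sets the factor's scale. This
latent-response formulation drops the assumption that raw Likert scores are
themselves normal — which matters precisely when item distributions are
skewed, the situation the built-in synthetic truth emulates with
right-skewed category cuts.

Reverse-keyed items are recoded ($r \mapsto K+1-r$) before the latent model
is applied, so every loading is expected positive and higher always means
more of the construct. The generator emits *raw* responses (reversed items
flipped back), and the fitting path recodes on entry; the two conventions
round-trip exactly.

### Priors

* free loadings: $N(0, 10^6)$ — essentially flat — in `"anchored"` mode. In
  probit mode with sampled thresholds the default is a weakly informative
  $N(0, 25)$: jointly rescaling an item's cuts and loading changes the
  observed likelihood only through the fixed unit residual, so the
  likelihood tends to a positive constant as the loading grows, and under
  a flat prior the tail's volume can dominate the posterior — on a
  sizeable fraction of simulated data sets at $n = 800$ the posterior mean
  of a high-communality loading then sits at 40+ with both chains in
  agreement, which is the mathematically correct but scientifically
  useless answer. A loading prior sd of 5 (loadings beyond ±15 against a
  marker of 1 have no substantive meaning on a 5-point scale) leaves
  plausible values untouched and makes the posterior usable. In `"anchored"`
  mode the anchored cuts pin each item's scale, the ridge does not exist,
  and the literal flat prior is retained.
* residual variances $\psi_j$: Uniform$(0, 100)$, sampled only in the
  `"anchored"` identification mode;
* factor precision $\Phi^{-1}$: Wishart with 10 degrees of freedom and
  identity scale (the BUGS `dwish(I, 10)` convention). At $F = 8$ factors
  this makes the prior expectation of the *covariance* $\Phi$ exactly the
  identity, and the implied marginal prior on a factor variance
  (inverse-gamma$(3/2, 1/2)$) is flat over roughly $[0.05, 2]$. The other
  common reading — scale $I/10$, so that the precision has identity
  expectation — implies a marginal prior on factor variances with mean 10
  and mode 2, which actively repels the small factor variances that high
  marker-relative loadings (e.g. 2.83 against a fixed 1.00) require; with
  that parametrization the prior visibly drags small factor variances
  upward at $n = 800$ and the corresponding loadings downward. The
  identity-scale convention is used throughout: an identity-expecting
  Wishart is read as a statement about the covariance.
* thresholds: flat on the ordered region, intersected with a wide box
  $[-30, 30]$ per cut. The box is what keeps the conditional proper when a
  response category happens to be empty; it is far outside any data-driven
  range and never binds in practice.

### Identification modes

Ordinal data carry no per-item scale: jointly rescaling
$(\tau_j, \lambda_j)$ changes the likelihood only through the fixed
residual standard deviation. Two standard resolutions are provided:

* **probit** (default): $\psi_j \equiv 1$ for every item, all thresholds
  free. This is the textbook identified parametrization of the graded
  probit factor model.
* **anchored**: $\psi_j$ free on $(0, 100)$ with each item's first and last
  interior cuts anchored at their frequency-based initial values, fixing
  the per-item affine frame instead. This mode reproduces the
  uniform-variance prior literally; whether thresholds in a BUGS-style
  implementation of this model are sampled or held at their
  standard-normal-implied initial values is a genuine modelling fork, so
  both behaviours are exposed (`sample_thresholds`).

## The sampler

`fit_ordcfa()` runs a partially collapsed Gibbs sampler. Per sweep:

1. **Per-item scale moves** (`update_item_scales()`): a multiplicative
   random-walk proposal rescales an item's cut vector and (non-marker)
   loading jointly by $c = e^\epsilon$. Both the item's latent responses
   *and the factors* are integrated out: conditional on the other items'
   latent responses, the item's latent response is Gaussian with
   closed-form leave-one-item-out moments, so the acceptance ratio is a
   product of ordinal-probit cell probabilities times the prior ratio and
   the group-move Jacobian $c^d$. Collapsing the factors is essential: a
   move conditioned on factors that were themselves inferred from the item
   being rescaled is self-confirming, and chains ratchet up the
   scale ridge into a quasi-absorbing regime. The collapsed move sees the
   misfit directly and traverses the ridge freely.
2. **Factor redraw** (`update_factors()`): exact multivariate-normal full
   conditional, shared precision Cholesky across respondents. Redrawing
   factors immediately after the factor-marginalized moves is what makes
   the partially collapsed composition valid.
3. **Single-cut moves** (`update_thresholds()`): random-walk
   Metropolis-Hastings on each free cut with the item's latent responses
   collapsed out (cell-probability ratios over the two adjacent
   categories). The textbook alternative — sampling each cut uniformly
   between the extreme latent responses of the adjacent categories — is a
   valid Gibbs step but moves $O(1/n)$ per sweep and cannot reach the
   posterior from frequency-based initial values at survey sizes, which is
   why the collapsed MH form is used.
4. **Latent-response redraw** (`update_latent_mlv()`): truncated normals
   for observed cells, untruncated for missing cells — the
   data-augmentation treatment of missingness (assumed missing completely
   at random). Truncated-normal sampling uses an inverse-CDF on log-CDF
   values with reflection into the lower tail, stable beyond eight
   standard deviations.
5. **Loadings** (`update_loadings()`): conjugate normal regressions of
   each item's latent responses on its factor; markers skipped.
6. **Residual variances** (`update_residual_variances()`, `"anchored"` mode
   only): truncated inverse-gamma full conditionals by inverse CDF.
7. **Factor covariance** (`update_factor_cov()`): conjugate Wishart update
   of the precision, inverted and re-symmetrized.

Any fixed sweep order yields a valid kernel; this order is fixed so runs
are reproducible, and chosen so that every partially collapsed move is
followed by the exact conditional redraw of what it marginalized before
anything else conditions on it.

Chains are reproducible from one root seed; chain $k$ uses
`seed + 1000003 * (k - 1)`. Base R has a single RNG stream, so
"sub-streams" are realized as deterministic per-chain seeds with a fixed
within-chain update order.

### Initialization and numerical choices

* Thresholds start at standard-normal quantiles of the observed cumulative
  category frequencies (clipped to $[5 \cdot 10^{-4}, 1 - 5 \cdot 10^{-4}]$
  and separated by $10^{-3}$ when frequencies coincide). An item with all
  observed mass in one category is an error advising category merging; a
  fully missing item falls back to uniform frequencies with a warning.
* Latent responses start at mid-bracket values; factors at zero; loadings
  and residual variances at 1; factor covariance at the identity.
* Proposal scales: 0.1 for single cuts, 0.05 on the log scale for item
  scale moves. Acceptance rates are recorded on the returned draws object;
  values between 0.2 and 0.9 across the test problems required no
  adaptation.
* Default chain settings are 2 chains of 10,000 sweeps with 5,000 burn-in
  and no thinning; none of these are stated by the source analysis and all
  are configurable.

## The synthetic-data generator

`default_hcfc_truth()` fixes a complete generating truth for the 20-item,
8-factor caregiver instrument, used by the recovery experiments:

* marker loadings 1; the three published headline loadings used verbatim
  (2.83 feeling tired, 2.92 feeling abandoned, 1.39 enjoy caring);
  remaining non-marker loadings plausible values near 1.
* the published 8×8 factor correlation matrix (which is positive definite
  as printed, smallest eigenvalue 0.29) as the true factor correlation;
* factor standard deviations are *not* quoted in the available text and
  are chosen here between 0.33 and 0.9 such that every item keeps moderate
  communality. This is not a free dial: loadings of 2.8–2.9 against a
  fixed marker of 1.00 are only consistent with small variances for those
  factors — otherwise the item approaches a noiseless copy of the factor
  and its scale becomes empirically unidentifiable, which no sampler can
  repair.
* residual variances 1, so the probit identification mode is exactly
  well-specified;
* per-item thresholds at the probit cuts of cumulative probabilities
  (0.05, 0.15, 0.40, 0.75) on each item's latent scale — right-skewed
  category distributions of the kind that motivate the latent-response
  treatment;
* missingness completely at random at rate 0.02 by default (a low rate
  consistent with face-to-face administration); the weakest mechanism
  compatible with augmentation-based handling.

The generator writes a truth record (factors and latent responses)
alongside the data; the fitting path never reads it, so recovery tests are
leak-proof. What the generator does *not* emulate: informative
missingness, differential item functioning, response styles
(e.g. acquiescence), or cluster structure; passing recovery tests
therefore says nothing about robustness to those features in real data.

## What the tests and the acceptance script compute

The validation suite is simulation-based throughout, because the study's
raw responses are not deposited and its printed tables are consequently
not reproducible at desk scale:

* *Oracle equivalence*: on a 1-factor, 2-item, 2-category instance with
  fixed thresholds ($n = 30$), the Gibbs posterior of the free loading is
  compared with a deterministic grid/quadrature posterior (Gauss–Hermite
  over the factor, 161×101 grid over loading and factor variance) within
  three Monte-Carlo standard errors. This small instance uses a proper
  $N(0, 4)$ loading prior: with two binary items the likelihood flattens
  to a positive constant in the loading, so under a variance-$10^6$ prior
  the exact posterior mean is dominated by the prior's tail and no finite
  grid (or chain) estimates it stably — the equivalence check is only
  meaningful for an integrable posterior.
* *Conjugate-update oracles*: the factor update with zero loadings
  reproduces the prior covariance (50,000 draws, 3%); the Wishart update
  with no respondents reproduces its analytic moment $E[W] = \nu S$ (20,000
  draws, 5%); the residual-variance update matches the untruncated
  inverse-gamma mean at $n = 20{,}000$ (5%).
* *Recovery at survey scale*: data from `default_hcfc_truth` at $n = 800$,
  probit mode, 2 × 10,000 sweeps; 95% credible intervals are required to
  cover at least 17 of the 20 true loadings, the three quoted loadings to
  be recovered within ±0.3, and the maximal-loading items for physical
  functioning and family support to be the published headline items.
* *Correlation-report calibration*: identity-Φ data must produce no pair
  starred at 0.001, and a single true correlation of 0.6 must be starred
  at 0.05 ($n = 800$, 500 retained draws).
* *Structural invariants* (markers ≡ 1, strictly ordered cuts, positive
  definite Φ, residual variances in their mode's support) are asserted at
  every retained draw of every test chain.
* *Classical layer*: exact scoring and reversal identities, Cronbach's
  alpha of duplicated items exactly 1 and of independent items near 0, and
  the posterior tail probability of $N(1,1)$ draws against 0 near
  $2\Phi(-1) \approx 0.317$.

`scripts/acceptance.R` recomputes the headline quantities from scratch at
the same sample sizes (recovery chains of 2 × 6,000 sweeps there, which
give the same posterior means to well within reporting precision) and
writes them as JSON.

## Known limitations

* The free-threshold probit parametrization leaves a near-flat likelihood
  ridge for items with very high communality; the collapsed scale move
  makes the chains mix across it, but the *posterior itself* is then wide,
  and with the flat loading prior its upper tail is heavy. Recovery
  experiments should use (and `default_hcfc_truth()` does use) truths with
  moderate communalities.
* Significance stars summarize posterior tail probabilities, not
  frequentist error rates; no multiplicity adjustment is applied anywhere,
  matching the descriptive-table convention.
* The descriptive layer's subgroup tests default to Welch $t$ / one-way
  ANOVA / Pearson correlation; the source analysis does not name its
  tests, and all are overridable.
* No regressions of factors on covariates (MIMIC structure), no
  Hamiltonian sampler, no model-comparison criteria.
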