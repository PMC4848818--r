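# ordcfa — Bayesian ordinal confirmatory factor analysis

`ordcfa` is an R package for confirmatory factor analysis of ordinal
Likert-scale questionnaires, built around the instrument measuring the
health capability of family caregivers (HCFC-8: 20 items on 5-point
scales, loading on 8 correlated factors such as physical functioning,
family support and material conditions/security). It is aimed at
researchers analysing small health-survey samples who want the ordinal
structure of their items taken seriously instead of treating Likert scores
as normal — which misleads exactly when item distributions are skewed.

## The model

Each item $j$ carries a normal latent response
$z_{ij} = \lambda_j \eta_{i,f(j)} + \varepsilon_{ij}$,
$\varepsilon_{ij} \sim N(0,\psi_j)$, and the observed category is
determined by ordered thresholds:
$y_{ij} = c \iff \tau_{j,c-1} < z_{ij} \le \tau_{j,c}$. The factors
$\eta_i$ are multivariate normal with free covariance $\Phi$ (factors may
correlate); each factor's marker item has $\lambda = 1$ to set its scale.
Estimation is by Gibbs sampling with data augmentation: latent responses
(including those of missing cells) are sampled inside the chain, making
every full conditional tractable. Priors: $N(0, \sigma^2_\lambda)$ on free
loadings, Uniform$(0,100)$ on residual variances (in `"anchored"` mode),
Wishart$(10, I)$ on the factor precision. Posterior "significance" is the
two-sided tail probability of a parameter's posterior against a test
value.

The package also ships the classical descriptive layer for such
instruments — 0–100 scale scores, Cronbach's $\alpha$, subgroup tables
(mean/sd with Welch $t$, ANOVA or correlation tests), score correlation
matrices with significance stars — and a synthetic-data generator for the
full ordinal-probit factor model, used for the recovery experiments below.

## Worked example

```r
library(ordcfa)

spec <- hcfc8_instrument()
spec
#> <instrument> 8 factors, 20 items, 5 response categories
#>   Psychological functioning: self_esteem [marker], body_image, negative_affects (reversed)
#>   Physical functioning: feeling_tired (reversed), health_got_worse (reversed) [marker]
#>   ...

# simulate a survey from the reference truth, then fit it back
cfg <- default_hcfc_truth(seed = 1, n_respondents = 800)
sim <- simulate_responses(cfg)
fit <- fit_ordcfa(sim$responses, spec,
                  chain_config(n_iterations = 4000, burn_in = 2000,
                               n_chains = 2, seed = 7))
loadings_report(fit)
#> Posterior factor loadings (95% credible intervals)
#> psychological (factor sd 0.70):
#>   self_esteem              1.00 (fixed)
#>   body_image               1.37 [0.98, 1.89]  <- max
#>   negative_affects         1.17 [0.87, 1.54]
#> physical (factor sd 0.46):
#>   feeling_tired            1.87 [1.26, 2.87]  <- max
#>   health_got_worse         1.00 (fixed)
#> ...
#> family_support (factor sd 0.40):
#>   difficulty_help          1.00 (fixed)
#>   feeling_abandoned        2.11 [1.48, 3.15]  <- max
#>   family_works_together    1.33 [0.95, 1.85]
#> ...

factor_correlation_report(fit)
#> Posterior-mean latent factor correlations
#>                   psychological physical      self_efficacy ...
#> physical          0.406***      1
#> self_efficacy     0.329***      0.464***      1
#> ...
#> Stars: posterior tail probability vs 0 < 0.05*, < 0.01**, < 0.001***

# classical layer
scores <- scale_scores(sim$responses, spec)
round(factor_alphas(sim$responses, spec), 2)
#> psychological  physical  self_efficacy  lifestyle  family_support ...
#>          0.64      0.39           0.62       0.69            0.44
summary(scores$physical)   # 0-100 scale
#>  Min. 1st Qu.  Median    Mean 3rd Qu.    Max.    NA's
#>  0.00   50.00   62.50   66.38   87.50  100.00       1
```

The loadings report reads like the instrument's contribution analysis:
`feeling_tired` dominates physical functioning (posterior mean 1.87
against the fixed 1.00 of `health_got_worse`; generating value 2.83 —
point recovery of such high loadings from n = 800 ordinal responses is
noisy, with a posterior sd around 0.5, though the credible interval and
the item ranking are stable), and `feeling_abandoned` dominates family
support. The correlation report is the posterior analogue of a starred
factor-correlation table; the classical layer reproduces the 0–100
descriptive conventions.

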