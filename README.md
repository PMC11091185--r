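# erspcm

Extreme-response-style adjusted Partial Credit Models for
cross-country comparisons of Likert-type rating data.

## The problem

Country comparisons built on rating scales assume that respondents in
every country read the response categories the same way. They often do
not: some countries favor the outer categories ("extreme response
style", ERS), others the middle. Because the same observed category
then maps to different latent trait levels in different countries,
country means — and any regression of country means on external
covariates such as the Human Development Index (HDI) — can be
confounded by scale usage. A reported curvilinear relationship between
a country-mean outcome and a covariate may shrink or vanish once
response styles are modeled.

`erspcm` is for survey methodologists and cross-cultural researchers
who want to probe such findings. It fits, to long-format ordinal
responses:

* **(a)** a multigroup Partial Credit Model (PCM) — country-specific
  trait distributions, shared item thresholds; all category
  differences are attributed to the trait;
* **(b)** an extended multigroup PCM with a person-level ERS dimension
  that acts as symmetric shifts of the item thresholds;

both coupled to a Bayesian country-level latent quadratic regression
of trait means on a standardized covariate, estimated jointly with the
measurement model.

## Model

For person $p$ in country $g$ and item $i$ on a $K$-point scale,

$$P(Y_{pi}=k) \propto \exp\big((k-1)\theta_p + s_k\eta_p -
\textstyle\sum_{j<k}\tau_{ij}\big),$$

with ERS scoring weights $s_k = |k-(K+1)/2|$ (so the model is exactly
a PCM with person-specific thresholds
$\tau_{ij} + (s_j - s_{j+1})\,\eta_p$), and

$$\theta_p \sim N(\mu_{\theta,g},1),\quad
\mu_{\theta,g} = \beta_0+\beta_1 x_g+\beta_2 x_g^2+u_g,\quad
u_g \sim N(0,\sigma_u^2),$$
$$\eta_p \sim N(\mu_{\eta,g},\sigma_\eta^2),\quad
\textstyle\sum_g \mu_{\eta,g}=0.$$

Setting $\eta \equiv 0$ recovers model (a). Posterior computation uses
an adaptive Metropolis-within-Gibbs sampler written in C++ (collapsed
conjugate updates at the country level, slice-sampled scale
parameters, interweaved non-centered moves); see the vignette
`vignettes/ers-adjusted-pcm.Rmd` for the full account.

A synthetic-data generator reproduces the confounding mechanism with
known ground truth: `confound_scenario()` builds datasets whose true
trait–covariate relationship is null while country ERS means carry a
quadratic covariate signal, so the unadjusted model reports a spurious
quadratic effect and the adjusted model does not.

## Worked example

```r
library(erspcm)

# a 30-country confounded survey: no true quadratic trait effect,
# but mid-covariate countries prefer the extreme categories
design <- simulation_design(G = 30, n_g = 100, I = 6, K = 9, seed = 2024)
sim    <- confound_scenario(design)
sim$truth$beta2
#> [1] 0

fit_u <- fit_model(sim$data, "pcm",     chains = 2, warmup = 400,
                   sampling = 500, seed = 7)
fit_a <- fit_model(sim$data, "ext_pcm", chains = 4, warmup = 500,
                   sampling = 750, seed = 7)
compare_variants(fit_u, fit_a)
#> <sensitivity_report> verdict: adjustment-sensitive 
#>              variant coefficient     mean      lo     hi     std excludes_zero
#> 1     pcm_multigroup       beta1 -0.00597 -0.1311  0.123 -0.0167         FALSE
#> 2     pcm_multigroup       beta2 -0.20129 -0.2950 -0.119 -0.7730          TRUE
#> 3 ext_pcm_multigroup       beta1 -0.00806 -0.1294  0.120 -0.0342         FALSE
#> 4 ext_pcm_multigroup       beta2  0.03035 -0.0697  0.134  0.1766         FALSE
```

Read: the unadjusted multigroup PCM estimates a credibly negative
quadratic coefficient (−0.20, 95% CI excluding zero) although the
generative truth is zero — the quadratic pattern lives entirely in the
countries' scale usage. The ERS-adjusted fit returns the coefficient
to ≈0 with an interval covering zero, and the report's verdict flags
the finding as *adjustment-sensitive*: its substantive conclusion
depends on whether response styles are modeled.

`export_plot_data(fit_a)` returns per-country posterior means with 95%
intervals and 50 posterior draws of the model-implied regression curve
for country-means-versus-covariate displays; `write_fit()` serializes
draws (CSV) and summaries (JSON). A thin command-line wrapper
(`exec/erspcm`, subcommands `simulate | fit | compare | report`) drives
the same functions from YAML configs.

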