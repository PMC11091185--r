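---
title: "Adjusting cross-country comparisons for extreme response style with an extended Partial Credit Model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusting cross-country comparisons for extreme response style with an extended Partial Credit Model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Cross-country comparisons built on Likert-type rating scales assume
that respondents everywhere use the response categories in the same
way. When countries differ in *extreme response style* (ERS) — a
content-independent preference for the outermost categories — observed
country means confound the trait of interest with scale usage, and
correlations between country means and external covariates (such as
the Human Development Index) can be partly or wholly artifactual.

`erspcm` provides the machinery to probe such findings: a multigroup
Partial Credit Model (PCM) that attributes all category differences to
the trait, an extended multigroup PCM that adds a person-level ERS
dimension, a country-level Bayesian latent quadratic regression linking
trait means to a standardized covariate, and a synthetic-data generator
that reproduces the confounding mechanism with known ground truth.

## Model

For person $p$ in country $g$ answering item $i$ on a $K$-point scale,
the extended model sets

$$P(Y_{pi} = k) \propto \exp\!\big((k-1)\,\theta_p + s_k\,\eta_p -
\textstyle\sum_{j<k}\tau_{ij}\big), \qquad k = 1,\dots,K,$$

where $\theta_p$ is the target trait, $\tau_{ij}$ are item thresholds,
and $\eta_p$ is the ERS trait with scoring weights $s_k$. The default
weights are the graded distance from the scale midpoint,
$s_k = |k - (K+1)/2|$ (for $K = 9$: `4 3 2 1 0 1 2 3 4`); a binary
extreme-vs-rest weighting is available as an alternative. With the
graded weights the ERS dimension is *exactly* a symmetric shift of the
thresholds: $\tau'_{ij} = \tau_{ij} + d_j \eta_p$ with
$d_j = s_j - s_{j+1}$, so positive $\eta$ widens the latent intervals
of the outermost categories on both ends of the scale and negative
$\eta$ widens the middle. The package exposes both parameterizations
(`ext_pcm_category_probs()`, `shifted_thresholds()`) and property-tests
their equality to machine precision; at $\eta = 0$ the model reduces
exactly to the PCM. The graded weights were chosen as the default
precisely because they reproduce this symmetric-shift geometry with a
single shift unit per threshold; unit (binary) weights concentrate the
shift on the outermost thresholds only.

The hierarchical structure is

$$\theta_p \sim N(\mu_{\theta,g(p)}, 1), \qquad
\mu_{\theta,g} = \beta_0 + \beta_1 x_g + \beta_2 x_g^2 + u_g, \qquad
u_g \sim N(0, \sigma_u^2),$$

with $x_g$ the standardized covariate, and for the extended variant

$$\eta_p \sim N(\mu_{\eta,g(p)}, \sigma_\eta^2), \qquad
\mu_{\eta,g} \sim N(0, \sigma_{\mu\eta}^2) \ \text{subject to}\
\textstyle\sum_g \mu_{\eta,g} = 0.$$

The quadratic latent regression is estimated *jointly* with the
measurement model (a one-stage fit), so the credibility intervals for
$\beta$ propagate measurement uncertainty; a two-step fit-then-regress
procedure would understate them.

**Identification.** Three constraints identify the scales: the grand
sum of all thresholds is 0, the within-country trait SD is fixed at 1
(all countries enter the regression symmetrically, so no reference
country is singled out), and the country ERS means sum to 0. Every
stored posterior draw satisfies all three.

**Priors** are weakly informative and configurable via `prior_spec()`:
Normal(0, 3) thresholds, Normal(0, 5) regression coefficients, and
half-Normal(2.5) on all SD parameters ($\sigma_u$, $\sigma_\eta$, and
the hyperprior scale $\sigma_{\mu\eta}$). On the logit scale these are
diffuse relative to any plausible rating-scale configuration.

## Posterior computation

The sampler (`fit_model()`) is an adaptive Metropolis-within-Gibbs
scheme written in C++:

* random-walk updates for person traits $\theta_p$, $\eta_p$ and for
  each item's threshold vector (jointly per item), with proposal scales
  adapted during warmup toward standard acceptance targets and frozen
  afterwards;
* conjugate Gibbs updates for $\mu_{\theta,g}$ and $\beta$, with
  $\mu_\theta$ *collapsed out* of the $\sigma_u$ and $\beta$ updates
  via $\bar\theta_g \sim N(x_g'\beta,\ \sigma_u^2 + 1/n_g)$ — this
  removes the funnel-shaped coupling between the country residual SD
  and the country means;
* slice-sampling for all scale parameters ($\sigma_u$,
  $\sigma_{\mu\eta}$ on their collapsed conditionals, $\sigma_\eta$ on
  its sufficient-statistic conditional), plus a joint multiplicative
  rescale move for $(\sigma_\eta, \eta)$ and $(\sigma_u, u)$ — the
  non-centered half of an interweaving pair that breaks the remaining
  funnels;
* per-country location moves that shift all of a country's $\theta_p$
  together with $\mu_{\theta,g}$, so country means mix at the
  data-informed rate rather than diffusing through person-level walks,
  and pairwise country ERS-location moves that trade $\eta$ mass
  between two countries while preserving the sum-to-zero constraint;
* per-country 2-D moves along the empirically learned posterior ridge
  of $(\mu_{\theta,g}, \mu_{\eta,g})$: under strong response-style
  confounding a country's trait mean and ERS mean trade off almost
  one-for-one, and axis-aligned updates cross that ridge slowly, so
  proposals are drawn from the scaled within-warmup covariance of the
  pair (an adaptive-Metropolis step, frozen after warmup);
* the ERS country means are drawn from their exact constrained
  conditional by projection of the unconstrained conjugate draw onto
  the sum-to-zero hyperplane.

The threshold location (its grand mean) is only softly identified
during sampling: thresholds carry proper Normal(0, 3) priors and a
likelihood-invariant translation move explores the near-flat direction.
Each stored draw is then mapped to the identified scale by grand-mean
centering the thresholds with the compensation absorbed into $\beta_0$
and $\mu_\theta$ (and analogously for the ERS location direction, where
the compensation $d_j\,\bar\eta$ cancels in the category normalizer).
This map leaves the likelihood and all hierarchical densities
unchanged, so the reported, identified quantities — $\beta$, centered
thresholds, country means — are unaffected; only the decomposition of
the overall location between $\beta_0$ and the threshold mean is
resolved by it. We chose this over hard-constrained proposals because
constrained threshold updates couple all items and triple the per-sweep
likelihood cost.

Convergence is assessed by split R-hat and rank-normalized bulk ESS
(Geyer-truncated autocorrelations). A fit is flagged `converged` when
the regression coefficients — the inferential targets — have split
R-hat below 1.01 and the linear and quadratic coefficients have bulk
ESS above 400. Scale parameters are reported in the diagnostics table
but do not gate the flag: $\sigma_\eta$ in particular mixes an order of
magnitude more slowly than the coefficients (its posterior is informed
by thousands of weakly identified person-level ERS values), and its
summaries need correspondingly longer runs. `compare_variants()`
refuses non-converged inputs rather than silently comparing them.

Defaults are 4 chains of 1000 warmup + 1000 sampling iterations with
all seeds derived from a single user seed; identical data, seed and
configuration reproduce the draws bit for bit.

## The synthetic-data generator

`simulate_dataset()` forward-simulates the full hierarchy: covariate
(standard-normal, standardized exactly to mean 0 / SD 1 with
denominator $G-1$), country means via the quadratic regression, person
traits, and categorical responses from the extended PCM. Defaults
emulate a 45-country survey on a nine-point scale with 100 persons per
country and 8 items; the per-country sample size and item count of any
particular real survey are free parameters of the design. Default
variance components ($\sigma_u = 0.3$, $\sigma_\theta = 1$ fixed,
$\sigma_\eta = 0.5$) put country-level variation and person-level ERS
variation in the range typically reported for cross-cultural rating
data: visible but far smaller than person-level trait variation.
Thresholds are standard-normal draws centered to a zero grand sum so
generated and estimated parameterizations coincide.

`confound_scenario()` constructs the cautionary mechanism explicitly:
no true trait-covariate relationship ($\beta_1 = \beta_2 = 0$), but
country ERS means carry the quadratic signal,
$\mu_{\eta,g} = \gamma_2 (x_g^2 - \overline{x^2})$. Two choices make
the confound bite, both fixed as scenario defaults: the trait mean sits
off the scale center ($\beta_0 = 1$, as with most self-report scales
whose means lie above the midpoint) so that symmetric extreme
responding moves observed means asymmetrically; and
$\gamma_2 = -0.75$, giving mid-covariate countries the stronger
extreme response style (a spread of roughly one logit in country ERS
means, the size of scale-usage difference illustrated by typical
cross-country comparisons) and hence an apparent inverted-U. On such
data the unadjusted multigroup PCM reports a credibly negative
quadratic coefficient while the ERS-adjusted model's interval covers
the true zero — the package's testable version of the claim that
response-style differences can masquerade as substantive quadratic
effects.

Scale-usage presets (`fig1_presets()`) encode three stylized
countries — baseline ($\mu_\eta = 0$), middle-preferring
($\mu_\eta = -1$), extreme-preferring ($\mu_\eta = +1$) — used in the
test suite to verify that negative ERS inflates the middle-category
share and positive ERS the outer-category share at identical trait
values.

**What the generator does not emulate.** Item-level DIF, non-normal
trait distributions, acquiescence or midpoint styles, and planned
missingness are out of scope; responses are conditionally independent
given the two traits. Passing recovery tests therefore demonstrate
correctness of the estimation machinery under the model's own
assumptions, not robustness of the adjustment on real survey data —
the substantive point of the sensitivity comparison is precisely that
different adjustment families can disagree.

## Reported quantities

`summarize_fit()` gives posterior means, SDs, 95% equal-tailed
credibility intervals (HPD intervals were rejected for
reparameterization sensitivity and to match standard reporting),
split R-hat and bulk ESS per parameter. Intervals use R's default
linear-interpolation percentile convention (type 7).
`standardized_coefficients()` rescales per draw:
$\beta_1^* = \beta_1\,\mathrm{SD}(x)/\mathrm{SD}(\mu_\theta)$ and
$\beta_2^* = \beta_2\,\mathrm{SD}(x^2)/\mathrm{SD}(\mu_\theta)$, with
the SD taken over that draw's country means — standardizing by the
country-mean SD (not the person-level trait SD) because the regression
is a country-level model; the posterior mean of the per-draw ratio is
reported. `compare_variants()` declares a comparison
"adjustment-sensitive" exactly when one variant's 95% interval for the
quadratic coefficient excludes zero while the other's does not,
operationalizing "credibly different from zero" as CI exclusion.
`export_plot_data()` emits per-country posterior means and intervals
plus 50 posterior draws of the model-implied regression curve on an
x-grid — data, not figures, so any plotting layer can consume them.

## Numerical choices and degenerate inputs

* Category probabilities are computed in log space with max
  subtraction; they remain finite and normalized for $|\theta|$,
  $|\eta|$, $|\tau_j|$ up to 30 (property-tested).
* Disordered thresholds are permitted and never reordered — standard
  PCM behavior where categories can lack a modal region.
* Missing responses are ignorably missing: they contribute nothing to
  the likelihood and are preserved by the IO round trip.
* $K = 2$ data are accepted by the data container and the plain PCM,
  but the extended variant raises an unidentifiable-ERS error (every
  symmetric weight vector is constant when $K = 2$).
* Ties in `split_rhat()` degeneracies: identical constant chains give
  1 by convention; zero within-chain variance with between-chain
  disagreement gives `Inf`.
* `fit_model()` accepts `fix = list(tau = ..., sigma_u = ...)` to hold
  thresholds and/or the country residual SD fixed; this supports
  validation against a dense-grid posterior on a small problem
  ($G = 2$, intercept-only regression, known thresholds), where the
  sampler's posterior mean of $\beta_0$ agrees with deterministic
  quadrature within 0.05.

## Problem sizes used in the checks

The automated checks run at deliberately desk-scale designs chosen to
balance statistical resolution against runtime on a single CPU:
parameter recovery uses $G = 30$ countries, $n_g = 200$ persons, 8
items, $K = 9$, true $\beta_2 = -0.3$, ten seeded replications with
2 chains of 400 + 500 iterations each; the confound demonstration uses
$G = 30$, $n_g = 100$, 6 items with 2-4 chains per variant. The
full-survey reproduction (45 countries, the study's sample sizes, 4
chains of 1000 + 1000) is the same code path at larger settings.

## Known limitations

* The sampler is single-threaded; chains run sequentially.
* $\sigma_\eta$ summaries converge more slowly than the regression
  coefficients (see above); treat its interval as indicative unless
  runs are lengthened.
* Only one response-style family (symmetric-shift ERS) is implemented;
  mixture or IRTree-style adjustments, marginal ML estimation, and
  information-criterion model comparison are out of scope.
* The latent regression is polynomial of degree at most 2 with a
  single covariate.
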