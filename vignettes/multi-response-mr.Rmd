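---
title: "Multi-response Mendelian randomization: model, priors and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-response Mendelian randomization: model, priors and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mr2)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of modifiable exposures on disease
outcomes from summary-level GWAS data. Classical summary-level methods —
univariable inverse-variance-weighted (IVW) regression and multivariable MR
(MV-MR) — analyze one outcome at a time. When several related outcomes are
of interest (multimorbidity: cardiovascular disease subtypes, correlated
biomarkers), one-outcome-at-a-time analysis ignores the information shared
between outcomes and cannot say whether an exposure is a *shared* cause of
several diseases or *distinct* to one.

This package implements MR2, a multi-response, multivariable Bayesian MR
model. For variant $i$ with exposure associations $\beta_{X_i}$ (length
$p$) and outcome associations $\beta_{Y_i}$ (length $q$), the model is a
seemingly unrelated regression (SUR) system

$$\beta_{Y_{ik}} = \mu_k + \beta_{X_i}^\top \theta_k + \epsilon_{ik},
\qquad (\epsilon_{i1},\dots,\epsilon_{iq})^\top \sim
N_q\!\big(0,\; D^{1/2} R\, D^{1/2}\big),$$

with $D = \mathrm{diag}(\delta_1^2,\dots,\delta_q^2)$ the per-outcome
overdispersions and $R$ the **residual correlation** between the
summary-level outcomes — the correlation the modeled exposures cannot
explain. Two mechanisms generate it: an unmeasured pleiotropic pathway
shared by several outcomes (whose contribution is always positive,
regardless of the sign or direction of the pathway effect), and non-genetic
factors that act on several outcomes at once. The intercepts $\mu_k$
capture directional pleiotropy and are off by default, the standard MR
convention.

Sparsity is imposed by a spike-and-slab prior: each entry of the $q \times
p$ effect matrix is exactly zero unless its binary indicator
$\gamma_{kj}$ is on, in which case the effect has a Gaussian slab prior.
The residual correlation matrix is constrained by a decomposable Gaussian
graphical model with a hyper-inverse Wishart (HIW) prior, so the residual
*precision* has exact zeros for outcome pairs without an edge.

## Priors and tunable parameters

All hyperparameters live in `mr2_prior()`:

* `slab_variance` (default 1): variance of the Gaussian slab on a nonzero
  effect, on the IVW-standardized scale where residual variances are
  $O(1)$; 1 is weakly informative for direct effects of magnitude below
  about one.
* `inclusion_a`, `inclusion_b` (default 1, 1): Beta hyperparameters of the
  common inclusion probability, marginalized analytically into a
  beta-binomial prior on the whole selection matrix. Beta(1, 1) is
  agnostic about the model size; larger `inclusion_b` favors sparsity.
* `hiw_df` (default 3) and `hiw_scale` (default 1): HIW degrees of freedom
  and scale matrix $\tau I$. `hiw_df` must exceed 2 for a finite prior
  mean; 3 is the weakest such choice and, with $\tau = 1$, centers the
  overdispersions near 1 on the standardized scale.
* `edge_prior` (default 0.5): Bernoulli prior on each residual-graph edge;
  0.5 is indifferent between presence and absence.

`fit_mr2()` defaults to 15,000 sweeps with 5,000 burn-in. One sweep makes
an add/delete/swap Metropolis–Hastings move on each outcome's inclusion
vector, refreshes all active effects from their Gaussian full
conditionals, proposes one residual-graph edge toggle, and redraws the
residual covariance. Because the paired effect proposal is the exact full
conditional, the nonzero effects are *implicitly marginalized* out of the
selection acceptance ratio, which keeps acceptance rates healthy (typically
0.1–0.4 on simulated data) and lets the chain move between models without
a separate reversible-jump construction.

## Why decomposable graphs

Restricting the residual graph to decomposable (chordal) graphs makes the
HIW prior conjugate clique by clique: the marginal likelihood of the
residuals with the covariance integrated out is available in closed form
from clique and separator factors, and the covariance full conditional can
be sampled exactly by a sequential clique algorithm. Non-decomposable
proposals are rejected outright; for the handfuls of outcomes MR is run on
(all graphs on up to three outcomes are decomposable, and most graphs on
five are), this restriction costs little and buys exact sampling. Each
draw's precision matrix carries exact zeros off the sampled graph — the
structural statement "these two outcomes are conditionally independent
given the others and the exposures".

The overdispersions are not given a separate update: the HIW full
conditional is drawn for the covariance $\Sigma$ and then split as
$\delta^2 = \mathrm{diag}(\Sigma)$, $R = \mathrm{cov2cor}(\Sigma)$. A
separate scale update would double-count the variances.

## IVW standardization with several outcomes

Classical IVW weights each variant by its outcome-specific precision.
With $q$ outcomes a common per-variant scale is needed so that a single
weighting applies to the whole row; `ivw_standardize()` divides row $i$ of
both $\beta_Y$ and $\beta_X$ by

$$v_i = \Big(q^{-1}\sum_k \mathrm{se}(\beta_{Y_{ik}})^{-2}\Big)^{-1/2},$$

the precision-averaged per-variant scale. This is the natural joint
generalization because the summary-level residual covariance of a variant
is proportional to a response-independent diagonal under independent
instruments, so averaging precisions over responses recovers that common
scale. For $q = 1$ it reduces exactly to first-order IVW (the package
asserts this numerically in its tests). The exact joint weighting scheme
is a convention of this package, exposed through the `mode` argument.

## Posterior summaries and decision rules

`summary()` on a fit returns the marginal posterior probability of
inclusion (mPPI) for every exposure–outcome pair, the edge posterior
probability of inclusion (ePPI) for every outcome pair, posterior means
and credible intervals of effects (unconditional, i.e. zeros included when
excluded — these are what the benchmark scores — and conditional on
inclusion), and residual partial correlations derived from each draw of
$R$. `jppi()` gives the probability that an exposure is selected for a
whole group of outcomes simultaneously — the evidence for a *shared*
cause; it can never exceed the smallest mPPI involved.

`fdr_select()` turns PPIs into a decision at a target Bayesian FDR: a
two-component Beta mixture fitted by EM (10 random restarts) clusters low
and high PPIs; each PPI's posterior null weight is the low component's
responsibility, and the largest set whose average null weight is below the
target is selected. When the mixture collapses (all PPIs similar, or
components closer than 0.05 in mean), selection falls back to the
median-probability-model rule (threshold 0.5) with a warning. A Beta pair
is used rather than a non-parametric estimate because it is transparent,
testable, and adequate for the bimodal PPI distributions the sampler
produces.

`compute_cpo()` screens individual variants: the conditional predictive
ordinate of variant $i$ is the harmonic mean over draws of its observation
density, computed with log-sum-exp for stability. "Scaled CPO" here means
division by the maximum CPO across variants (a unit-free convention of
this package, since several scalings are in circulation); variants below
the default threshold 0.01 are flagged, and the intended workflow is flag,
remove, refit.

## The synthetic-data generator

`simulate_individual()` implements the generating model, for outcome $k$
measured on $N$ individuals:

$$Y_k = X\theta_k + A\,\theta_A + U\,\theta_{YU} + \varepsilon_k,$$

where $X$ are $p$ correlated exposures instrumented by $n$ independent
biallelic variants (dosages Binomial(2, $f$), $f \sim U(0.05, 0.5)$ —
independence standing in for LD pruning), $U$ a confounder of exposures
and outcomes, and $A$ an unmeasured pleiotropic pathway that is a
descendant of the instruments. `extract_summary()` then produces the
two-sample summary statistics by per-variant univariable regressions, the
first half of the sample providing the exposure GWAS, the second half the
outcome GWAS, with configurable overlap between the per-outcome samples.

Scenarios: **I** null (no effects, no confounder, correlated errors
$r_Y = 0.6$); **II** confounding only; **III/IV** an undirected/directed
shared pathway on top of confounding; **V** correlated outcome errors on
top of confounding.

Design choices a reader should know:

* **Effect pattern.** Exactly `round(sparsity * p * q)` of the $q \times p$
  effects are nonzero (default 30%), with magnitudes $U(0.1, 0.3)$. Signs
  are positive by default (`effect_sign = "positive"`): with
  risk-increasing effects, shared exposures contribute *positively* to the
  raw correlation between outcome summary statistics, which is the regime
  in which the raw correlation exceeds the residual one and the two are
  worth contrasting. A `"random"`-signs option is provided; it makes
  exposure-driven covariance average to zero and the raw correlation can
  then fall below the residual value.
* **Exposure correlation.** `r_x` (default 0.6) is built identically into
  the genetic effect vectors and the non-genetic factors of the exposures,
  so the summary-level design matrix — what the regressions actually see —
  inherits the same pairwise correlation. The confounder adds further
  individual-level exposure correlation on top in scenarios II–V.
* **Instrument strength.** `exposure_h2` (default 0.55) is the fraction of
  exposure variance explained by the instruments, chosen together with
  `a_genetic_ratio` so that the weighted-regression baseline reproduces
  the reference operating range (AUC near 0.92 under confounding and 0.85
  under shared pleiotropy at $N = 100{,}000$); both are stated package
  conventions, exposed in the configuration.
* **Error scales.** `h_x` (default 0.10) fixes the fraction of outcome
  variance explained by the exposures relative to the
  exposure + confounder + error budget; the pathway $A$ adds noise *on
  top* of that budget, so the pleiotropy scenarios are strictly harder
  than the confounding one.
* **The pathway at the summary scale.** The closed-form residual
  correlation treats $A$ as a random vector whose summary-level footprint
  is its OLS projection onto the instruments. A pathway with a literal
  genetic architecture would be amplified at the summary level by a factor
  of order $N/n$ and drive the residual correlation to one. The generator
  therefore parameterizes the genetic component of $A$ at the summary
  scale: `a_genetic_ratio` (default 25) is the ratio of the genetic to the
  projection-level variance of $\beta_A$. This keeps simulated behavior
  invariant to $N$, keeps `theoretical_outcome_correlation()` exact for
  the generator (it reports the effective pathway variance), and preserves
  the qualitative claim that pathway-induced correlation survives even
  with disjoint outcome samples, because the genetic component of $A$ is
  shared across samples while shared errors are not.

What the generator does *not* emulate: linkage disequilibrium between
instruments, weak-instrument regimes beyond what `exposure_h2` exposes,
binary (case-control) outcomes, allele-frequency/effect-size coupling, and
winner's-curse selection of instruments. Passing the simulation benchmarks
therefore says nothing about those failure modes on real data.

## Numerical choices

Normal-equation solves in the selection and refresh steps add a ridge
jitter of $10^{-8}$ to the diagonal; swap moves pick uniformly among
eligible pairs; the rank-based AUC uses midrank tie correction; quantile
credible intervals use the draws' empirical quantiles; the CPO
accumulates on the log scale. Chains are exactly reproducible given
`seed`. Degenerate inputs (fewer than 3 variants, missing values,
constant exposure columns, non-decomposable fixed graphs) are refused
with errors rather than patched.

## Problem sizes used in the shipped checks

The package's test suite and the acceptance script rerun the simulation
study at the study design ($n = 100$, $p = 15$, $q = 5$,
$N = 100{,}000$): 50 replicates for the weighted-regression baseline and
10–12 replicates with shortened chains (3,500 sweeps, 1,200 burn-in) for
the sampler — enough for replicate-level means at the tolerances asserted,
and chosen so the whole suite runs on a single CPU in well under half an
hour. The residual-correlation tracking check runs at $N = 20{,}000$,
where the generator's summary-scale parameterization gives the same
residual-correlation theory at a quarter of the cost. Longer chains
(the 15,000-sweep default) are recommended for real analyses.

## A minimal session

```{r example, eval = FALSE}
cfg <- scenario_config("III_undirected_pleiotropy", seed = 1)
dat <- simulate_summary(cfg)            # summary_data with attached truth
std <- ivw_standardize(dat)             # joint-precision IVW scaling
fit <- fit_mr2(std, seed = 1)           # spike-and-slab SUR sampler
sm  <- summary(fit)

sel <- fdr_select(sm$mppi, fdr_level = 0.05)   # exposures at 5% FDR
jppi(fit, exposure = 3, outcomes = c(1, 2))    # shared-cause evidence
cpo <- compute_cpo(fit, std)                   # variant outlier screen
```

## Known limitations

Inference is conditional on the selected instruments; weak instruments
bias multivariable estimates in data-dependent directions and no
correction is applied. The model assumes Gaussian summary-level responses
(appropriate after IVW standardization of continuous or log-odds scale
associations) and no reverse causation among outcomes. The clique
enumeration bounds the number of outcomes at 16, and in practice the
method is intended for a handful of related outcomes; the number of
instruments should comfortably exceed $q(p+1) + q(q-1)/2$ for the
residual-correlation structure to be well identified (the fitter warns
otherwise).
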