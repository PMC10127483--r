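---
title: "Methods: Finlay-Wilkinson plasticity analysis and candidate-gene screening"
author: "earplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Finlay-Wilkinson plasticity analysis and candidate-gene screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earplast)
```

## The problem

Phenotypic plasticity is the variation of a genotype's trait value across
environments. In a multi-environment trial of a transgenic maize inbred
population — hundreds of target genes, each represented by one to ten
independent transformation events, all in the genetic background of one
shared wild-type recipient line — plasticity analysis asks which genes raise
a yield trait (kernel number per ear, above all) *consistently* across
environments, and which change how strongly the trait responds to the
environment. `earplast` implements the full chain: a ground-truth simulator
for such trials, Finlay-Wilkinson regression, per-line plasticity
summaries, a wild-type-anchored candidate-gene screening cascade, AMMI
stability validation, and measurement-quality metrics for the phenotyping
platform that produces the data.

## The model

Each observation of one trait is modelled as

$$y_{ij} = \mu + g_i + (1 + b_i)\,h_j + \varepsilon_{ij},$$

where $\mu$ is the population mean, $g_i$ the genetic value (main effect)
of line $i$, $h_j$ the effect of environment $j$ (a year–site–block
microenvironment), and $1 + b_i$ the line's slope on the environment
effects — its *linear plasticity*. A slope of one ($b_i = 0$) means the line
tracks the average environmental response; a slope of zero ($b_i = -1$)
means it does not respond to the environment at all. The variance of a
line's residuals around its own regression line is its *nonlinear
plasticity*: environmental response the linear term cannot explain.

The model is not identified without constraints; we use
$\sum_j h_j = 0$, $\operatorname{mean}_i(b_i) = 0$ and
$\operatorname{mean}_i(g_i) = 0$ (the last absorbed into $\mu$). The
wild-type is an ordinary line in the fit; it becomes special only
afterwards, when every line's $(g, b)$ is re-expressed relative to the
wild-type's.

### Least-squares estimator

`fit_fw_ols()` fits the bilinear model by alternating exact conditional
least squares: intercepts $(\mu, g)$ given $(b, h)$; environment effects
$h$ given the rest (a weighted per-column regression with weights
$1 + b_i$); per-line slopes given $h$ (a per-row regression). After each
sweep the parameters are mapped back onto the identified scale by exact
reparameterisations (centring $h$ into $g$, centring $g$ into $\mu$, and
rescaling $h$ by $1 + \bar b$ while mapping $b \mapsto (1+b)/(1+\bar b) -
1$), which leave the fitted values unchanged. Every step is an exact
conditional minimiser, so the residual sum of squares is monotonically
non-increasing — a property the test suite asserts on every fit it makes.
Convergence is declared when the largest parameter change in a sweep drops
below `tol` (default 1e-8, default cap 500 sweeps). Replicated ears within
a (line, environment) cell are averaged before fitting. Lines observed in
fewer than two environments have no identifiable slope and are dropped with
a warning; per-line residual variances use $n_i - 2$ degrees of freedom,
with the convention that a line seen in exactly two environments (an exact
fit) has residual variance zero.

### Bayesian estimator

`fit_fw_bayes()` is a Gibbs sampler for the hierarchical formulation:
exchangeable Gaussian priors $g_i \sim N(0, \sigma^2_g)$,
$b_i \sim N(0, \sigma^2_b)$, $h_j \sim N(0, \sigma^2_h)$, homoscedastic
Gaussian residuals, a flat prior on $\mu$, and scaled-inverse-$\chi^2$
priors on all four variance components. Conditioned on $h$ the slope
updates are ordinary linear regressions and vice versa, so every full
conditional is conjugate. Saved draws are mapped onto the identified scale
before averaging, so posterior means satisfy the same constraints as the
least-squares fit.

Prior scales left unset are anchored at the least-squares variance
decomposition of the same data with `nu = 2` prior degrees of freedom — a
barely-proper, weakly informative choice whose influence vanishes against
hundreds of observations but which keeps the sampler on the right scale
(and lets the posterior concentrate on the exact solution for noiseless
fixtures). The chain starts at the least-squares solution. Defaults are
30,000 iterations, 5,000 burn-in, thinning 5; the test suite and the
acceptance script use shorter chains (4,000–20,000 iterations), which we
found indistinguishable from the defaults on the simulated trial sizes used
there (posterior means of $g$ correlate with least-squares estimates above
0.999). Divergent variance draws abort with the iteration number.

## The simulator and what it does (not) emulate

`simulate_dataset()` draws $(g_i, b_i)$ from a bivariate Gaussian with
optional correlation `rho_gb` (field populations show a positive
genetic-value/plasticity correlation), environment effects $h_j$ from a
centred Gaussian, and residuals per line. Default study conditions, chosen
once to mimic a realistic kernel-number trial:

* `mu = 450` kernels, `sd_g = 45` (a 10% genetic coefficient of variation),
  `sd_h = 45` (environment swings comparable to genetic spread),
  `sigma = 15` residual kernels;
* `sd_b = 0.3`: slope dispersion with a quartile coefficient of dispersion
  of the slope $1+b$ near 0.2, the midpoint of the 0.1–0.3 range typical of
  ear-trait populations;
* two years × three sites × two blocks (each year–site–block triple is one
  microenvironment), one measured ear per plot, one shared wild-type with
  $g = 0, b = 0$ so that wild-type-relative quantities have a known anchor.

Two conventions make stated noise ratios exact rather than approximate.
The $b$ draws are centred to mean zero, and the $h$ draws are centred and
standardised so that their *population* spread equals `sd_h` exactly — the
simulated environments are the complete set of environments in the trial,
not a sample from a larger population, so the $1/n$ variance convention is
the appropriate one. Without this, with only six environments the realised
spread of $h$ varies enough between seeds to change the effective
signal-to-noise ratio of a whole experiment.

The generator emulates the *structure* of a real trial (gene/event
hierarchy, OE/Cas9 material classes, microenvironment grid, skewed
near-zero "negative-effect" traits via `simulate_skewed_trait()`, injected
outliers via `inject_outliers()`, optional missingness). It does not
emulate spatial field trends within blocks, genotype-specific
heteroscedasticity across environments, measurement error structure of an
imaging platform, or kernel-level spatial structure on the ear — so passing
recovery tests here demonstrates correctness of the estimators and the
cascade under the stated model, not robustness to every field artefact.

### The planted-signal benchmark

`planted_signal_experiment()` is the designed experiment for validating the
screening cascade end to end. Sensitivity and specificity are only
well-defined against a binary truth, so background genes are true nulls
(their lines share the wild-type genetic value) and a known subset of
planted genes carries a strong positive shift in $g$ (default: one
environment-effect standard deviation, with residual noise
$\sigma = 0.25\,\mathrm{sd}(h)$). Two design features mirror real trials
and matter for the operating characteristics: every ear in a plot is
measured (default five replicate ears per line per microenvironment), and
the shared wild-type reference — the anchor of every comparison in the
population — is measured much more densely than any single event (default
20 ears per microenvironment). With a single-ear wild-type the anchor's
estimation error is common to all comparisons, and an unlucky draw can
flood the candidate list; dense wild-type replication is both what a real
trial does and what makes the screen's specificity stable.

## The screening cascade

For each year and the primary trait (normal kernel number by default):

1. **Wild-type-relative placement** (`wt_relative()`): $\Delta g = g_i -
   g_{WT}$, $\Delta b = b_i - b_{WT}$; quadrant labels by the signs,
   exact ties assigned to the `+` side and flagged
   (`classify_quadrants()`).
2. **Event rule** (`select_candidates_per_year()`): a gene is a per-year
   candidate when strictly $g > g_{WT}$ in at least `min_events = 3`
   independent events. Both the $g$-only and the joint $g$-and-$b$ counts
   are reported.
3. **Cross-year combination** (`combine_years()`): both-years /
   first-year-only / second-year-only categories.
4. **Advantage filter** (`advantage_filter()`): genes whose advantage is
   marginal are dropped. The published procedure states the intent
   ("small advantages" removed) but no quantitative rule, so the filter is
   operationalised as: retain a gene only if the median $\Delta g$ over its
   wild-type-beating events is at least `min_delta_g_sd = 0.25` population
   standard deviations of $g$. The rule is monotone in its threshold,
   logged per gene, and configurable; 0.25 SD is deliberately mild — it
   removes noise-level advantages without second-guessing genuine ones.
5. **Supporting traits** (`supporting_trait_check()`): candidates are
   reported on ear length and kernels per row (the components of kernel
   number) and flagged when a supporting-trait advantage is negative.

Selection uses point estimates, not credible intervals, which matches the
procedure the screen operationalises; the uncertainty enters through the
event-replication requirement instead.

## AMMI validation

`fit_ammi()` decomposes a genotype × environment table of cell means into
grand mean, main effects, and an SVD of the double-centred interaction
matrix. IPCA scores are scaled by the square root of the singular values so
paired outer products reconstruct the multiplicative terms exactly; the sum
of squared singular values equals the interaction sum of squares (asserted
to 1e-6 relative in the tests). The AMMI stability value is the standard
two-axis form
$\mathrm{ASV} = \sqrt{(w\,s_{1})^2 + s_{2}^2}$ with $w = SS_1/SS_2$, the
ratio of the first two interaction sums of squares; when the interaction
has rank one the ASV degrades gracefully to $|s_1|$. The published
validation names the AMMI model and CV jointly but not the precise
stability statistic; the two-axis ASV is the field's default and the choice
is configurable by using the returned scores directly. Missing cells are
imputed with the iterated additive (row + column) model and flagged.
`mean_stability_screen()` flags genotypes with strictly higher mean and no
higher CV than the wild-type (optionally also no higher ASV): the
conjunction actually required by the published validation is not stated, so
all three columns are emitted and the conjunction is a flag, not a data
loss.

## Measurement-quality metrics

The six static characteristics of a phenotyping platform are implemented in
two families. Accuracy-type metrics compare to a manual reference value:
`accuracy_single()` defaults to $100 - |MV - RV|/RV \times 100$ floored at
zero, so 100 means exact agreement and the metric never exceeds 100; the
signed textbook form ($100 - (MV-RV)/RV \times 100$, which exceeds 100 for
underestimates) is preserved in `mode = "literal"` because published
protocols print it. `trueness()` is the accuracy of the replicate mean —
for an unbiased instrument, averaging shrinks error, so trueness is at
least accuracy in expectation. CV-type metrics (precision,
reproducibility, technical repeatability, robustness) share one
computation, `cv_based_metric()`: per-object CV over the protocol's
repeat structure, averaged over objects, reported as $100(1 - \overline{CV})$
so zero spread scores 100; the raw mean CV is available via
`output = "raw_cv"`. The percentage transform is an interpretation (the
published table reports percentages without stating one), and it makes the
metric blind to constant bias by construction — a deterministic instrument
scores 100 regardless of offset, which is what repeatability means.

## Numerical choices and degenerate inputs

* Quartiles use linear interpolation between order statistics
  (`stats::quantile`, type 7) everywhere — the outlier fences, the quartile
  coefficient of dispersion `(Q3 - Q1)/(Q3 + Q1)`.
* The 1.5 × IQR outlier filter is applied per trait per year by default
  ("the population" is not further specified in the published procedure;
  the grouping is configurable). A constant vector has IQR 0 and nothing
  is removed. Missing values are never flagged.
* CVs use the sample (n − 1) standard deviation; CV of a zero-mean vector
  is an error, not NaN.
* Correlation matrices use pairwise-complete observations; zero-variance
  columns produce missing rows/columns with a warning rather than an
  error.
* Exact ties with the wild-type in quadrant classification go to the `+`
  side and are flagged; the event rule uses strict inequality, so a tie
  never counts as beating the wild-type.
* Seeds: every stochastic function takes an explicit seed; identical seeds
  give bit-identical output, which the pipeline manifest (config hash +
  per-file MD5 checksums) makes auditable.

## Problem sizes used in the tests

The test suite and the acceptance script run the recovery experiment at
roughly 200 lines × 6 environments with 20 replicates (least squares) and
one 20,000-iteration Gibbs chain, and the screening benchmark at 200 genes
with 20 planted signals. These sizes were chosen as the smallest at which
the operating characteristics stabilise: correlations between true and
estimated genetic values exceed 0.95, slope correlations sit near their
information-theoretic ceiling
$\mathrm{sd}(b)/\sqrt{\mathrm{sd}(b)^2 + \sigma^2/\sum_j h_j^2} \approx
0.83$ at the stated noise level, and screening sensitivity/specificity are
reproducible across seeds.

## Known limitations

* Each trait is fitted independently; there is no multi-trait joint model.
* The Bayesian sampler assumes homoscedastic residuals within a trait-year
  fit; per-line residual variances are a derived summary, not sampled
  parameters.
* The advantage filter is an operationalisation of a qualitatively stated
  step; different thresholds give nested but different candidate sets.
* The simulator's wild-type is exactly null by default; set
  `wt_null = FALSE` to draw it like any other line when studying anchor
  error.
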