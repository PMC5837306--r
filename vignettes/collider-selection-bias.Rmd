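---
title: "Simulating collider bias from selective participation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating collider bias from selective participation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(collidersim)
```

## The problem

Large cohort and cross-sectional studies rarely observe the population they
intend to represent: people volunteer, and people drop out, at rates that
depend on their own characteristics. When two variables both influence
participation, restricting analysis to participants conditions on their
common effect — a collider — and thereby induces an association between
the two variables inside the selected sample that does not exist (or has a
different size) in the intended study population. This matters for genetic
epidemiology in particular: a polygenic allele score that predicts a
phenotype inherits, through that phenotype, any participation pressure the
phenotype exerts, so selection can fabricate or distort score–outcome
associations even though genotypes cannot be causally affected by
participation.

`collidersim` packages a Monte Carlo machine for quantifying this effect,
plus a small linear-Gaussian DAG simulator for qualitative variants of the
selection structure, and the classic two-coins-and-a-bell enumeration
(`coin_toy()`) where conditioning on the bell induces a correlation of
exactly −1/2 between two independent fair coins.

## The simulation model

The intended study population contains `n_population` individuals with
three unit-SD Gaussian variables:

- allele score: $G \sim N(0, 1)$,
- phenotype: $P = r\,G + \sqrt{1 - r^2}\,\varepsilon_P$,
- outcome: $O = \gamma\,P + \sqrt{1 - \gamma^2}\,\varepsilon_O$,

with independent standard-Normal noise terms. The outcome noise is rescaled
by $\sqrt{1-\gamma^2}$ so that $O$ keeps unit marginal SD when the causal
effect $\gamma$ of phenotype on outcome is non-zero; under this scaling the
population regression coefficient of $O$ on $G$ is exactly $\gamma r$,
which is what the non-null grids report as the true coefficient. (With
$\gamma = 0$ the score–outcome association is exactly null.)

Participation is a Bernoulli draw per individual with

$$\Pr(S = 1 \mid P, O) = \mathrm{expit}\big(\alpha + \log(\mathrm{OR}_P)\,P
  + \log(\mathrm{OR}_O)\,O\big),$$

i.e. phenotype and outcome act additively (no interaction) on the log-odds
of selection, each parameterized as an odds ratio per SD. The intercept
$\alpha$ is calibrated by `calibrate_intercept()` so that the *expected*
selected fraction equals `target_fraction`; the realized number selected is
then binomial around the target. Calibration integrates the expit over the
bivariate Gaussian law of $(P, O)$ with tensor-product Gauss–Hermite
quadrature (64 nodes per dimension; the integrand is smooth, and the root
is polished until the expectation matches the target to $10^{-8}$) and
solves for $\alpha$ with `uniroot`. Selection odds ratios of 1.2, 1.5 and
1.8 per SD shift the mean phenotype and outcome of participants by about
0.2, 0.4 and 0.6 SD relative to non-participants.

The analysis step, `fit_outcome_on_score()`, is an unadjusted OLS of
outcome on allele score in the selected sample — deliberately not
adjusting for the phenotype, which is what leaves the collider path open.
Confidence intervals are Wald intervals at $\pm 1.959964\,\mathrm{se}$;
with selected samples around half a million the Normal/t distinction is
irrelevant, and the fixed constant makes results bit-reproducible.
Classical OLS standard errors are used for the main analysis; the
inverse-probability-weighted estimator (below) uses HC0 sandwich errors
because its weighted residuals are heteroscedastic by construction.

## Study conditions and defaults

The generator's defaults are the study conditions of the headline
experiment: an intended population of 9,000,000, a target selected
fraction of 1/18 (about 500,000 participants — the scale of a large
national biobank's invitation campaign), 100 replicates per scenario, and
scenario grids crossing $\mathrm{OR} \in \{1.2, 1.5, 1.8\}$ (applied
equally to phenotype and outcome) with
$r \in \{0.05, 0.10, 0.15, 0.20, 0.30\}$, i.e. scores explaining 0.25% to
9% of phenotypic variance; the non-null grid adds $\gamma = 0.1$.

`run_scenario()` aggregates replicates into the mean and SD of the
coefficient and its z-score plus the count of 95% CIs containing the
reference value (zero in null scenarios, $\gamma r$ otherwise);
`run_grid()` crosses the grids in table order (descending OR, ascending
$r$). A typical null-grid cell at full scale looks like:

```{r, eval = FALSE}
s <- run_scenario(scenario_config(r = 0.30, or_p = 1.8, seed = 1))
s[, c("mean_beta", "sd_beta", "mean_z", "sd_z", "n_ci_covering")]
#>   mean_beta  sd_beta mean_z  sd_z n_ci_covering
#> 1   -0.0081   0.0013  -5.80  1.06             0
```

(9e6 individuals × 100 replicates; about two to three minutes of
computing. The snippet above is from a 10-replicate run of the same
scenario; the tested full runs reproduce the −0.008 mean coefficient and
the large negative mean z within Monte Carlo tolerance, with 0/100 CIs
containing zero.)

## Reproducibility contract

Each scenario owns a master seed. Replicate $i$ uses the $i$-th
L'Ecuyer-CMRG stream derived from that seed (`parallel::nextRNGStream`),
with the population draws and the selection draws on separate substreams,
so any single replicate can be regenerated in isolation and the full 9M
population is regenerated independently for every replicate. Grid cells
get consecutive derived seeds. The caller's RNG state is never disturbed.
Re-running any scenario, grid, or CLI invocation with the same seed
reproduces results bit-for-bit.

A numerical choice worth stating: the simulation kernels draw Normal
variates by inverting the uniform stream with Acklam's rational
approximation to the Normal quantile (absolute error below $8 \times
10^{-9}$, vastly smaller than any Monte Carlo noise at these sample
sizes), which makes full-scale replicate generation roughly four times
faster than the vectorized base-R path while remaining a pure function of
the R RNG state.

## Inverse probability weighting

When the selection model is known, weighting each selected individual by
the inverse of its true selection probability restores consistent
estimation: `ipw_fit()` implements this as weighted least squares with
robust errors. In the null grids the unweighted selected-sample
coefficient is negative everywhere (both odds ratios positive, $r > 0$),
while the IPW coefficient is centred on zero; the tests verify the bias
removal across the grid with an explicit Monte Carlo error allowance,
since at feasible replicate counts the residual IPW bias estimate has
noise of the same order as a tenth of the smallest grid bias.

## The DAG library

`dag_spec()` defines a small structural-equation graph over nodes such as
`G`, `P`, `O`, `U` (a shared unobserved factor) with an implicit logistic
selection node `S`; every continuous node's noise is rescaled so its
marginal SD is 1 (the constructor errors if a node's parental variance
already exceeds 1). The intercept calibration generalizes the
two-covariate case: the selection parents' analytic covariance is
Cholesky-factored and the same Gauss–Hermite machinery applied, so the
`core` preset — the main simulation's structure — reproduces
`simulate_population()` + `apply_selection()` *draw for draw* given the
same seed.

The panel presets encode qualitative selection scenarios. The published
panel graphics were not available to this implementation, only their
captions, so each preset is the minimal linear-Gaussian graph that
provably exhibits the captioned behaviour, with the chosen edges stated in
`?dag_preset`; the tests verify the behaviour by simulation rather than
assuming the topology. Two design choices are worth recording:

- `panelF` needs the phenotype–outcome association biased while the
  score–outcome association stays clean. The preset uses `G -> P`,
  `U -> P` with selection on `O` and `U`: conditioning on the collider `S`
  opens `O`–`U` (biasing `P`–`O` through `U`), while `G` remains
  d-separated from `O` because `P` is an unconditioned collider on the
  only connecting path.
- The panel presets default to a selected fraction of 0.3 (attrition-like
  participation) and shared-factor weight 0.5, rather than the headline
  study's 1/18 fraction and 0.3 weights. At demonstration sizes
  ($n = 10^6$, 20 replicates) the 1/18 fraction leaves only ~55k selected
  individuals and Monte Carlo noise of the same order as the panel biases
  themselves; with the 0.3 fraction every panel's captioned behaviour is
  at least eight Monte Carlo SEs from zero, so the demonstrations are
  reliable. The core preset keeps the study conditions.

`bias_report()` classifies each association's selection-induced bias as
negligible, positive or negative using a 3-SE rule on the mean
selected-minus-full coefficient difference across replicates.

## What the tests do and do not show

The test suite re-runs the full-scale grid cells that anchor the published
tables (9e6 individuals, 100 replicates each) and checks the replicate
means, z-scores, coverage counts, selected-sample sizes and participation
shifts at their Monte Carlo tolerances; properties that are invariant to
population size (mean bias, nominal coverage under neutral selection, IPW
bias removal) are checked at reduced scale — 4.5e5 to 1.8e6 individuals —
with the invariance itself verified by comparing a 9e6 and a 9e5 run of
the same scenario. Problem sizes were chosen so the default suite and the
acceptance script each complete in tens of minutes on a single CPU.

The generator emulates the *structure* the study posits — Gaussian
unit-variance variables, log-odds-linear selection, no interaction — and
none of the complications of real cohorts: discrete genotypes and LD,
non-Normal phenotypes, nonlinear or interacting selection, longitudinal
attrition as a time-to-event process, or measurement error. Passing tests
therefore certify the collider-bias mechanism and its magnitudes under
the stated model, not the size of selection bias in any particular real
study. The mortality/competing-risk story (a phenotype that kills before
the outcome can be observed) is represented as a selection node, not a
survival process.

## Known limitations

- Selection intercept calibration supports at most three selection
  parents (tensor quadrature); the presets need at most two.
- The DAG simulator covers linear-Gaussian structures with unit-SD nodes
  only; weights implying parental variance above 1 are rejected rather
  than renormalized.
- `ipw_fit()` requires the *true* selection model; estimating the
  selection model from data (and multiple imputation generally) is out of
  scope.
- The coverage reference in non-null scenarios is the population
  coefficient $\gamma r$; no attempt is made to decompose bias into
  selection and estimation components.
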