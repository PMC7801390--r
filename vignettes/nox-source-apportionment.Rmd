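---
title: "Partitioning fossil and non-fossil NOx emissions from precipitation-nitrate isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning fossil and non-fossil NOx emissions from precipitation-nitrate isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noxsource)
```

## The problem

Fossil-fuel NOx emissions (coal combustion, vehicle exhausts) are well
inventoried; non-fossil emissions (biomass burning, microbial N cycling in
soils and animal wastes) are not, because their emission factors are
diffuse and largely unrecorded. The natural nitrogen-isotope composition
of nitrate in precipitation offers an integrating tracer: the four source
classes emit NOx with distinct δ15N signatures, precipitation scavenges
the ambient NOx pool together with its oxidation products, and so the
δ15N of wet-deposited nitrate encodes the emission mix. This package
implements the inference chain from tabulated δ15N observations to
regional fossil/non-fossil emission budgets.

## Model and assumptions

### Initial-NOx reconstruction

The initial NOx pool (the mix of all emissions before oxidation) cannot be
sampled directly. Its δ15N is reconstructed as the concentration-weighted
mean of the three species precipitation collects — ambient NO2 (weighted
`C_NO2 / f_NO2` to represent total NOx), HNO3 and particulate nitrate:

$$\delta^{15}N_{i\text{-}NOx} = \frac{\delta_{NOx} C_{NO2}/f_{NO2} +
\delta_{HNO3} C_{HNO3} + \delta_{pNO3} C_{pNO3}}{C_{NO2}/f_{NO2} +
C_{HNO3} + C_{pNO3}}$$

This is a convex combination: the result is bounded by the extreme
species values and is invariant to the concentration unit, so
`reconstruct_i_nox()` accepts any single consistent unit per record and
performs no conversion. Where ambient coverage is sparse the global mean
values f_NO2 = 0.64 ± 0.10 and δ15N_NOx = −7.7 ± 2.9 ‰ are the
conventional defaults (they are the defaults of `simulate_ambient()`).

### The processing offset

The offset ¹⁵Δ between precipitation-nitrate δ15N and the reconstructed
initial-NOx δ15N absorbs the isotope effects of atmospheric processing.
It is estimated per record (`offset_single()`, exactly
`obs − reconstruction`), summarised per scenario (`scenario_offset()`:
sample mean ± SD), and pooled across the two conventional scenarios —
synchronous ambient observations versus non-synchronous compilations —
by `pooled_offset()`. **Pooling rule:** the mean is the unweighted average
of the two scenario means; the SD uses quadrature propagation
$\sqrt{s_1^2+s_2^2}/2$, the standard rule for the mean of two independent
estimates. For the canonical scenario estimates (2.1 ± 1.7 ‰ and
5.7 ± 3.2 ‰) this yields 3.9 ± 1.8 ‰. The half-range rule
$|m_1-m_2|/2$ happens to give the same 1.8 ‰ there; quadrature is what is
computed.

### The mixing model

At urban sites all four sources contribute; at non-urban sites vehicle
exhaust is excluded (little long-range transport of traffic NOx), leaving
a three-source balance. Observations are modelled as

$$y_i \sim N\!\Big(\textstyle\sum_k f_k \mu_k + \Delta,\;
\sum_k f_k^2 \sigma_k^2 + \sigma_\Delta^2 + \sigma_{res}^2\Big),
\qquad \sum_k f_k = 1,$$

the SIAR-style likelihood in which source spread, offset uncertainty and
a residual term combine. Priors: flat Dirichlet(1, …, 1) on the fraction
simplex (uninformative; there is no basis for informative weights) and a
half-normal prior on σ_res. The residual term is retained because real
site-year replicates scatter beyond what source spread explains; its
prior scale (`resid_scale`, default 5 ‰) is wide relative to observed
within-site spreads and the posterior shrinks it readily (degenerate
zero-noise fixtures recover σ_res near 0).

**Sampler.** Random-walk Metropolis on an unconstrained parameterisation:
additive-log-ratio (ALR) transform of the simplex plus log σ_res, with
the ALR Jacobian Σ log f_k and the log-scale Jacobian applied so the
stated priors are exact. A single joint Gaussian proposal is used; its
scale adapts every 50 burn-in iterations toward a 23% acceptance rate and
is frozen afterwards, preserving detailed balance of the retained draws.
Defaults (4 chains × 10 000 iterations, 5 000 burn-in, thinning 2) retain
10 000 draws, matching the output size conventional for SIAR runs.
Convergence is monitored with the Gelman–Rubin potential scale reduction
factor (`check_convergence()`, flag threshold 1.05).

Tunable parameters that matter:

| parameter | unit | default | why |
|---|---|---|---|
| `offset` mean/SD | ‰ | 0 ± 0 (pass 3.9 ± 1.8 for the pooled estimate) | shifts the mixture and widens the likelihood |
| `resid_scale` | ‰ | 5 | half-normal scale for σ_res; wide but proper |
| `n_iter`/`burn_in`/`thin`/`n_chains` | – | 10 000 / 5 000 / 2 / 4 | ≈10 000 retained draws; ≥2 chains for diagnostics |
| `proposal_scale` | – | 0.4 | initial RW scale; adapted during burn-in |

### Regional aggregation and budgets

A source's region-wide contribution combines its urban and non-urban
fractions with population weights,
$F = f_{urban} P_{urban} + f_{non\text{-}urban} P_{non\text{-}urban}$.
A literal *product* of all four terms is sometimes printed in this
context; it cannot be a relative contribution (it neither stays on the
fraction scale nor preserves the sum to one across sources), so the
weighted sum is implemented, with the product form available behind
`rule = "product"` purely for audit. Fossil = S1 + S2 and non-fossil =
S3 + S4; the inventory fossil amount then scales to
$A_{total} = A_{fossil}/F_{fossil}$ and
$A_{non\text{-}fossil} = A_{total} - A_{fossil}$, identities that hold
exactly and per Monte Carlo draw.

Uncertainty is propagated by Monte Carlo (default 10 000 draws, matching
the conventional output size) with truncated-normal inputs — shares on
(0, 1], amounts on [0, ∞) — or directly from supplied posterior draws.
A caution documented here because it is easy to miss: when the fossil
share has non-trivial mass near 0, the ratio $A_{fossil}/F$ is so
heavy-tailed that its variance need not exist; Monte Carlo SDs of
`a_total` are then simulation-size dependent (two independent 10⁶-draw
estimates of the SD at F ~ N(0.5, 0.1) truncated to (0, 1] differ by
~10%). The central (plug-in) values are what correspond to printed
budget numbers; the MC means exceed them because 1/F is convex.

The cross-region headline share is reported as the unweighted mean of the
regional non-fossil shares (57%, 54%, 53% → 55% after rounding). Whether
a published aggregate of this kind is weighted or unweighted is often
unstated; the unweighted mean reproduces the printed value here and is
what `scripts/acceptance.R` reports, without asserting it as the only
possible rule.

### Year windows and fit granularity

Observation windows differ by region (e.g. 2000–2016 vs 2000–2017 in
different summaries of the same compilation), so `run_pipeline()` treats
per-region year windows as configuration, never as constants. Two fit
granularities are exposed: `"site_year"` (fit each site-year's replicates,
then average posterior means across site-years — the default, matching
how replicate tables are usually fed to SIAR) and `"pooled"` (one fit per
region × class). A precomputed contribution table can bypass the MCMC
stage entirely; downstream results are then identical, which the test
suite checks.

## The synthetic-data generator

No machine-readable compiled dataset exists (published values live in
figures), so the generator emulates its statistical structure:

- **Observation tables** (`simulate_observations()`): per-stratum normal
  δ15N with the printed stratum moments (e.g. East Asia urban 1.7 ± 5.4 ‰,
  non-urban 0.3 ± 3.1 ‰), sites nested in strata and replicates nested in
  site-years. Replicate counts per site-year are not published; the
  default is 5, configurable. The within/between-site variance split is
  likewise unpublished; the default splits stratum variance 50/50, which
  keeps pooled moments exact while giving realistic nesting.
- **Mixtures** (`simulate_mixture()`): the forward mass balance with
  per-observation source draws, offset draws and residual noise — the
  exact generative counterpart of the mixing likelihood, used for
  parameter-recovery tests.
- **Ambient records** (`simulate_ambient()`): log-normal concentrations
  (positivity), truncated-normal f_NO2 on (0, 1], normal isotope values.
  The HNO3/p-NO3 isotope defaults (1 ± 3 ‰, 5 ± 4 ‰) are realistic
  mid-latitude values chosen once; concentrations default to plausible
  µg m⁻³ magnitudes. These choices only shape test fixtures — the
  reconstruction is scale-invariant and convex regardless.

What the generator does **not** emulate: spatial autocorrelation between
sites, seasonal structure (compiled observations mix warm/cool/whole-year
sampling; the compilation evidence is that this does not reshape regional
patterns), temporal trends within a stratum, and digitisation error in
the compiled values. A green parameter-recovery test therefore
establishes that the sampler inverts the stated generative model at
realistic n — not that field data satisfy that model.

## Source signatures

Only two end-members have compiled signatures stable enough to hard-code:
coal combustion 13.7 ± 3.9 ‰ and microbial N cycling −30.2 ± 6.7 ‰.
Vehicle-exhaust and biomass-burning signatures vary strongly across
compilations, so `nox_sources()` requires them explicitly. The values
used throughout the tests (vehicle −4 ± 4 ‰, biomass 1 ± 4 ‰) are
synthetic stand-ins in the plausible literature range, chosen once for
fixtures and not asserted as a recommendation.

## Numerical choices

- **Tolerances.** Simplex closure is enforced to 1e-9 on generator inputs
  and holds to the same tolerance on every retained draw (the ALR inverse
  is exactly normalised). Posterior means sum to 1 within 1e-6.
- **Initialisation.** Chains start at the simplex centre (ALR zero) and
  σ_res at the observation SD — overdispersed starts are unnecessary at
  these dimensions, and the Gelman–Rubin check guards against false
  convergence.
- **Degenerate inputs.** All-identical source means trigger a
  non-identifiability warning but still sample (the posterior is the
  prior). A zero fossil share is a hard error in `emission_budget()`: the
  budget identity divides by it and an all-non-fossil regime is outside
  the mass balance's validity. Zero-variance generators return exact
  constants.
- **Tie-breaks.** `closed_form_two_source()` clamps the algebraic
  inversion to [0, 1]; equal source means are an error there.
- **Determinism.** Every stochastic entry point takes a seed and restores
  the caller's RNG stream; `run_pipeline()` spawns per-stage,
  per-stratum seeds from one master seed by a deterministic string hash,
  so one flag reproduces the whole bundle from its manifest.
- **Label permutation.** Permuting source order permutes posterior
  columns statistically, not byte-identically: the ALR transform fixes a
  reference coordinate and the RNG stream maps to coordinates by
  position, so exact equivariance is impossible for any fixed-stream
  sampler in this parameterisation. The test suite checks equivariance of
  posterior means within Monte Carlo error.

## Descriptive statistics

`compare_groups()` operates on site-level means (so heavily replicated
sites do not dominate): one-way ANOVA across regions within each site
class, and a Welch two-sample test for urban vs non-urban within each
region — Welch rather than a pooled-ANOVA contrast because the two
classes have visibly unequal variances in compiled data; this is a
documented choice. The conventional significance level for these spatial
contrasts is α = 0.1, reflecting small regional site counts and high
natural δ15N variability. `fit_trend()` fits ordinary least squares of
site-year mean δ15N on year with the Pearson correlation and a pointwise
95% confidence band; linear fits only — smoothers are out of scope.

## Known limitations

- The likelihood ignores concentration dependence (MixSIAR-style
  covariates), hierarchical pooling across sites, and a second isotope
  dimension (δ18O), all deliberately out of scope.
- The RW-Metropolis sampler mixes slowly when two sources' signatures
  overlap (vehicle vs biomass): with short chains, credible intervals are
  noisy and the Gelman–Rubin statistic can exceed 1.1. Use the default
  chain lengths (or longer) for reporting; the diagnostics are there to
  be read.
- Monte Carlo SDs of ratio-derived budget quantities are heavy-tail
  sensitive (see above); report central values alongside MC spreads.
- Scenario offset estimates can be recomputed from any supplied ambient
  table, but published per-record scenario inputs are supplementary-only;
  the package accepts the printed scenario summaries as direct constants.
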