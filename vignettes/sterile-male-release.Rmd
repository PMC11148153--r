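---
title: "Methods: sterile-male-release suppression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sterile-male-release suppression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lampreysmr)
```

This vignette is the package's account of its science: the two models it
implements, the parameters that matter, what the synthetic generator does and
does not emulate, and the numerical and design choices made where the
published record leaves the design open. It states no empirical result that
the test suite and acceptance script do not themselves compute.

## 1. The problem

Sterile-male release suppresses a pest population by flooding the spawning
grounds with sterilized males so that most matings produce no viable
offspring. For sea lamprey — semelparous, nest-building, with males mating
multiply — the technique is evaluated on two levels:

1. **Egg accounting (adult stage):** given the realized overflooding ratio in
   a stream-year, how many of the eggs deposited were neutralized?
2. **Recruitment effect (larval stage):** did the density of age-1 larvae the
   following year actually fall, and by how much per unit of release effort?

The package implements both, plus a generator that creates complete synthetic
studies so the pipeline is testable end to end.

## 2. Adult assessment chain

For a stream-year with `M` sterile males released, `R` recaptured in
assessment traps, and `C` wild captures:

* **Abundance.** Equal catchability makes the sterile cohort a marked sample:
  `N̂ = round(C·M/R)` (Lincoln–Petersen). When `M = 0` or `R = 0` the season
  is *not estimable* and reported as NA, never zero. Rows may carry an
  `abundance_override` — an independently derived estimate used when the
  Petersen value is unavailable (no-release years) or superseded; the
  packaged fixture uses overrides exactly where the published table's
  abundance cannot be reproduced from its own counts, and flags rows whose
  published arithmetic is internally inconsistent as `ambiguous` so exact
  tests skip them.
* **Overflooding ratio.** `r = R/m`, with `m` the observed wild-male count
  when captures were sexed, else `C·(1 − p_female)`. Reported ratios are
  rounded half away from zero (all published integers use that rounding; R's
  default half-to-even does not reproduce them). Published ratios censored as
  "greater than 40:1" are carried with `ratio_censored_at = 40` and the bound
  is used in arithmetic.
* **Eggs.** `eggs_before = N̂·p_female·fecundity` with defaults 0.5 and
  51,000 (the study system's measured values); `eggs_after = eggs_before/r`
  under the *table* convention — every egg could meet a different male, so a
  wild male outnumbered `r`:1 fertilizes a `1/r` share. The textbook
  random-mating alternative, division by `r + 1` (the wild male is one of
  `r + 1` candidates), is selectable via `convention = "random-mating"`; the
  table convention is the default because it is the only one consistent with
  the published before/after columns. With no release (`r = 0`) eggs are
  unchanged; the implied reduction is `100·(1 − 1/r)`.

## 3. Recruitment model

Observations are survey-level age-1 recruitment indices: density (larvae per
m² of habitat) × 1000, rounded half away from zero; zero-density surveys are
legitimate observations. Age-1 status is assigned from length and month
(20–40 mm May–June, 40–60 mm July–August, 60–80 mm September–October; other
months are not assessable). The process model is white noise on the log
scale with an effort-proportional mortality term:

$$\log(A_{yr,s}) = a_s + a'_{yr,s} - q_s E_{yr,s}, \qquad
  a'_{yr,s} \sim \mathrm{Normal}(0, \sigma_a)$$

$$\hat a_{yr,s,l} \sim \mathrm{NegBinomial}(A_{yr,s}, \theta),
  \qquad \mathrm{Var} = \mu + \mu^2/\theta$$

* `E` is sterile males released / 1000 in the *spawning* year — one year
  before the survey year, because surveyed age-1 larvae hatched the previous
  spring. Observations whose spawning-year release count is unknown are
  dropped with a warning.
* `q_s ≥ 0` is instantaneous mortality per unit effort; the communicated
  effect is `100·(1 − e^{-qE})`, the percent reduction in recruitment, with
  `E = 1` (1000 males) the reporting convention. A signed-`q` variant
  (`q_signed = TRUE` with a symmetric prior) exists for sensitivity analysis.
* `θ` is shared across streams and years; `a_s` and `q_s` are
  stream-specific. Sites within a stream-year are treated as exchangeable
  replicates (no site effects) — the published model block writes a single
  observation equation, and nothing in the available record identifies site
  effects.

**Priors.** The study's exact low-information priors are in an unavailable
supplement, so the defaults here are documented reconstructions, not the
originals: `a_s ~ Normal(0, 10)`, `σ_a ~ half-Normal(0, 2)`,
`q_s ~ half-Normal(0, 1.5)`, `θ ~ half-Normal(0, 5)`. The `q` prior spreads
the implied percent reduction per 1000 males broadly over 0–100% (prior
median ≈ 64%), qualitatively matching a weak prior on the effect scale. All
four are configurable (`prior_config()`, or YAML via `priors_from_yaml()`).
Because the original priors and raw survey data are unavailable, the
published posterior medians (67/50/52% for the three streams) are *not*
reproduction targets; the package's correctness is instead established by
parameter-recovery, oracle-agreement and convergence tests on synthetic data.

## 4. Sampler and numerics

The posterior is sampled by adaptive random-walk Metropolis-within-Gibbs:

* **Parameterization.** Year deviations are non-centered
  (`a' = σ_a·z`, `z ~ Normal(0,1)`) to avoid the funnel that makes centered
  hierarchical scales mix poorly; `σ_a`, `q_s`, `θ` are proposed on the log
  scale with the Jacobian included (keeping them positive without boundary
  rejections).
* **Blocks.** Because the likelihood factorizes over stream-years, proposals
  for all streams (or all groups) are evaluated in one vectorized pass and
  accepted independently. A dedicated *ridge* block proposes a joint shear
  `(a_s, q_s) → (a_s + δ, q_s + δ/Ē_s)` along the direction the likelihood
  leaves unconstrained in release streams — a unit-Jacobian symmetric move
  that roughly halves the worst split-R-hat at default settings.
* **Adaptation.** Proposal scales adapt toward 44% acceptance during warmup
  only (rate `min(0.25, 1/√t)`); kept draws come from a fixed kernel, so the
  chain is valid without diminishing-adaptation arguments.
* **Defaults.** 4 chains × 5000 iterations, warmup 2000 — the published MCMC
  protocol. Initialization is data-informed (stream means) with jitter and
  retries; a persistent non-finite posterior raises an initialization error.
* **Diagnostics.** Split-R-hat per parameter (each chain halved; Gelman–Rubin
  on the halves). The convergence contract on the default synthetic fit is
  R-hat ≤ 1.05; typical values are ≤ 1.03 (the field study reported
  1.00–1.01 on its data). Constant parameters (e.g. pinned in sub-models)
  return NA rather than a spurious statistic.
* **Degenerate designs.** With a single year per stream, effort and mean
  recruitment are confounded and the marginal posterior of `q` collapses to
  its prior; a test asserts this (Kolmogorov–Smirnov distance < 0.1), so the
  software cannot quietly "find" an effect an unreplicated design cannot
  support.

The sub-model used by the quadrature oracle (one stream, deviations pinned
to zero, `σ_a` and `θ` fixed) is exposed through `fit_mcmc(..., fix = )`, and
the oracle integrates the exact 2-parameter posterior on a fine grid; the
MCMC mean of `q` must agree within 3 Monte-Carlo standard errors (batch
means).

## 5. What the synthetic generator emulates — and what it does not

`simulation_config()` states a world mirroring the study footprint: 3
streams × 10 years; no releases in the first four years or the seventh (the
pandemic gap); ~1000 males per release-year otherwise; 15 surveys per
stream-year; wild runs of ~40 adults; trap capture probability 0.2 (published
seasons imply roughly 0.05–0.3); fecundity truncated-Normal with sd 12,000 on
[3,100, 72,000]. Two calibration notes:

* the truncated-Normal *location* is solved (closed-form truncated mean +
  uniroot) so the realized mean fecundity equals the stated 51,000 — naive
  clipping would bias it ~2% low;
* per-year survey counts and site areas are not published; the defaults are
  stand-ins and are flagged as such in `truth.json`.

Trapping is equal-catchability binomial; egg viability is binomial thinning
at `1/r`. One RNG stream per bundle with fixed substream order (trapping,
eggs, recruitment), so a bundle regenerates byte-identically from config +
seed but cannot be partially regenerated — simplicity was preferred over
granular reproducibility.

A green test on this world establishes that the estimators and sampler
recover what they claim *under the model's own assumptions*. It does not
establish robustness to what the generator omits: unequal catchability or
trap-shy animals, immigration, density-dependent recruitment, spatial
clustering of larvae beyond NB overdispersion, site effects, aging error in
the length-band rule, or habitat change (two dams were removed mid-study).
Those are exactly the caveats the field program itself reports.

## 6. Known limitations

* The published per-stream posterior estimates cannot be matched exactly
  without the unpublished priors and raw survey tables; tests assert
  recovery and calibration properties instead.
* The Petersen estimator is the single mark-recapture variant implemented
  (no Chapman/Bailey corrections); at the observed recapture counts the
  small-sample correction would be within rounding of the reported integers.
* No density-dependent stock-recruitment extension and no model-comparison
  machinery (WAIC/LOO) — only convergence diagnostics and posterior
  summaries.
* The egg accounting is deterministic bookkeeping, not a mating-system
  model; its "table" divisor is adopted from the published accounting and
  the alternative divisor changes `eggs_after` by the factor `r/(r+1)`.
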