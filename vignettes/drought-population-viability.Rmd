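---
title: "Drought indices, drought-growth regression and population viability projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drought indices, drought-growth regression and population viability projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtpop)
```

## Overview

`droughtpop` links three pieces of machinery that population ecologists
usually wire together by hand: percentile-threshold drought indices from
monthly drought-severity series, mixed-effects regressions of annual
population growth on drought intensity, and a stochastic projection model
that converts the fitted drought effect into century-scale extinction
probabilities under drought-frequency scenarios. This vignette documents
the model, its assumptions, the parameters that matter, and the design
choices made where conventions were genuinely open.

## Drought classification and intensity indices

A month at a location is *in drought* when its severity value $q$ (a
standardized wetness scale, $-10$ dry to $+10$ wet) is strictly below the
location's threshold $\theta$: the 10th percentile of the location's
reference distribution of monthly values. Extreme-event analysis
conventionally defines "extreme" relative to the 10th/90th percentile of a
reference climate, which motivates the default; `percentile` is
configurable.

Numerical conventions that the definition leaves open, and the choices made
here:

* **Percentile interpolation.** Linear interpolation between order
  statistics (R's default `type = 7`), configurable through `type`. On the
  series $1, 2, \dots, 100$ the 10th percentile is 10.9.
* **Reference distribution.** All non-missing months of the location's own
  record within `reference_period` (default: the full series). Spatial
  pooling across locations is *not* performed: drought is relative to the
  local climatology. At least 120 reference months (ten years) are
  required, configurable via `min_months`.
* **Ties at the threshold.** Strict inequality $q < \theta$; a month
  exactly at $\theta$ is not in drought.
* **Missing months** are excluded from threshold estimation; for index
  computation they count as non-drought but are reported, and a year with
  more than `max_missing = 3` missing months yields absent (`NA`) indices
  rather than misleadingly small ones.

Annual indices per location-year: $T$ (total drought months of the year,
0–12), $C$ (maximum consecutive drought months, 0–12), and $T_{t2}$,
$C_{t2}$ over the 24-month window spanning the preceding and focal
calendar years (0–24). A consecutive run may cross the December/January
boundary — this is the only reading under which $C_{t2}$ differs from
$\max(C_{\text{prev}}, C_{\text{cur}})$. A year is a *drought year* iff
$T \ge 1$. When the preceding year is absent the two-year indices are
absent, not zero.

The "modal PDSI" of twelve continuous values is ill-defined as stated;
`annual_summary_pdsi()` computes the mode of one-decimal-rounded values
and breaks ties toward the lower (drier) value.

Grid cells (`grid_cell_lookup()`) are half-open and lower-edge inclusive
with origin $(-90, -180)$ and 2.5° edges; the north pole and antimeridian
clamp into the last cell, so every valid coordinate maps to exactly one
cell.

## Growth rates and census-quality filters

Annual log growth $r_t = \ln(N_{t+1}/N_t)$ is computed only for censuses
in consecutive calendar years; any gap produces no observation. Filters:

* **Species sample size:** a species is retained only with strictly more
  than 20 pooled growth observations.
* **Initial abundance:** populations whose first census is below the
  species' herd-size range are dropped whole. "Below the range" is
  ambiguous; the package compares against the range's *lower bound* (the
  most permissive consistent reading) by default, with a midpoint option.
* **Physiological maximum:** observations with
  $r > \ln(1 + f_{\max})$ — the all-female, maximum-fecundity,
  no-mortality bound, with $f_{\max}$ the species' maximum offspring per
  female per year — are removed; the rule is one-sided.
* **Zero abundances** make $r$ undefined; such pairs are skipped with a
  warning rather than aborting a run.
* Exclusions that rest on metadata judgement (heavy management, poaching,
  mixed survey methods) are not inferred by the package; they should be
  applied to the input records by the analyst.

Drought covariates attach to the growth interval $t \to t+1$ as the
indices of calendar year $t$ — drought during the interval's first year.
The alternative anchoring (the year before the interval) is one join key
away; the package fixes the former and documents it rather than exposing a
knob that silently changes the science.

Life-history groups cross movement and diet: sedentary species cannot
escape local drought (S vs M), grazers and mixed feeders depend wholly or
partly on drought-intolerant forage (G vs B, the latter including
omnivores): SG, SB, MG, MB.

## The mixed model

`fit_drought_response()` fits
$r = \alpha + b\,x + u_{\text{location}} + v_{\text{species}} +
\varepsilon$ with crossed random intercepts, by maximum likelihood (not
REML, so single-predictor fits on the same data are comparable), via
`lme4`. Random slopes are not included — the random-effects structure is
deliberately the simplest one consistent with "location and species as
random effects". p-values are Wald $z$ on the fixed slope; with the
sample sizes this analysis needs (hundreds of observations) the df
correction debate is immaterial. Groups containing a single species (or a
single location) drop the unidentifiable random term with a message.

Index choice: $C$, $T$ and their two-year variants are strongly
rank-correlated by construction, so model comparison between them is
reported (`compare_indices()`) but the projection default is $C$, the
index matching the standard definition of a drought *event*; this is an
explicit argument, not a hidden rule.

## The projection model

Abundance follows $N_{t+1} = N_t e^{R_t}$, $R_t = a + b D_t$, with $D_t$
the drought months of year $t$ drawn from a two-state Markov generator:

* the first year is in drought with probability `p_init` (the *initial
  threshold*);
* a drought year is followed by a drought year with probability `ddt`, a
  non-drought year by a non-drought year with probability `nddt`;
* every drought year draws its length (months, support 1–12) afresh from
  the empirical distribution of $C$ over observed drought years.

Estimation (`estimate_markov_params()`) counts transitions only within a
location and only between consecutive calendar years.

The intercept $a$ is the drought-free growth rate, yet it is estimated
from observed growth: by default the mean $r$ over observations with
$C = 0$; when fewer than five drought-free observations exist the overall
mean $r_{av}$ is used with a warning (`estimate_intercept()` exposes both
modes). `calibrate_intercept()` instead solves
$a = \ln\lambda^\ast - b\,\mathbb{E}[D]$ for a target mean growth
multiplier $\lambda^\ast$, with $\mathbb{E}[D]$ the stationary expected
drought months — used when calibrating to a published species-level
$\lambda$.

**Scenarios.** `20C` leaves the generator alone; `B1` doubles and `A2`
triples drought occurrence as a step change at 2025 and 2040 respectively
("detectable by" those years). A doubling/tripling of *occurrence* is
implemented as a rescaling of the stationary drought-year frequency
$\pi = p_{\text{enter}}/(p_{\text{enter}} + p_{\text{exit}})$ through the
entry probability only: $\pi' = \min(m\pi, 0.95)$ and
$p_{\text{enter}}' = \min\!\big(\pi' p_{\text{exit}}/(1-\pi'),\, 1\big)$.
Drought persistence `ddt` and the length distribution are untouched —
droughts become more frequent, not longer. The 0.95 cap keeps the chain
ergodic; when a requested multiple would exceed it (or push
$p_{\text{enter}}$ past 1) the achieved frequency saturates below the
nominal multiple, which the user can check with
`stationary_drought_frequency()`. Medium-length droughts are assumed to
scale like short ones.

**Simulation.** 5000 replicates (default) from the population's first
census to 2099. A replicate is extinct in the first year $N \le 5$
individuals and is absorbed there — no rescue or recolonisation.
Abundance is a continuous state (this is a scalar geometric-growth model,
not an individual-based one; rounding would add artificial extinction at
small $N$). Per replicate, $\lambda_i = \exp(\bar R)$ over the years
realised before extinction or the horizon; reported are the mean and SD of
$\lambda_i$ over replicates and $E$, the fraction extinct by the horizon.
Species-level summaries average populations without weights; the SD
reported is the across-replicate SD averaged over populations (across-year
and across-population alternatives exist but are not what a
"λ (SD) per species" table shape implies).

**RNG.** One seed in `simulation_config()` governs a single stream from
which replicate-vectorised draws are made, giving bit-reproducibility for
a fixed `(seed, n_sims)`. Per-replicate independent substreams (results
order-independent in `n_sims`) were considered and rejected: base R lacks
a lightweight substream API, and reproducibility of the published ensemble
size is what matters here.

## Validation

* `r_squared_fit()`: per *replicate*, the squared Pearson correlation
  between observed and simulated abundance at matching years, summarised
  as mean and SD over replicates (fitting against the replicate-wise
  trajectories, not the ensemble mean, is what makes an SD meaningful).
  Being a squared correlation it is invariant to affine rescaling of
  either series and blind to sign — documented, not hidden.
* `pseudomedian_ci()`: Hodges–Lehmann pseudomedian (median of all Walsh
  averages) with the signed-rank confidence interval, exact for
  $n \le 25$ without ties, normal approximation otherwise (with heavy
  ties — run lengths are small integers — the interval is approximate by
  construction).
* `episode_length_check()`: observed versus simulated drought and
  non-drought episode lengths, each as pseudomedian + 95% CI, passing
  when both pairs of intervals overlap. Applying a two-sample location
  test to unpaired observed/simulated runs would be the obvious
  alternative; the one-sample-CI-overlap form is kept because it matches
  how such checks are conventionally reported (a pseudomedian and CI per
  sample).

## The synthetic world

Real abundance records of the kind this analysis consumes are confidential
database extracts, so the package generates a synthetic analogue with
known ground truth (`generate_world()`):

* **Monthly severity series:** stationary AR(1) per location
  ($\phi = 0.85$ monthly, innovation SD 1.05, hence marginal SD ≈ 2),
  independent across locations. AR(1) is the simplest process with
  PDSI-like persistence; $\phi$ is configurable so the implied
  drought-episode structure can be tuned (at the defaults, episode-length
  pseudomedians sit near the 2-year drought / 3-year break pattern typical
  of semi-arid records).
* **Traits:** 12 species covering all four life-history groups, herd
  sizes and offspring caps plausible for ungulates.
* **Abundance records:** 71 populations, censuses 1970–2005; log-abundance
  random walk with drift $a_{\text{sp}} + b_{\text{group}} C_{t}$ plus
  location and species intercepts (SD 0.02 each) and residual SD 0.05;
  multiplicative log-normal observation noise (SD 0.05, a typical survey
  CV); censuses dropped independently with probability 0.2. Default true
  slopes: SG $-0.04$, SB $-0.01$, MG $0.001$, MB $0$ — a strong effect in
  the drought-sensitive group, nulls elsewhere.

What the synthetic world does **not** emulate: spatial correlation between
grid cells, observation-noise autocorrelation, density dependence,
management interventions, or real PDSI climatology. A green test on
synthetic data therefore establishes that the *machinery* is correct
(definitions, filters, estimators, simulator), not that any particular
real-world effect size is right.

Note one deliberate mismatch between generator and estimator: observation
noise on abundance induces negatively correlated errors in successive
growth rates, which the independent-error mixed model ignores. At the
default noise scale this makes the slope's Wald CI mildly conservative —
parameter-recovery tests pass *because* of honest slack, not in spite of
it.

## Numerical and degenerate-input choices

* Thresholds refuse locations with fewer than the floor of reference
  months, naming the location and count.
* `run_length_stats()` with no drought years reports an absent (not zero)
  recurrence interval; Markov estimation refuses sequences with no
  transitions out of a state, naming the state.
* Noise-free regressions are recovered exactly (singular-fit warnings from
  the optimiser are tolerated deliberately).
* Extinction at exactly the threshold ($N = 5$) counts as extinct
  ($\le$, not $<$).
* All Monte-Carlo tests use fixed seeds and tolerances stated in absolute
  terms where the check is an absolute band.

## Known limitations

The projection model is deliberately simple: exponential growth with no
density dependence, age/sex structure, predation, dispersal or disease;
drought is assumed to be the sole driver acting on growth. Extinction
probabilities should be read comparatively (across scenarios, species,
initial sizes), not as absolute forecasts. The scenario machinery reshapes
drought *frequency* only; intensification of individual droughts (longer
or deeper episodes) would require modifying `ddt` or the length
distribution, which the data structures allow but no scenario preset does.
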