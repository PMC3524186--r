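# droughtpop

Drought indices, drought–growth regression and stochastic population
viability projections for ungulates in arid and semi-arid environments.

## The problem

Herbivore populations in arid and semi-arid regions are strongly limited by
resource availability, and droughts — expected to become markedly more
frequent over the 21st century — can depress their growth enough to drive
local extinction. `droughtpop` is for quantitative ecologists who want to
(i) measure a population's historical exposure to drought from a monthly
drought-severity record, (ii) estimate how strongly drought intensity
depresses annual population growth, and (iii) project abundance decades
ahead under drought-frequency scenarios to obtain extinction probabilities.

## The model

**Drought classification.** For each location, a month is in drought when
its Palmer Drought Severity Index value *q* (standardized −10 dry … +10
wet) falls strictly below θ, the 10th percentile of the location's
reference distribution. A year is a *drought year* if it contains at least
one such month. Annual intensity indices: *T* = total drought months of the
year, *C* = maximum consecutive drought months, and *T*<sub>t2</sub>,
*C*<sub>t2</sub>, the same over the 24-month window ending with the year.

**Drought response.** Annual log growth rates
*r*<sub>t</sub> = ln(*N*<sub>t+1</sub>/*N*<sub>t</sub>) from
consecutive-year censuses are regressed on a drought index with linear
mixed-effects models (crossed random intercepts for population location and
species, ML), pooled and within four life-history groups from the
movement × diet cross (sedentary/mobile × grazer-mixed/browser-omnivore:
SG, SB, MG, MB). The fixed slope *b* is the per-drought-month change in
log growth.

**Projection.** Abundance follows stochastic exponential growth,

> *N*<sub>t+1</sub> = *N*<sub>t</sub> · exp(*R*<sub>t</sub>),
> *R*<sub>t</sub> = *a* + *b·D*<sub>t</sub>,

where *a* is the drought-free log growth rate (estimated from observed
drought-free years) and *D*<sub>t</sub> is the year's drought months, drawn
from a two-state Markov generator: a year's drought status persists with
probability `ddt` (drought → drought) or `nddt` (non-drought →
non-drought), and drought years draw their length in months from the
empirical distribution of *C*. Scenarios `20C` (current conditions), `B1`
(drought frequency ×2 from 2025) and `A2` (×3 from 2040) rescale the
generator's stationary drought frequency through its entry probability.
Monte-Carlo ensembles (5000 replicates to 2099, extinction at *N* ≤ 5)
yield the mean annual growth multiplier λ and the extinction probability
*E*.

## Worked example

The package ships a synthetic-data generator with known ground truth (the
real abundance records this class of analysis uses are confidential), so
the whole pipeline runs out of the box:

```r
library(droughtpop)

world <- generate_world(synthetic_world_spec(seed = 42))  # true SG slope -0.04
fit <- fit_drought_response(world$observations, predictor = "C", group = "SG")
fit
#> Drought response fit  [group: SG]
#>   r ~ C + (1 | location_id) + (1 | species)  (ML, n = 405)
#>   slope b  = -0.03814  (SE 0.00228, Wald p = 5.282e-63)
#>   intercept = +0.05404
```

The fitted slope recovers the generating value −0.04: each additional
consecutive drought month costs about 3.8% of annual growth. Estimate the
drought generator from the SG locations' drought-year sequence and project
a small population under the three scenarios:

```r
sg_locs <- unique(world$observations$location_id[world$observations$group == "SG"])
mk <- estimate_markov_params(world$indices[world$indices$location_id %in% sg_locs, ])
a  <- estimate_intercept(world$observations[world$observations$group == "SG", ])
params <- simulator_params("species_01", a = a, b = fit$slope, markov = mk)

for (scn in c("20C", "B1", "A2")) {
  pr <- project_population(50, 1970, params, scenario_spec(scn),
                           simulation_config(n_sims = 5000, rng_seed = 1,
                                             store_trajectories = FALSE))
  cat(sprintf("%s: lambda %.4f (SD %.4f)  E = %.3f\n",
              scn, pr$lambda_mean, pr$lambda_sd, pr$E))
}
#> 20C: lambda 1.0076 (SD 0.0070)  E = 0.002
#> B1: lambda 0.9913 (SD 0.0066)  E = 0.104
#> A2: lambda 0.9945 (SD 0.0067)  E = 0.042
```

Under current conditions this population grows slowly (λ ≈ 1.008) and
essentially never goes extinct by 2099; doubling or tripling drought
frequency pushes mean growth below replacement and raises the century-end
extinction probability to 4–10% (B1 exceeds A2 here because its onset is
fifteen years earlier). Validation helpers ([`r_squared_fit()`],
[`pseudomedian_ci()`], [`episode_length_check()`]) check the model against
the observed record.

## Acceptance script

`scripts/acceptance.R` re-runs the projection model from scratch with the
installed package: it builds the sedentary-grazer drought generator,
calibrates the growth intercept to target mean growth multipliers of 0.92
(a declining, waterbuck-like population) and 1.05 (a growing, buffalo-like
one), projects 5000 replicates from N₀ = 1000 in 1970 to 2099 with
extinction at N ≤ 5, and writes the resulting extinction probabilities to
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/drought-population-viability.Rmd`)
describes the model, its assumptions, the tunable parameters, what the
synthetic world does and does not emulate, and the package's numerical and
design choices.
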