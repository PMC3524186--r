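#' Drought-frequency scenario
#'
#' Three scenarios for 21st-century drought occurrence: `20C`, continuation
#' of current conditions; `B1`, a doubling of drought occurrence detectable
#' by 2025; `A2`, a tripling detectable by 2040. Medium-length droughts are
#' assumed to scale like short ones, so the multiplier acts on the
#' stationary drought-year frequency of the Markov generator as a step
#' change at the onset year.
#'
#' @param name `"20C"`, `"B1"` or `"A2"`.
#' @return list of class `scenario_spec` with `name`, `onset_year`,
#'   `occurrence_multiplier`.
#' @export
scenario_spec <- function(name = c("20C", "B1", "A2")) {
  name <- match.arg(name)
  spec <- switch(name,
    "20C" = list(onset_year = NA_integer_, occurrence_multiplier = 1),
    "B1"  = list(onset_year = 2025L, occurrence_multiplier = 2),
    "A2"  = list(onset_year = 2040L, occurrence_multiplier = 3)
  )
  structure(c(list(name = name), spec), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %s: drought frequency x%g%s\n", x$name,
              x$occurrence_multiplier,
              if (is.na(x$onset_year)) "" else
                sprintf(" from %d onward", x$onset_year)))
  invisible(x)
}

#' Apply a drought scenario to Markov parameters at a given year
#'
#' Before the scenario's onset year the generator is unchanged. From the
#' onset year onward the stationary drought-year frequency
#' `pi = p_enter / (p_enter + p_exit)` (with `p_enter = 1 - nddt`,
#' `p_exit = 1 - ddt`) is rescaled to `pi' = min(m * pi, 0.95)` by solving
#' for a new entry probability `p_enter' = pi' * p_exit / (1 - pi')`
#' (capped at 1), i.e. only `nddt` changes; drought persistence `ddt` and
#' the within-drought length distribution are left alone. The 0.95 cap
#' keeps the chain ergodic.
#'
#' @param markov a [markov_params()] object.
#' @param scenario a [scenario_spec()].
#' @param year calendar year being simulated.
#' @return a [markov_params()] object (possibly the input unchanged).
#' @examples
#' m <- markov_params(0.3, 0.5, 0.8)
#' apply_scenario(m, scenario_spec("B1"), 2050)  # nddt drops to 1/3
#' @export
apply_scenario <- function(markov, scenario, year) {
  stopifnot(inherits(markov, "markov_params"),
            inherits(scenario, "scenario_spec"))
  m <- scenario$occurrence_multiplier
  if (m == 1 || is.na(scenario$onset_year) || year < scenario$onset_year) {
    return(markov)
  }
  p_enter <- 1 - markov$nddt
  p_exit <- 1 - markov$ddt
  pi0 <- p_enter / (p_enter + p_exit)
  pi1 <- min(m * pi0, 0.95)
  p_enter1 <- min(pi1 * p_exit / (1 - pi1), 1)
  markov_params(p_init = markov$p_init, ddt = markov$ddt,
                nddt = 1 - p_enter1, length_dist = markov$length_dist)
}

#' Stationary drought-year frequency of the generator
#'
#' Closed form for the two-state chain: `(1 - nddt) / ((1 - nddt) + (1 - ddt))`.
#'
#' @param markov a [markov_params()] object.
#' @return stationary probability that a year is a drought year.
#' @export
stationary_drought_frequency <- function(markov) {
  p_enter <- 1 - markov$nddt
  p_exit <- 1 - markov$ddt
  if (p_enter + p_exit == 0) {
    stop("chain with ddt = nddt = 1 has no unique stationary distribution",
         call. = FALSE)
  }
  p_enter / (p_enter + p_exit)
}

#' Expected drought months per year at stationarity
#'
#' `E[D] = pi * E[C | drought]` under the generator's stationary
#' distribution; used to calibrate the drought-free intercept `a` towards a
#' target mean growth multiplier.
#'
#' @param markov a [markov_params()] object (needs `length_dist`).
#' @return expected value of the annual drought-month draw `D`.
#' @export
expected_drought_months <- function(markov) {
  if (is.null(markov$length_dist)) {
    stop("markov parameters carry no drought-length distribution",
         call. = FALSE)
  }
  stationary_drought_frequency(markov) * sum((1:12) * markov$length_dist)
}

#' Choose the intercept a that yields a target mean growth multiplier
#'
#' The modelled annual growth rate is `R = a + b * D`. At stationarity the
#' per-replicate geometric-mean growth multiplier concentrates on
#' `exp(a + b * E[D])`, so `a = log(target_lambda) - b * E[D]` calibrates
#' the simulator to a species' observed mean growth multiplier.
#'
#' @param target_lambda target mean annual multiplier (e.g. 0.92).
#' @param b drought-effect slope (log-rate per drought month).
#' @param markov a [markov_params()] object.
#' @return the intercept `a` (annual log growth in the absence of drought,
#'   shifted for the stationary drought load).
#' @export
calibrate_intercept <- function(target_lambda, b, markov) {
  stopifnot(target_lambda > 0, is.finite(b))
  log(target_lambda) - b * expected_drought_months(markov)
}

#' Simulator parameters for one species
#'
#' @param species species label.
#' @param a drought-free annual log growth rate. Estimated from data as the
#'   mean observed `r` over drought-free years (see [estimate_intercept()]).
#' @param b per-drought-month effect on log growth (slope of the fitted
#'   [fit_drought_response()] model for the species' group).
#' @param markov a [markov_params()] object with a length distribution.
#' @return list of class `simulator_params`.
#' @export
simulator_params <- function(species, a, b, markov) {
  stopifnot(is.finite(a), is.finite(b), inherits(markov, "markov_params"))
  if (is.null(markov$length_dist)) {
    stop("projection requires a drought-length distribution", call. = FALSE)
  }
  structure(list(species = species, a = a, b = b, markov = markov),
            class = "simulator_params")
}

#' Estimate the drought-free intercept a from observed growth rates
#'
#' The drought-free growth rate of a species is estimated as the mean
#' observed `r` over observations with no drought exposure (`C = 0`). When
#' fewer than `min_drought_free` such observations exist the estimate falls
#' back to the overall mean `r` (the paper-style `r_av`), with a warning.
#'
#' @param observations growth observations (with `C`) for one species.
#' @param min_drought_free minimum drought-free sample size (default 5).
#' @param mode `"drought_free"` (default) or `"overall"` to force `r_av`.
#' @return scalar estimate of `a`.
#' @export
estimate_intercept <- function(observations, min_drought_free = 5,
                               mode = c("drought_free", "overall")) {
  mode <- match.arg(mode)
  r <- observations$r[!is.na(observations$r)]
  if (mode == "overall") return(mean(r))
  free <- observations$r[!is.na(observations$r) & !is.na(observations$C) &
                           observations$C == 0]
  if (length(free) < min_drought_free) {
    warning("only ", length(free), " drought-free observation(s); ",
            "falling back to the overall mean growth rate", call. = FALSE)
    return(mean(r))
  }
  mean(free)
}

#' Simulation configuration
#'
#' @param n_sims number of Monte-Carlo replicates (default 5000).
#' @param end_year projection horizon (default 2099).
#' @param extinction_threshold abundance at or below which a population is
#'   extinct (default 5 individuals).
#' @param rng_seed optional integer seed set before simulating.
#' @param store_trajectories keep the full replicate-by-year abundance and
#'   drought matrices (default `TRUE`).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_sims = 5000, end_year = 2099,
                              extinction_threshold = 5, rng_seed = NULL,
                              store_trajectories = TRUE) {
  stopifnot(n_sims >= 1, extinction_threshold >= 0)
  structure(list(n_sims = as.integer(n_sims), end_year = as.integer(end_year),
                 extinction_threshold = extinction_threshold,
                 rng_seed = rng_seed,
                 store_trajectories = isTRUE(store_trajectories)),
            class = "simulation_config")
}

sample_drought_length <- function(markov, n) {
  sample.int(12L, size = n, replace = TRUE, prob = markov$length_dist)
}

#' Draw the initial annual drought state
#'
#' A uniform draw against the initial threshold `p_init` decides whether
#' the first simulated year is in drought; if so, the number of drought
#' months `D0` is sampled from the drought-length distribution, otherwise
#' `D0 = 0`.
#'
#' @param markov a [markov_params()] object with a length distribution.
#' @param n number of independent draws.
#' @return integer vector of length `n` with values in `{0, 1..12}`.
#' @export
sample_initial_drought <- function(markov, n = 1) {
  stopifnot(inherits(markov, "markov_params"))
  in_drought <- runif(n) < markov$p_init
  d <- integer(n)
  if (any(in_drought)) {
    d[in_drought] <- sample_drought_length(markov, sum(in_drought))
  }
  d
}

#' Advance the annual drought state one year
#'
#' From a drought year (`D > 0`) the chain stays in drought with
#' probability `ddt`; from a non-drought year it stays out with probability
#' `nddt`. Every drought year draws a fresh length from the drought-length
#' distribution.
#'
#' @param D integer vector of current states (0 or 1..12).
#' @param markov a [markov_params()] object with a length distribution.
#' @return integer vector of next-year states.
#' @export
step_drought <- function(D, markov) {
  stopifnot(all(D %in% 0:12))
  u <- runif(length(D))
  next_drought <- ifelse(D > 0, u < markov$ddt, u >= markov$nddt)
  d <- integer(length(D))
  if (any(next_drought)) {
    d[next_drought] <- sample_drought_length(markov, sum(next_drought))
  }
  d
}

#' Simulate an annual drought sequence
#'
#' Runs the generator forward for `n_years`, optionally applying a
#' scenario's frequency modification year by year.
#'
#' @param markov a [markov_params()] object with a length distribution.
#' @param n_years sequence length.
#' @param start_year calendar year of the first state (used for scenario
#'   onset timing).
#' @param scenario a [scenario_spec()]; default continuation of current
#'   conditions.
#' @return integer vector of length `n_years` of drought months per year.
#' @export
simulate_drought_sequence <- function(markov, n_years, start_year = 1970,
                                      scenario = scenario_spec("20C")) {
  # the scenario is a step change, so only two parameter sets ever occur
  onset <- scenario$onset_year
  m_post <- if (is.na(onset)) markov else apply_scenario(markov, scenario,
                                                         onset)
  at_year <- function(year) {
    if (is.na(onset) || year < onset) markov else m_post
  }
  D <- integer(n_years)
  D[1] <- sample_initial_drought(at_year(start_year), 1)
  if (n_years > 1) {
    for (i in 2:n_years) {
      D[i] <- step_drought(D[i - 1], at_year(start_year + i - 1L))
    }
  }
  D
}

#' Annual growth update under drought forcing
#'
#' `N[t+1] = N[t] * exp(a + b * D[t])`: scalar geometric growth with the
#' year's drought months `D` acting on the log rate. Abundance is a
#' continuous state; no demographic rounding is applied.
#'
#' @param N current abundance (vectorised).
#' @param params a [simulator_params()] object (or any list with `a`, `b`).
#' @param D drought months of the year (vectorised).
#' @return next-year abundance.
#' @export
growth_step <- function(N, params, D) {
  stopifnot(all(N >= 0))
  N * exp(params$a + params$b * D)
}

#' Monte-Carlo projection of one population
#'
#' Projects a population from its first census to the horizon with the
#' stochastic drought-forced growth model. Each replicate draws an initial
#' drought state, then alternates [step_drought()] (with the scenario's
#' frequency modification from its onset year) and [growth_step()]. A
#' replicate becomes extinct in the first year its abundance is at or below
#' the extinction threshold and is absorbed there. The per-replicate growth
#' summary is the geometric-mean annual multiplier
#' `lambda_i = exp(mean R_t)` over the years realised before extinction (or
#' the whole horizon); `E` is the fraction of replicates extinct by the
#' horizon.
#'
#' @param N0 initial abundance (must exceed the extinction threshold).
#' @param start_year calendar year of the initial abundance.
#' @param params a [simulator_params()] object.
#' @param scenario a [scenario_spec()].
#' @param config a [simulation_config()].
#' @return object of class `population_projection`: list with
#'   `lambda_mean`, `lambda_sd`, `E`, per-replicate `lambda`, `extinct`,
#'   `extinction_year`, `years`, and (if stored) `trajectories` and `D`
#'   matrices of dimension `n_sims x length(years)`.
#' @examples
#' m <- markov_params(0.4, 0.5, 0.71, c(rep(1/6, 6), rep(0, 6)))
#' p <- simulator_params("waterbuck-like", a = calibrate_intercept(0.92, -0.04, m),
#'                       b = -0.04, markov = m)
#' proj <- project_population(1000, 1970, p,
#'                            config = simulation_config(n_sims = 100,
#'                                                       rng_seed = 1))
#' proj$E
#' @export
project_population <- function(N0, start_year, params,
                               scenario = scenario_spec("20C"),
                               config = simulation_config()) {
  stopifnot(inherits(params, "simulator_params"),
            inherits(config, "simulation_config"))
  if (!is.finite(N0) || N0 <= config$extinction_threshold) {
    stop("initial abundance must exceed the extinction threshold",
         call. = FALSE)
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  n <- config$n_sims
  years <- start_year:config$end_year
  n_steps <- length(years) - 1L
  if (n_steps < 1) stop("end_year must exceed start_year", call. = FALSE)

  keep <- config$store_trajectories
  if (keep) {
    traj <- matrix(NA_real_, nrow = n, ncol = length(years),
                   dimnames = list(NULL, years))
    dmat <- matrix(NA_integer_, nrow = n, ncol = length(years),
                   dimnames = list(NULL, years))
  }

  N <- rep(N0, n)
  alive <- rep(TRUE, n)
  ext_year <- rep(NA_integer_, n)
  sumR <- numeric(n)
  nR <- integer(n)
  D <- sample_initial_drought(apply_scenario(params$markov, scenario,
                                             start_year), n)
  if (keep) { traj[, 1] <- N; dmat[, 1] <- D }

  for (i in seq_len(n_steps)) {
    yr_next <- years[i + 1L]
    R <- params$a + params$b * D
    N_new <- ifelse(alive, N * exp(R), N)
    sumR[alive] <- sumR[alive] + R[alive]
    nR[alive] <- nR[alive] + 1L
    newly_dead <- alive & N_new <= config$extinction_threshold
    ext_year[newly_dead] <- yr_next
    alive <- alive & !newly_dead
    N <- N_new
    if (i < n_steps || keep) {
      D <- step_drought(D, apply_scenario(params$markov, scenario, yr_next))
    }
    if (keep) { traj[, i + 1L] <- N; dmat[, i + 1L] <- D }
  }

  lambda <- exp(sumR / pmax(nR, 1L))
  out <- list(
    species = params$species,
    start_year = start_year,
    years = years,
    scenario = scenario$name,
    n_sims = n,
    lambda = lambda,
    lambda_mean = mean(lambda),
    lambda_sd = sd(lambda),
    extinct = !alive,
    extinction_year = ext_year,
    E = mean(!alive)
  )
  if (keep) { out$trajectories <- traj; out$D <- dmat }
  structure(out, class = "population_projection")
}

#' @export
print.population_projection <- function(x, ...) {
  cat(sprintf("Population projection [%s, scenario %s]\n",
              x$species, x$scenario))
  cat(sprintf("  %d replicates, %d-%d\n", x$n_sims, x$start_year,
              max(x$years)))
  cat(sprintf("  lambda = %.4f (SD %.4f)\n", x$lambda_mean, x$lambda_sd))
  cat(sprintf("  extinction probability E = %.4f\n", x$E))
  invisible(x)
}

#' Species-level summary over population projections
#'
#' Unweighted means over populations of the per-population mean growth
#' multiplier, its across-replicate SD, and the extinction probability —
#' the shape of a species row in a scenario summary table.
#'
#' @param projections list of `population_projection` objects for one
#'   species.
#' @return one-row tibble `species, scenario, n_populations, lambda_mean,
#'   lambda_sd, E`.
#' @export
summarize_species <- function(projections) {
  stopifnot(length(projections) >= 1,
            all(vapply(projections, inherits, logical(1),
                       "population_projection")))
  tibble::tibble(
    species = projections[[1]]$species,
    scenario = projections[[1]]$scenario,
    n_populations = length(projections),
    lambda_mean = mean(vapply(projections, `[[`, numeric(1), "lambda_mean")),
    lambda_sd = mean(vapply(projections, `[[`, numeric(1), "lambda_sd")),
    E = mean(vapply(projections, `[[`, numeric(1), "E"))
  )
}
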