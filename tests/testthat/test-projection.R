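test_that("initial drought state honours the initial threshold", {
  never <- markov_params(0, 0.5, 0.5, c(rep(1 / 6, 6), rep(0, 6)))
  set.seed(1)
  expect_true(all(sample_initial_drought(never, 500) == 0))

  always3 <- markov_params(1, 0.5, 0.5, c(0, 0, 1, rep(0, 9)))
  expect_true(all(sample_initial_drought(always3, 500) == 3))

  m <- markov_params(0.4, 0.5, 0.71, c(rep(1 / 6, 6), rep(0, 6)))
  set.seed(2)
  d <- sample_initial_drought(m, 10000)
  expect_lt(abs(mean(d > 0) - 0.40), 0.02)
  expect_true(all(d %in% 0:6))
})

test_that("drought stepping follows the distance thresholds", {
  absorb_d <- markov_params(0.5, 1, 0.5, c(rep(1 / 6, 6), rep(0, 6)))
  set.seed(3)
  expect_true(all(step_drought(rep(3L, 500), absorb_d) > 0))

  absorb_n <- markov_params(0.5, 0.5, 1, c(rep(1 / 6, 6), rep(0, 6)))
  expect_true(all(step_drought(rep(0L, 500), absorb_n) == 0))

  # long-run drought-year frequency matches the two-state stationary form
  m <- markov_params(0.4, 0.5, 0.8, c(rep(1 / 6, 6), rep(0, 6)))
  expect_equal(stationary_drought_frequency(m), 0.2 / 0.7)
  set.seed(4)
  d <- simulate_drought_sequence(m, 1e5)
  expect_lt(abs(mean(d > 0) - 0.2 / 0.7), 0.01)
})

test_that("simulated run lengths are geometric with the implied means", {
  m <- markov_params(0.4, 0.5, 2 / 3, c(rep(1 / 6, 6), rep(0, 6)))
  set.seed(5)
  d <- simulate_drought_sequence(m, 6e4)
  rl <- run_length_stats(d > 0)
  # interior runs only (first/last are censored) -- at this length the
  # censoring bias is negligible
  expect_equal(mean(rl$drought_run_lengths), 1 / (1 - m$ddt),
               tolerance = 0.05)
  expect_equal(mean(rl$nondrought_run_lengths), 1 / (1 - m$nddt),
               tolerance = 0.05)
  # chi-square goodness of fit against the geometric law, 1% level
  gof <- function(lengths, p_stay) {
    k <- pmin(lengths, 8)
    obs <- tabulate(k, nbins = 8)
    probs <- dgeom(0:6, prob = 1 - p_stay)
    probs <- c(probs, 1 - sum(probs))
    suppressWarnings(stats::chisq.test(obs, p = probs)$p.value)
  }
  expect_gt(gof(rl$drought_run_lengths, m$ddt), 0.01)
  expect_gt(gof(rl$nondrought_run_lengths, m$nddt), 0.01)
})

test_that("scenario rescaling follows the stationary-frequency algebra", {
  m <- markov_params(0.3, 0.5, 0.8, c(rep(1 / 6, 6), rep(0, 6)))
  # identity scenario and pre-onset years leave parameters untouched
  expect_identical(apply_scenario(m, scenario_spec("20C"), 2098), m)
  expect_identical(apply_scenario(m, scenario_spec("B1"), 2024), m)

  # worked doubling: pi 2/7 -> 4/7, p_enter' = 2/3, nddt' = 1/3
  b1 <- apply_scenario(m, scenario_spec("B1"), 2025)
  expect_equal(b1$nddt, 1 / 3, tolerance = 1e-12)
  expect_equal(b1$ddt, m$ddt)
  expect_equal(b1$length_dist, m$length_dist)
  expect_equal(stationary_drought_frequency(b1),
               2 * stationary_drought_frequency(m))

  # a large multiplier caps the stationary frequency at 0.95
  m2 <- markov_params(0.3, 0.96, 0.9, c(rep(1 / 6, 6), rep(0, 6)))
  big <- apply_scenario(m2, scenario_spec("A2"), 2050)
  expect_equal(stationary_drought_frequency(big), 0.95)
  expect_equal(big$nddt, 1 - 0.95 * 0.04 / 0.05)

  # and the entry probability itself never exceeds 1
  m3 <- markov_params(0.3, 0.1, 0.2, c(rep(1 / 6, 6), rep(0, 6)))
  capped <- apply_scenario(m3, scenario_spec("A2"), 2050)
  expect_equal(capped$nddt, 0)
  expect_equal(stationary_drought_frequency(capped), 1 / 1.9)
})

test_that("growth step is exact exponential growth in drought forcing", {
  p <- simulator_params("x", a = 0, b = -0.04, markov = test_markov())
  expect_equal(growth_step(100, p, 5), 100 * exp(-0.2))
  expect_equal(growth_step(100, p, 0), 100)  # D = 0: factor e^a only
  p2 <- simulator_params("x", a = log(1.03), b = 0, markov = test_markov())
  expect_equal(growth_step(c(10, 20), p2, c(7, 0)), c(10, 20) * 1.03)
})

test_that("deterministic decay and growth bracket the extinction outcomes", {
  m <- test_markov()
  # b = 0 removes drought forcing entirely: closed-form geometric decline
  dec <- simulator_params("decline", a = log(0.92), b = 0, markov = m)
  pr <- project_population(1000, 1970, dec,
                           config = simulation_config(n_sims = 50,
                                                      rng_seed = 6))
  expect_equal(pr$E, 1)
  expect_equal(pr$lambda_mean, 0.92)
  expect_equal(pr$lambda_sd, 0)
  # crossing year: smallest t with 1000 * 0.92^t <= 5
  t_cross <- ceiling(log(5 / 1000) / log(0.92))
  expect_true(all(pr$extinction_year == 1970 + t_cross))

  gro <- simulator_params("grow", a = log(1.05), b = 0, markov = m)
  pr2 <- project_population(1000, 1970, gro,
                            config = simulation_config(n_sims = 50,
                                                       rng_seed = 7))
  expect_equal(pr2$E, 0)
  expect_equal(pr2$lambda_mean, 1.05)

  # trajectories equal the closed form to 1e-9 relative error
  expect_equal(pr2$trajectories[1, ],
               setNames(1000 * 1.05^(0:129), 1970:2099),
               tolerance = 1e-9)
})

test_that("projections are reproducible and extinction is absorbing", {
  m <- test_markov()
  p <- simulator_params("w", a = calibrate_intercept(0.92, -0.04, m),
                        b = -0.04, markov = m)
  cfg <- simulation_config(n_sims = 1, rng_seed = 42)
  a1 <- project_population(1000, 1970, p, config = cfg)
  a2 <- project_population(1000, 1970, p, config = cfg)
  expect_identical(a1$trajectories, a2$trajectories)
  expect_identical(a1$D, a2$D)

  cfg2 <- simulation_config(n_sims = 200, rng_seed = 43)
  pr <- project_population(1000, 1970, p, config = cfg2)
  # once a trajectory crosses the threshold it never moves again
  for (i in which(pr$extinct)) {
    traj <- pr$trajectories[i, ]
    k <- match(pr$extinction_year[i], pr$years)
    expect_true(all(traj[k:length(traj)] == traj[k]))
    expect_lte(traj[k], 5)
    expect_true(all(traj[seq_len(k - 1)] > 5))
  }
})

test_that("extinction probability is monotone in N0 and in a", {
  m <- test_markov()
  E_at <- function(N0, lam) {
    p <- simulator_params("x", a = calibrate_intercept(lam, -0.04, m),
                          b = -0.04, markov = m)
    project_population(N0, 1970, p,
                       config = simulation_config(n_sims = 300, rng_seed = 9,
                                                  store_trajectories = FALSE))$E
  }
  e_n <- sapply(c(10, 100, 1000), E_at, lam = 0.97)
  expect_true(all(diff(e_n) <= 0))
  e_a <- sapply(c(0.94, 0.97, 1.0, 1.03), function(l) E_at(100, l))
  expect_true(all(diff(e_a) <= 0))
})

test_that("initial abundance must exceed the extinction threshold", {
  m <- test_markov()
  p <- simulator_params("x", a = 0, b = 0, markov = m)
  expect_error(project_population(5, 1970, p), "exceed")
  expect_error(project_population(-1, 1970, p), "exceed")
})

test_that("species summaries average populations without weights", {
  m <- test_markov()
  mk <- function(lam, seed) {
    p <- simulator_params("sp", a = log(lam), b = 0, markov = m)
    project_population(1000, 1970, p,
                       config = simulation_config(n_sims = 20,
                                                  rng_seed = seed))
  }
  one <- mk(1.05, 1)
  expect_equal(summarize_species(list(one))$lambda_mean, one$lambda_mean)
  two <- summarize_species(list(mk(1.0, 2), mk(1.1, 3)))
  expect_equal(two$lambda_mean, 1.05)
  expect_equal(summarize_species(list(mk(0.9, 4), mk(1.1, 5)))$E, 0.5)
})

test_that("intercept calibration hits the target mean growth multiplier", {
  m <- test_markov()
  expect_equal(expected_drought_months(m),
               (0.29 / 0.79) * 3.5)
  a <- calibrate_intercept(0.92, -0.04, m)
  pr <- project_population(1000, 1970,
                           simulator_params("w", a, -0.04, m),
                           config = simulation_config(n_sims = 2000,
                                                      rng_seed = 10,
                                                      store_trajectories = FALSE))
  expect_equal(pr$lambda_mean, 0.92, tolerance = 0.005)
})
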