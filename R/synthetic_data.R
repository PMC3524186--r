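#' Specification of a synthetic study world
#'
#' Describes a synthetic analogue of the data the pipeline consumes:
#' monthly PDSI-like series on a coarse grid, an ungulate trait table, and
#' irregular yearly abundance censuses 1970-2005 whose growth is driven by
#' `a + b * C` plus random intercepts and noise. Defaults emulate the study
#' system: 12 species over the four life-history groups, ~70 populations in
#' southern/eastern African semi-arid grid cells, drought episodes lasting
#' about two years with three-year breaks, and an SG drought effect of
#' -0.04 per drought month.
#'
#' @param n_locations number of grid locations (default 12).
#' @param n_species number of species (default 12).
#' @param n_populations number of populations (default 71).
#' @param years calendar years of the monthly series (default 1970:2005).
#' @param ar1_phi monthly AR(1) coefficient of the PDSI-like series
#'   (default 0.85, giving multi-month drought persistence).
#' @param innovation_sd AR(1) innovation SD (default 1.05, marginal SD
#'   around 2 on the -10..+10 scale).
#' @param b_group named vector of true drought slopes per life-history
#'   group (log growth per drought month).
#' @param a_range range from which species' drought-free log growth rates
#'   are drawn.
#' @param sd_location,sd_species SDs of the location and species random
#'   intercepts on `r` (default 0.02 each).
#' @param sd_resid residual SD of annual log growth (default 0.05).
#' @param obs_noise_sd multiplicative (log-normal) observation noise SD on
#'   abundance (default 0.05, a typical aerial-survey CV scale).
#' @param gap_prob probability each yearly census is independently missed
#'   (default 0.2, yielding irregular series).
#' @param n0_range range of initial true abundances.
#' @param seed integer RNG seed.
#' @return list of class `synthetic_world_spec`.
#' @export
synthetic_world_spec <- function(n_locations = 12, n_species = 12,
                                 n_populations = 71, years = 1970:2005,
                                 ar1_phi = 0.85, innovation_sd = 1.05,
                                 b_group = c(SG = -0.04, SB = -0.01,
                                             MG = 0.001, MB = 0),
                                 a_range = c(0.02, 0.12),
                                 sd_location = 0.02, sd_species = 0.02,
                                 sd_resid = 0.05, obs_noise_sd = 0.05,
                                 gap_prob = 0.2, n0_range = c(200, 2000),
                                 seed = 1L) {
  stopifnot(abs(ar1_phi) < 1, innovation_sd >= 0,
            all(c("SG", "SB", "MG", "MB") %in% names(b_group)),
            sd_location >= 0, sd_species >= 0, sd_resid >= 0,
            obs_noise_sd >= 0, gap_prob >= 0, gap_prob < 1,
            n0_range[1] > 0, n0_range[2] >= n0_range[1])
  structure(list(n_locations = n_locations, n_species = n_species,
                 n_populations = n_populations, years = years,
                 ar1_phi = ar1_phi, innovation_sd = innovation_sd,
                 b_group = b_group, a_range = a_range,
                 sd_location = sd_location, sd_species = sd_species,
                 sd_resid = sd_resid, obs_noise_sd = obs_noise_sd,
                 gap_prob = gap_prob, n0_range = n0_range,
                 seed = as.integer(seed)),
            class = "synthetic_world_spec")
}

#' Generate PDSI-like monthly drought-severity series
#'
#' One stationary AR(1) monthly series per location, independent across
#' locations, initialised from the stationary distribution. Locations are
#' scattered over a southern-African semi-arid window so that grid-cell
#' lookups behave like the real product.
#'
#' @param spec a [synthetic_world_spec()].
#' @return monthly series tibble (`location_id, lat, lon, year, month,
#'   pdsi`).
#' @export
generate_pdsi <- function(spec) {
  stopifnot(inherits(spec, "synthetic_world_spec"))
  set.seed(spec$seed)
  n_months <- length(spec$years) * 12L
  marg_sd <- spec$innovation_sd / sqrt(1 - spec$ar1_phi^2)
  lats <- runif(spec$n_locations, -30, -15)
  lons <- runif(spec$n_locations, 20, 35)
  series <- lapply(seq_len(spec$n_locations), function(i) {
    q <- numeric(n_months)
    q[1] <- rnorm(1, 0, marg_sd)
    eps <- rnorm(n_months - 1, 0, spec$innovation_sd)
    for (t in 2:n_months) q[t] <- spec$ar1_phi * q[t - 1] + eps[t - 1]
    tibble::tibble(
      location_id = sprintf("loc_%02d", i),
      lat = lats[i], lon = lons[i],
      year = rep(spec$years, each = 12L),
      month = rep(1:12, length(spec$years)),
      pdsi = q
    )
  })
  dplyr::bind_rows(series)
}

#' Generate an ungulate trait table
#'
#' Species are spread over the four movement x diet groups (at least one
#' per group), with herd-size ranges and offspring caps plausible for
#' medium-to-large ungulates (single offspring per female per year for
#' most, twinning allowed for a few smaller-bodied species).
#'
#' @param spec a [synthetic_world_spec()].
#' @return trait tibble `species, movement, diet, herd_size_min,
#'   herd_size_max, max_offspring_per_female_per_year` plus the derived
#'   `group` column.
#' @export
generate_traits <- function(spec) {
  stopifnot(inherits(spec, "synthetic_world_spec"))
  set.seed(spec$seed + 1L)
  n <- spec$n_species
  movement <- rep(c("sedentary", "sedentary", "non_sedentary",
                    "non_sedentary"), length.out = n)
  diet <- rep(c("grazer", "browser", "mixed", "omnivore"), length.out = n)
  herd_min <- sample(c(5L, 10L, 15L, 20L), n, replace = TRUE)
  traits <- tibble::tibble(
    species = sprintf("species_%02d", seq_len(n)),
    movement = movement,
    diet = diet,
    herd_size_min = herd_min,
    herd_size_max = herd_min * sample(3:10, n, replace = TRUE),
    max_offspring_per_female_per_year = sample(c(1L, 1L, 1L, 2L), n,
                                               replace = TRUE)
  )
  assign_group(traits)
}

#' Generate abundance records with known ground truth
#'
#' Populations are assigned to species and grid locations; each follows a
#' log-abundance random walk with drift `a_species + b_group * C` plus
#' location and species random intercepts and residual annual noise.
#' Observed abundances carry multiplicative log-normal observation noise,
#' and each yearly census is independently missed with the spec's gap
#' probability (the first year is always kept so initial abundance is
#' defined).
#'
#' @param spec a [synthetic_world_spec()].
#' @param indices annual drought indices for the spec's locations
#'   ([annual_drought_indices()]).
#' @param traits trait table from [generate_traits()].
#' @return list: `records` (abundance tibble), `truth` (list of the
#'   parameters actually used: `a_species`, `b_group`, `u_location`,
#'   `v_species`, and the per-population assignment table).
#' @export
generate_populations <- function(spec, indices, traits) {
  stopifnot(inherits(spec, "synthetic_world_spec"))
  set.seed(spec$seed + 2L)
  locs <- unique(indices$location_id)
  if (length(locs) < spec$n_locations) {
    stop("indices cover ", length(locs), " locations; spec expects ",
         spec$n_locations, call. = FALSE)
  }
  a_species <- setNames(runif(spec$n_species, spec$a_range[1],
                              spec$a_range[2]), traits$species)
  u_location <- setNames(rnorm(length(locs), 0, spec$sd_location), locs)
  v_species <- setNames(rnorm(spec$n_species, 0, spec$sd_species),
                        traits$species)

  assignment <- tibble::tibble(
    population_id = sprintf("pop_%03d", seq_len(spec$n_populations)),
    species = traits$species[rep(seq_len(spec$n_species),
                                 length.out = spec$n_populations)],
    location_id = sample(locs, spec$n_populations, replace = TRUE)
  )
  assignment$group <- as.character(
    traits$group[match(assignment$species, traits$species)])

  yrs <- spec$years
  records <- lapply(seq_len(nrow(assignment)), function(i) {
    pop <- assignment[i, ]
    idx <- indices[indices$location_id == pop$location_id, ]
    C <- idx$C[match(yrs, idx$year)]
    C[is.na(C)] <- 0L
    drift <- a_species[pop$species] + v_species[pop$species] +
      u_location[pop$location_id] +
      spec$b_group[pop$group] * C[-length(yrs)]
    r_true <- drift + rnorm(length(yrs) - 1, 0, spec$sd_resid)
    logN <- cumsum(c(log(runif(1, spec$n0_range[1], spec$n0_range[2])),
                     r_true))
    obs <- exp(logN + rnorm(length(yrs), 0, spec$obs_noise_sd))
    keep <- c(TRUE, runif(length(yrs) - 1) >= spec$gap_prob)
    tibble::tibble(
      population_id = pop$population_id,
      species = pop$species,
      location_id = pop$location_id,
      year = yrs[keep],
      abundance = obs[keep]
    )
  })
  records <- dplyr::bind_rows(records)
  list(
    records = records,
    truth = list(a_species = a_species, b_group = spec$b_group,
                 u_location = u_location, v_species = v_species,
                 assignment = assignment)
  )
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper running the whole synthetic pipeline: monthly PDSI
#' series, thresholds and annual indices, traits, abundance records, and
#' the growth observations joined to the drought indices (with the group
#' label attached) — everything needed to exercise the analysis end to end.
#'
#' @param spec a [synthetic_world_spec()].
#' @param percentile threshold percentile (default 10).
#' @return list `pdsi, thresholds, flags, indices, traits, records,
#'   observations, truth`.
#' @export
generate_world <- function(spec = synthetic_world_spec(), percentile = 10) {
  pdsi <- generate_pdsi(spec)
  # lat/lon travel alongside location_id; keep one coordinate per location
  thresholds <- compute_threshold(pdsi, percentile = percentile)
  flags <- flag_drought_months(pdsi, thresholds)
  indices <- annual_drought_indices(flags)
  traits <- generate_traits(spec)
  pops <- generate_populations(spec, indices, traits)
  coords <- pdsi |>
    dplyr::distinct(.data$location_id, .data$lat, .data$lon)
  records <- dplyr::left_join(pops$records, coords, by = "location_id")
  observations <- compute_growth_rates(records) |>
    join_drought(indices) |>
    dplyr::left_join(traits[, c("species", "group")], by = "species")
  list(pdsi = pdsi, thresholds = thresholds, flags = flags,
       indices = indices, traits = traits, records = records,
       observations = observations, truth = pops$truth)
}
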