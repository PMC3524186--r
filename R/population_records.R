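#' Per-year log growth rates from abundance time series
#'
#' Growth rates are only defined between censuses in consecutive calendar
#' years: `r[t] = log(N[t+1] / N[t])`. Pairs of records separated by a gap
#' of one or more missing years produce no observation. Pairs in which
#' either abundance is zero are skipped (the log is undefined) and counted
#' in a warning rather than failing the run.
#'
#' @param records data frame with columns `population_id`, `species`,
#'   `location_id`, `lat`, `lon`, `year`, `abundance` (one record per
#'   population-year, abundance >= 0).
#' @return tibble `population_id, species, location_id, lat, lon, year, r`
#'   where `year` is the first year `t` of the interval `t -> t+1`.
#' @examples
#' rec <- tibble::tibble(population_id = "p1", species = "s", location_id = "L",
#'                       lat = -20, lon = 25, year = c(1990, 1991, 1993),
#'                       abundance = c(100, 110, 140))
#' compute_growth_rates(rec)  # one observation, r = log(1.1)
#' @export
compute_growth_rates <- function(records) {
  required <- c("population_id", "species", "location_id", "lat", "lon",
                "year", "abundance")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("abundance records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(records$abundance < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  dup <- records |>
    dplyr::count(.data$population_id, .data$year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate census for population-year(s): ",
         paste(sprintf("%s/%d", dup$population_id, dup$year), collapse = ", "),
         call. = FALSE)
  }
  obs <- records |>
    dplyr::arrange(.data$population_id, .data$year) |>
    dplyr::group_by(.data$population_id, .data$species, .data$location_id,
                    .data$lat, .data$lon) |>
    dplyr::reframe({
      y <- .data$year
      a <- .data$abundance
      tibble::tibble(year = head(y, -1), gap = diff(y),
                     n_from = head(a, -1), n_to = tail(a, -1))
    }) |>
    dplyr::filter(.data$gap == 1L)
  zero <- obs$n_from == 0 | obs$n_to == 0
  if (any(zero)) {
    warning("skipped ", sum(zero),
            " consecutive-year pair(s) with zero abundance (log growth ",
            "rate undefined)", call. = FALSE)
    obs <- obs[!zero, ]
  }
  obs |>
    dplyr::mutate(r = log(.data$n_to / .data$n_from)) |>
    dplyr::select("population_id", "species", "location_id", "lat", "lon",
                  "year", "r")
}

#' Keep species with enough growth observations
#'
#' A species enters the analysis only when its growth-rate sample size,
#' pooled over all of its populations, is strictly greater than `threshold`
#' (default 20) — exactly 20 observations is not enough.
#'
#' @param observations growth observations from [compute_growth_rates()].
#' @param threshold strict lower bound on per-species observation count.
#' @return the observations of retained species.
#' @export
filter_min_observations <- function(observations, threshold = 20) {
  keep <- observations |>
    dplyr::count(.data$species) |>
    dplyr::filter(.data$n > threshold)
  observations[observations$species %in% keep$species, , drop = FALSE]
}

#' Drop populations that start below the species' herd-size range
#'
#' Populations whose first abundance record is smaller than the species'
#' herd-size range are considered unstable (plausibly a fragment of a herd,
#' or a unit mismatch) and removed whole. By default "smaller than the
#' range" means below its lower bound `herd_size_min` (the most permissive
#' reading); set `bound = "midpoint"` to compare against the range midpoint.
#'
#' @param records abundance records.
#' @param traits species trait table with `species`, `herd_size_min`,
#'   `herd_size_max`.
#' @param bound `"min"` (default) or `"midpoint"`.
#' @return records of retained populations.
#' @export
filter_initial_abundance <- function(records, traits, bound = c("min", "midpoint")) {
  bound <- match.arg(bound)
  unknown <- setdiff(unique(records$species), traits$species)
  if (length(unknown) > 0) {
    stop("no traits for species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  firsts <- records |>
    dplyr::arrange(.data$population_id, .data$year) |>
    dplyr::group_by(.data$population_id, .data$species) |>
    dplyr::summarise(first_abundance = dplyr::first(.data$abundance),
                     .groups = "drop") |>
    dplyr::left_join(traits[, c("species", "herd_size_min", "herd_size_max")],
                     by = "species") |>
    dplyr::mutate(cutoff = if (bound == "min") .data$herd_size_min
                  else (.data$herd_size_min + .data$herd_size_max) / 2)
  drop_ids <- firsts$population_id[firsts$first_abundance < firsts$cutoff]
  records[!records$population_id %in% drop_ids, , drop = FALSE]
}

#' Remove growth rates beyond the species' physiological maximum
#'
#' The largest growth rate physiologically possible arises when every
#' individual is female, each produces the species' maximum number of
#' offspring in the year, and nobody dies: `N[t+1] = N[t] * (1 + f)` with
#' `f` the maximum offspring per female per year, i.e.
#' `r_max = log(1 + f)`. Observations with `r > r_max` are attributed to
#' immigration, introductions or census error and removed (the rule is
#' one-sided: arbitrarily negative rates are kept).
#'
#' @param observations growth observations.
#' @param traits trait table with `species` and
#'   `max_offspring_per_female_per_year`.
#' @return observations with super-maximal growth rates removed; the number
#'   removed is reported via a message when positive.
#' @export
max_growth_filter <- function(observations, traits) {
  unknown <- setdiff(unique(observations$species), traits$species)
  if (length(unknown) > 0) {
    stop("no traits for species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  obs <- observations |>
    dplyr::left_join(
      traits[, c("species", "max_offspring_per_female_per_year")],
      by = "species") |>
    dplyr::mutate(r_max = log(1 + .data$max_offspring_per_female_per_year))
  bad <- obs$r > obs$r_max
  if (any(bad)) {
    message("removed ", sum(bad),
            " observation(s) exceeding the physiological maximum growth rate")
  }
  obs[!bad, setdiff(names(obs), c("max_offspring_per_female_per_year",
                                  "r_max")), drop = FALSE]
}

#' Assign species to life-history groups
#'
#' Four groups from the movement x diet cross: grazers and mixed feeders
#' depend wholly or partly on drought-intolerant (grass) forage (the G
#' side), browsers and omnivores do not (B); sedentary species cannot
#' escape local drought (S), non-sedentary (nomadic/migratory/wide-ranging)
#' species can (M). Hence SG, SB, MG, MB.
#'
#' @param traits trait table with `movement` in
#'   `{sedentary, non_sedentary}` and `diet` in
#'   `{grazer, mixed, browser, omnivore}`.
#' @return `traits` with a `group` factor column (levels SG, SB, MG, MB).
#' @examples
#' assign_group(tibble::tibble(species = "impala", movement = "sedentary",
#'                             diet = "mixed"))
#' @export
assign_group <- function(traits) {
  bad_mov <- setdiff(unique(traits$movement), c("sedentary", "non_sedentary"))
  if (length(bad_mov) > 0) {
    stop("unknown movement class(es): ", paste(bad_mov, collapse = ", "),
         call. = FALSE)
  }
  bad_diet <- setdiff(unique(traits$diet),
                      c("grazer", "mixed", "browser", "omnivore"))
  if (length(bad_diet) > 0) {
    stop("unknown diet class(es): ", paste(bad_diet, collapse = ", "),
         call. = FALSE)
  }
  grass <- traits$diet %in% c("grazer", "mixed")
  sed <- traits$movement == "sedentary"
  traits$group <- factor(
    ifelse(sed, ifelse(grass, "SG", "SB"), ifelse(grass, "MG", "MB")),
    levels = c("SG", "SB", "MG", "MB")
  )
  traits
}

#' Attach drought indices to growth observations
#'
#' The growth interval `t -> t+1` carries the drought indices of calendar
#' year `t` (the interval's first year, the "preceding year" of the census
#' at `t+1`). Populations are matched to the drought series of the grid
#' cell / location they fall in via `location_id`. Observations for years
#' without computed indices keep `NA` values; model-fitting functions drop
#' them.
#'
#' @param observations growth observations.
#' @param indices annual indices from [annual_drought_indices()].
#' @return observations with `T`, `C`, `T_t2`, `C_t2`, `drought_year`
#'   columns appended.
#' @export
join_drought <- function(observations, indices) {
  absent <- observations |>
    dplyr::distinct(.data$population_id, .data$location_id) |>
    dplyr::filter(!.data$location_id %in% unique(indices$location_id))
  if (nrow(absent) > 0) {
    stop("no drought indices for the location of population(s): ",
         paste(absent$population_id, collapse = ", "), call. = FALSE)
  }
  dplyr::left_join(
    observations,
    indices[, c("location_id", "year", "T", "C", "T_t2", "C_t2",
                "drought_year")],
    by = c("location_id", "year")
  )
}
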