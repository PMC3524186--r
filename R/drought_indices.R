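#' Validate a monthly drought-severity series
#'
#' A monthly series is a data frame with columns `location_id`, `year`,
#' `month` and `pdsi` (optionally `lat`, `lon`). Within each location the
#' (year, month) pairs must be strictly increasing with no duplicates and no
#' gaps are required; `pdsi` may be `NA` for missing months but must be
#' finite where present.
#'
#' @param series data frame of monthly values.
#' @return the input, invisibly, after validation.
#' @export
validate_monthly_series <- function(series) {
  required <- c("location_id", "year", "month", "pdsi")
  missing_cols <- setdiff(required, names(series))
  if (length(missing_cols) > 0) {
    stop("monthly series is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(series$month < 1 | series$month > 12, na.rm = TRUE)) {
    stop("month values must lie in 1..12", call. = FALSE)
  }
  bad <- series |>
    dplyr::group_by(.data$location_id) |>
    dplyr::summarise(
      ok = !anyDuplicated(.data$year * 12L + .data$month) &&
        !is.unsorted(.data$year * 12L + .data$month, strictly = TRUE),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("months are unordered or duplicated for location(s): ",
         paste(bad$location_id, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(series$pdsi) & !is.na(series$pdsi))) {
    stop("pdsi values must be finite or NA", call. = FALSE)
  }
  invisible(series)
}

#' Percentile drought threshold for each location
#'
#' The drought threshold theta of a location is a low percentile (10th by
#' default) of the location's reference distribution of monthly
#' drought-severity values; months with values strictly below theta are
#' classified as drought months. The reference distribution is the set of
#' non-missing monthly values of that location within `reference_period`
#' (all years of the series by default). Percentiles use linear
#' interpolation between order statistics (R's default `type = 7`
#' convention, configurable).
#'
#' @param series monthly series (see [validate_monthly_series()]).
#' @param percentile percentile in (0, 100); default 10.
#' @param reference_period length-2 integer vector `c(start, end)` of
#'   calendar years, or `NULL` for the full record.
#' @param min_months minimum number of non-missing reference months required
#'   per location (default 120, i.e. ten years).
#' @param type quantile interpolation convention passed to
#'   [stats::quantile()].
#' @return a tibble with one row per location: `location_id`, `theta`,
#'   `percentile`, `n_reference`, `ref_start`, `ref_end`.
#' @examples
#' s <- tibble::tibble(location_id = "L1", year = rep(1970:1979, each = 12),
#'                     month = rep(1:12, 10), pdsi = rnorm(120))
#' compute_threshold(s, percentile = 10, reference_period = c(1970, 1979))
#' @export
compute_threshold <- function(series, percentile = 10, reference_period = NULL,
                              min_months = 120, type = 7) {
  validate_monthly_series(series)
  stopifnot(length(percentile) == 1, percentile > 0, percentile < 100)
  if (is.null(reference_period)) {
    reference_period <- range(series$year)
  }
  ref <- series |>
    dplyr::filter(.data$year >= reference_period[1],
                  .data$year <= reference_period[2],
                  !is.na(.data$pdsi))
  counts <- ref |>
    dplyr::count(.data$location_id, name = "n_reference")
  # locations entirely absent from the reference window also fail the floor
  all_locs <- unique(series$location_id)
  counts <- dplyr::left_join(tibble::tibble(location_id = all_locs), counts,
                             by = "location_id")
  counts$n_reference[is.na(counts$n_reference)] <- 0L
  short <- counts[counts$n_reference < min_months, ]
  if (nrow(short) > 0) {
    stop("too few non-missing reference months for threshold estimation: ",
         paste(sprintf("%s has %d (< %d)", short$location_id,
                       short$n_reference, min_months), collapse = "; "),
         call. = FALSE)
  }
  ref |>
    dplyr::group_by(.data$location_id) |>
    dplyr::summarise(
      theta = as.numeric(quantile(.data$pdsi, probs = percentile / 100,
                                  type = type, names = FALSE)),
      percentile = percentile,
      n_reference = dplyr::n(),
      ref_start = reference_period[1],
      ref_end = reference_period[2],
      .groups = "drop"
    )
}

#' Flag drought months against a threshold
#'
#' A month is a drought month when its value is *strictly* below the
#' location's threshold theta; a month exactly at theta is not in drought.
#' Missing months are flagged `FALSE` (non-drought) and reported through the
#' `missing` column so downstream index computation can account for them.
#'
#' @param series monthly series.
#' @param thresholds output of [compute_threshold()] covering every location
#'   present in `series`.
#' @return the series with logical columns `drought` and `missing` appended.
#' @export
flag_drought_months <- function(series, thresholds) {
  validate_monthly_series(series)
  absent <- setdiff(unique(series$location_id), thresholds$location_id)
  if (length(absent) > 0) {
    stop("no threshold for location(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  series |>
    dplyr::left_join(thresholds[, c("location_id", "theta")],
                     by = "location_id") |>
    dplyr::mutate(
      missing = is.na(.data$pdsi),
      drought = !is.na(.data$pdsi) & .data$pdsi < .data$theta
    ) |>
    dplyr::select(-"theta")
}

longest_run <- function(flags) {
  if (length(flags) == 0 || !any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

#' Annual drought-intensity indices
#'
#' For each location-year with a complete 12-month record, computes the four
#' drought-intensity indices: `T`, the total number of drought months of the
#' year; `C`, the maximum number of consecutive drought months within the
#' year; and `T_t2` / `C_t2`, the same quantities over the 24-month window
#' spanning the preceding and the focal year (consecutive runs may cross the
#' December/January boundary). A year is a drought year when it contains at
#' least one drought month (`T >= 1`).
#'
#' Years whose 12 months are not all present in the series yield no row.
#' When the preceding year is absent the two-year indices are `NA` rather
#' than zero. A year with more than `max_missing` missing-value months
#' yields `NA` indices (the record is too incomplete to classify).
#'
#' @param flags flagged series from [flag_drought_months()].
#' @param max_missing most missing months tolerated within a year before its
#'   indices are reported as `NA` (default 3).
#' @return tibble `location_id, year, T, C, T_t2, C_t2, drought_year,
#'   n_missing`.
#' @export
annual_drought_indices <- function(flags, max_missing = 3) {
  stopifnot(all(c("drought", "missing") %in% names(flags)))
  one_location <- function(d) {
    d <- d[order(d$year, d$month), ]
    yrs <- sort(unique(d$year))
    complete <- vapply(yrs, function(y) sum(d$year == y) == 12L, logical(1))
    yrs <- yrs[complete]
    if (length(yrs) == 0) return(NULL)
    rows <- lapply(yrs, function(y) {
      cur <- d[d$year == y, ]
      n_miss <- sum(cur$missing)
      if (n_miss > max_missing) {
        return(tibble::tibble(year = y, T = NA_integer_, C = NA_integer_,
                              T_t2 = NA_integer_, C_t2 = NA_integer_,
                              drought_year = NA, n_missing = n_miss))
      }
      T_ <- sum(cur$drought)
      C_ <- longest_run(cur$drought)
      prev <- d[d$year == y - 1L, ]
      if (nrow(prev) == 12L && sum(prev$missing) <= max_missing) {
        win <- c(prev$drought, cur$drought)
        T2 <- sum(win)
        C2 <- longest_run(win)
      } else {
        T2 <- NA_integer_
        C2 <- NA_integer_
      }
      tibble::tibble(year = y, T = as.integer(T_), C = as.integer(C_),
                     T_t2 = as.integer(T2), C_t2 = as.integer(C2),
                     drought_year = T_ >= 1L, n_missing = n_miss)
    })
    dplyr::bind_rows(rows)
  }
  flags |>
    dplyr::group_by(.data$location_id) |>
    dplyr::group_modify(~ one_location(.x)) |>
    dplyr::ungroup()
}

#' Run-length statistics of a drought-year sequence
#'
#' Decomposes an ordered sequence of drought-year flags into maximal runs of
#' consecutive drought and non-drought years, and computes the mean
#' recurrence interval (drought frequency): the average gap in years between
#' successive drought years.
#'
#' @param drought_year logical vector, ordered by year, no `NA`.
#' @param years optional calendar years (defaults to positions).
#' @return object of class `run_length_stats`: a list with
#'   `drought_run_lengths`, `nondrought_run_lengths` and
#'   `mean_recurrence_interval` (`NA` when fewer than two drought years).
#' @examples
#' run_length_stats(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
#' @export
run_length_stats <- function(drought_year, years = seq_along(drought_year)) {
  stopifnot(is.logical(drought_year), !anyNA(drought_year),
            length(drought_year) == length(years))
  if (length(drought_year) < 2) {
    stop("at least two classified years are required", call. = FALSE)
  }
  r <- rle(drought_year)
  gaps <- diff(years[drought_year])
  structure(
    list(
      drought_run_lengths = as.integer(r$lengths[r$values]),
      nondrought_run_lengths = as.integer(r$lengths[!r$values]),
      mean_recurrence_interval = if (sum(drought_year) >= 2) mean(gaps)
                                 else NA_real_
    ),
    class = "run_length_stats"
  )
}

#' @export
print.run_length_stats <- function(x, ...) {
  cat("Run-length statistics\n")
  cat("  drought runs (years):    ",
      paste(x$drought_run_lengths, collapse = " "), "\n")
  cat("  non-drought runs (years):",
      paste(x$nondrought_run_lengths, collapse = " "), "\n")
  cat("  mean recurrence interval:",
      format(x$mean_recurrence_interval, digits = 4), "years\n")
  invisible(x)
}

#' Two-state Markov drought-generator parameters
#'
#' Container for the parameters of the annual drought generator: `p_init`,
#' the marginal probability that a year is a drought year (the "initial
#' threshold"); `ddt`, the probability that a drought year is followed by
#' another drought year (drought distance threshold); `nddt`, the
#' probability that a non-drought year is followed by another non-drought
#' year; and `length_dist`, the distribution of the drought-intensity index
#' `C` (months, support 1..12) conditional on the year being in drought.
#'
#' @param p_init,ddt,nddt probabilities in `[0, 1]`.
#' @param length_dist numeric vector of length 12 summing to 1 (probability
#'   that `C = 1..12` given a drought year), or `NULL` when only the yearly
#'   chain is of interest.
#' @return object of class `markov_params`.
#' @export
markov_params <- function(p_init, ddt, nddt, length_dist = NULL) {
  probs <- c(p_init = p_init, ddt = ddt, nddt = nddt)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("p_init, ddt and nddt must be probabilities in [0, 1]",
         call. = FALSE)
  }
  if (!is.null(length_dist)) {
    if (length(length_dist) != 12 || any(length_dist < 0)) {
      stop("length_dist must be 12 non-negative probabilities (C = 1..12)",
           call. = FALSE)
    }
    if (abs(sum(length_dist) - 1) > 1e-12) {
      stop("length_dist must sum to 1", call. = FALSE)
    }
  }
  structure(list(p_init = p_init, ddt = ddt, nddt = nddt,
                 length_dist = length_dist),
            class = "markov_params")
}

#' @export
print.markov_params <- function(x, ...) {
  cat("Markov drought-generator parameters\n")
  cat(sprintf("  p_init (P[year in drought]) = %.4f\n", x$p_init))
  cat(sprintf("  ddt  (P[drought -> drought]) = %.4f\n", x$ddt))
  cat(sprintf("  nddt (P[non-dr. -> non-dr.]) = %.4f\n", x$nddt))
  if (!is.null(x$length_dist)) {
    cat("  drought-length distribution (months 1..12):\n   ",
        paste(sprintf("%.3f", x$length_dist), collapse = " "), "\n")
  }
  invisible(x)
}

#' Estimate Markov drought parameters from classified years
#'
#' Pools drought-year sequences (transitions are counted within each
#' location, never across locations) and estimates the two-state Markov
#' generator: `p_init` as the fraction of drought years, `ddt` and `nddt` as
#' the empirical same-state transition probabilities, and the drought-length
#' distribution as the empirical distribution of `C` over drought years.
#' Only transitions between consecutive calendar years are counted.
#'
#' @param indices either a data frame with columns `location_id`, `year`,
#'   `drought_year` and (optionally) `C`, or a plain logical vector of
#'   drought-year flags for a single location.
#' @param C optional integer vector of `C` values for the drought years when
#'   `indices` is a logical vector.
#' @return a [markov_params()] object (with `length_dist = NULL` when no `C`
#'   values are available).
#' @examples
#' estimate_markov_params(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
#' @export
estimate_markov_params <- function(indices, C = NULL) {
  if (is.logical(indices)) {
    indices <- tibble::tibble(location_id = "pooled",
                              year = seq_along(indices),
                              drought_year = indices)
    if (!is.null(C)) {
      indices$C <- NA_integer_
      indices$C[indices$drought_year] <- as.integer(C)
    }
  }
  d <- indices[!is.na(indices$drought_year), ]
  if (nrow(d) == 0) stop("no classified years", call. = FALSE)
  p_init <- mean(d$drought_year)

  trans <- d |>
    dplyr::arrange(.data$location_id, .data$year) |>
    dplyr::group_by(.data$location_id) |>
    dplyr::reframe(from = head(.data$drought_year, -1),
                   to = tail(.data$drought_year, -1),
                   step = diff(.data$year)) |>
    dplyr::filter(.data$step == 1L)
  n_from_d <- sum(trans$from)
  n_from_n <- sum(!trans$from)
  if (n_from_d == 0) {
    stop("no transitions out of the drought state: cannot estimate ddt",
         call. = FALSE)
  }
  if (n_from_n == 0) {
    stop("no transitions out of the non-drought state: cannot estimate nddt",
         call. = FALSE)
  }
  ddt <- sum(trans$from & trans$to) / n_from_d
  nddt <- sum(!trans$from & !trans$to) / n_from_n

  length_dist <- NULL
  if ("C" %in% names(d)) {
    cs <- d$C[d$drought_year & !is.na(d$C)]
    if (length(cs) > 0) {
      if (any(cs < 1 | cs > 12)) {
        stop("C values in drought years must lie in 1..12", call. = FALSE)
      }
      length_dist <- tabulate(cs, nbins = 12) / length(cs)
    }
  }
  markov_params(p_init, ddt, nddt, length_dist)
}

#' Locate a point on the 2.5-degree drought grid
#'
#' Maps coordinates to the cell of a regular lat/lon grid (2.5 x 2.5 degrees
#' by default, matching gridded PDSI products). Cells are half-open,
#' lower-edge inclusive, with origin at (-90, -180); the north pole and the
#' antimeridian clamp into the last cell.
#'
#' @param lat,lon coordinates in degrees (vectors recycled to equal length).
#' @param cell_size cell edge in degrees.
#' @return tibble `lat_index, lon_index, cell_id, lat_min, lat_max, lon_min,
#'   lon_max` (indices are 0-based from the origin corner).
#' @examples
#' grid_cell_lookup(0.1, 0.1)
#' @export
grid_cell_lookup <- function(lat, lon, cell_size = 2.5) {
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  if (any(lat < -90 | lat > 90)) stop("lat out of [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon > 180)) stop("lon out of [-180, 180]",
                                        call. = FALSE)
  n_lat <- ceiling(180 / cell_size)
  n_lon <- ceiling(360 / cell_size)
  i_lat <- pmin(floor((lat + 90) / cell_size), n_lat - 1)
  i_lon <- pmin(floor((lon + 180) / cell_size), n_lon - 1)
  tibble::tibble(
    lat_index = as.integer(i_lat),
    lon_index = as.integer(i_lon),
    cell_id = sprintf("cell_%03d_%03d", as.integer(i_lat), as.integer(i_lon)),
    lat_min = -90 + i_lat * cell_size,
    lat_max = -90 + (i_lat + 1) * cell_size,
    lon_min = -180 + i_lon * cell_size,
    lon_max = -180 + (i_lon + 1) * cell_size
  )
}

#' Annual mean and modal PDSI
#'
#' Summaries used to sanity-check the drought indices against the raw
#' severity scale: the mean of the year's monthly values and their mode.
#' The mode of twelve continuous values is computed on values rounded to
#' one decimal place, breaking ties toward the lower value.
#'
#' @param series monthly series.
#' @return tibble `location_id, year, mean_pdsi, modal_pdsi, n_missing`;
#'   years with any missing months are summarised over the available months
#'   and counted in `n_missing` (with a warning).
#' @export
annual_summary_pdsi <- function(series) {
  validate_monthly_series(series)
  out <- series |>
    dplyr::group_by(.data$location_id, .data$year) |>
    dplyr::summarise(
      mean_pdsi = mean(.data$pdsi, na.rm = TRUE),
      modal_pdsi = {
        v <- round(.data$pdsi[!is.na(.data$pdsi)], 1)
        if (length(v) == 0) NA_real_ else {
          tab <- table(v)
          min(as.numeric(names(tab)[tab == max(tab)]))
        }
      },
      n_missing = sum(is.na(.data$pdsi)) + (12L - dplyr::n()),
      .groups = "drop"
    )
  out$mean_pdsi[is.nan(out$mean_pdsi)] <- NA_real_
  if (any(out$n_missing > 0)) {
    warning(sum(out$n_missing > 0),
            " location-year(s) summarised with missing months",
            call. = FALSE)
  }
  out
}
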