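#' Replicate-wise r-squared between observed and modelled abundance
#'
#' For each Monte-Carlo replicate, the squared Pearson correlation between
#' the observed abundances and that replicate's simulated abundances at the
#' matching years; reported as a mean and SD over replicates. Being a
#' squared correlation it measures shared shape, not level or sign — a
#' replicate declining exactly as fast as the observations rise still
#' scores 1.
#'
#' @param observed data frame with `year` and `abundance` for one
#'   population.
#' @param projection a `population_projection` with stored trajectories.
#' @return list `r2_mean`, `r2_sd`, `n_years` (overlapping years used);
#'   both statistics `NA` when the observed series is constant.
#' @export
r_squared_fit <- function(observed, projection) {
  stopifnot(inherits(projection, "population_projection"))
  if (is.null(projection$trajectories)) {
    stop("projection was run without stored trajectories", call. = FALSE)
  }
  obs <- observed[!is.na(observed$abundance), c("year", "abundance")]
  common <- intersect(obs$year, projection$years)
  if (length(common) < 3) {
    stop("need at least 3 overlapping years (have ", length(common), ")",
         call. = FALSE)
  }
  y <- obs$abundance[match(common, obs$year)]
  if (var(y) == 0) {
    message("observed series is constant: r-squared undefined")
    return(list(r2_mean = NA_real_, r2_sd = NA_real_,
                n_years = length(common)))
  }
  sims <- projection$trajectories[, as.character(common), drop = FALSE]
  r2 <- apply(sims, 1, function(x) {
    if (var(x) == 0) return(NA_real_)
    cor(x, y)^2
  })
  list(r2_mean = mean(r2, na.rm = TRUE), r2_sd = sd(r2, na.rm = TRUE),
       n_years = length(common))
}

#' Hodges-Lehmann pseudomedian with a signed-rank confidence interval
#'
#' The pseudomedian of a sample is the median of all Walsh averages
#' `(x[i] + x[j]) / 2`, `i <= j`; its confidence interval inverts the
#' one-sample Wilcoxon signed-rank statistic (exact for `n <= 25` without
#' ties, normal approximation otherwise). This is the estimator/interval
#' pair conventionally reported for episode-length medians.
#'
#' @param x numeric sample, `n >= 3`.
#' @param conf.level confidence level (default 0.95).
#' @return list `pseudomedian`, `lower`, `upper`, `n`, `conf.level`.
#' @examples
#' pseudomedian_ci(c(1, 2, 3))$pseudomedian  # 2
#' @export
pseudomedian_ci <- function(x, conf.level = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 values (have ", n, ")", call. = FALSE)
  if (length(unique(x)) == 1) {
    return(list(pseudomedian = x[1], lower = x[1], upper = x[1], n = n,
                conf.level = conf.level))
  }
  wt <- suppressWarnings(
    wilcox.test(x, conf.int = TRUE, conf.level = conf.level,
                exact = n <= 25)
  )
  list(pseudomedian = unname(wt$estimate),
       lower = unname(wt$conf.int[1]),
       upper = unname(wt$conf.int[2]),
       n = n, conf.level = conf.level)
}

#' Compare observed and simulated drought/non-drought episode lengths
#'
#' Computes the pseudomedian and 95% confidence interval for the drought
#' and non-drought run lengths of an observed and a simulated drought-year
#' classification, and flags agreement when the observed and simulated
#' intervals overlap for both episode types.
#'
#' @param observed,simulated [run_length_stats()] objects.
#' @param conf.level confidence level for the intervals.
#' @return list of class `episode_length_report`: tibble `summary` (one row
#'   per sample) and logicals `drought_overlap`, `nondrought_overlap`,
#'   `pass`.
#' @export
episode_length_check <- function(observed, simulated, conf.level = 0.95) {
  stopifnot(inherits(observed, "run_length_stats"),
            inherits(simulated, "run_length_stats"))
  rows <- list(
    c("observed", "drought"), c("observed", "non_drought"),
    c("simulated", "drought"), c("simulated", "non_drought")
  )
  samples <- list(observed$drought_run_lengths,
                  observed$nondrought_run_lengths,
                  simulated$drought_run_lengths,
                  simulated$nondrought_run_lengths)
  if (any(lengths(samples) == 0)) {
    stop("all four run-length samples must be non-empty", call. = FALSE)
  }
  cis <- lapply(samples, pseudomedian_ci, conf.level = conf.level)
  summary <- tibble::tibble(
    source = vapply(rows, `[`, character(1), 1),
    episode = vapply(rows, `[`, character(1), 2),
    n = vapply(cis, `[[`, numeric(1), "n"),
    pseudomedian = vapply(cis, `[[`, numeric(1), "pseudomedian"),
    lower = vapply(cis, `[[`, numeric(1), "lower"),
    upper = vapply(cis, `[[`, numeric(1), "upper")
  )
  overlap <- function(a, b) a$lower <= b$upper && b$lower <= a$upper
  drought_overlap <- overlap(cis[[1]], cis[[3]])
  nondrought_overlap <- overlap(cis[[2]], cis[[4]])
  structure(list(summary = summary,
                 drought_overlap = drought_overlap,
                 nondrought_overlap = nondrought_overlap,
                 pass = drought_overlap && nondrought_overlap),
            class = "episode_length_report")
}

#' @export
print.episode_length_report <- function(x, ...) {
  cat("Episode-length check (pseudomedian [95% CI], years):\n")
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  cat(sprintf("  drought CIs overlap:     %s\n", x$drought_overlap))
  cat(sprintf("  non-drought CIs overlap: %s\n", x$nondrought_overlap))
  cat(sprintf("  overall: %s\n", if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
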