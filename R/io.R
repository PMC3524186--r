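#' Read a long-format monthly PDSI CSV
#'
#' Expects header `location_id,lat,lon,year,month,pdsi` (UTF-8, '.'
#' decimal); empty `pdsi` fields become missing months.
#'
#' @param path CSV path.
#' @return validated monthly series tibble.
#' @export
read_pdsi_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- tibble::as_tibble(d)
  d$location_id <- as.character(d$location_id)
  d$year <- as.integer(d$year)
  d$month <- as.integer(d$month)
  d$pdsi <- as.numeric(d$pdsi)
  validate_monthly_series(d)
  d
}

#' Read abundance records / species traits CSVs
#'
#' `read_records_csv` expects
#' `population_id,species,location_id,lat,lon,year,abundance`;
#' `read_traits_csv` expects
#' `species,movement,diet,herd_size_min,herd_size_max,max_offspring_per_female_per_year`.
#'
#' @param path CSV path.
#' @return tibble.
#' @export
read_records_csv <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  required <- c("population_id", "species", "location_id", "lat", "lon",
                "year", "abundance")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    stop("records CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d$year <- as.integer(d$year)
  d
}

#' @rdname read_records_csv
#' @export
read_traits_csv <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  required <- c("species", "movement", "diet", "herd_size_min",
                "herd_size_max", "max_offspring_per_female_per_year")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    stop("traits CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d
}

#' Write / read Markov drought parameters as flat YAML
#'
#' A minimal flat `key: value` YAML subset (scalars plus one bracketed
#' sequence for the length distribution) so the generator parameters can be
#' versioned as plain text without a YAML dependency.
#'
#' @param markov a [markov_params()] object.
#' @param path output path.
#' @return `write_markov_yaml` returns `path` invisibly; `read_markov_yaml`
#'   returns a [markov_params()] object.
#' @export
write_markov_yaml <- function(markov, path) {
  stopifnot(inherits(markov, "markov_params"))
  lines <- c(
    sprintf("p_init: %.17g", markov$p_init),
    sprintf("ddt: %.17g", markov$ddt),
    sprintf("nddt: %.17g", markov$nddt)
  )
  if (!is.null(markov$length_dist)) {
    lines <- c(lines, sprintf("length_dist: [%s]",
                              paste(sprintf("%.17g", markov$length_dist),
                                    collapse = ", ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_markov_yaml
#' @export
read_markov_yaml <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = ":")),
                 character(1))
  get_num <- function(k) {
    if (!k %in% keys) stop("missing key '", k, "' in ", path, call. = FALSE)
    as.numeric(vals[match(k, keys)])
  }
  length_dist <- NULL
  if ("length_dist" %in% keys) {
    raw <- vals[match("length_dist", keys)]
    raw <- gsub("^\\[|\\]$", "", raw)
    length_dist <- as.numeric(trimws(strsplit(raw, ",")[[1]]))
  }
  markov_params(get_num("p_init"), get_num("ddt"), get_num("nddt"),
                length_dist)
}

#' Write annual drought indices to CSV
#'
#' Columns `location_id,year,T,C,T_t2,C_t2,drought_year`.
#'
#' @param indices output of [annual_drought_indices()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_indices_csv <- function(indices, path) {
  utils::write.csv(
    indices[, c("location_id", "year", "T", "C", "T_t2", "C_t2",
                "drought_year")],
    path, row.names = FALSE)
  invisible(path)
}
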