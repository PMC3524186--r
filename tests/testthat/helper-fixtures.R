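# Shared fixtures and independent oracles used across test files.

# Build a single-location monthly series from a vector of q values starting
# January of start_year.
make_series <- function(q, start_year = 1970, location_id = "L1",
                        lat = -20, lon = 25) {
  n <- length(q)
  tibble::tibble(
    location_id = location_id, lat = lat, lon = lon,
    year = start_year + (seq_len(n) - 1L) %/% 12L,
    month = (seq_len(n) - 1L) %% 12L + 1L,
    pdsi = q
  )
}

# Flagged series straight from a logical drought vector (q = -3 for drought
# months, 0 otherwise, theta = -2): lets index tests state flags directly.
make_flags <- function(drought, start_year = 1970, location_id = "L1") {
  s <- make_series(ifelse(drought, -3, 0), start_year, location_id)
  s$missing <- FALSE
  s$drought <- drought
  s
}

# Brute-force longest-run oracle: explicit loop over all sub-runs.
oracle_longest_run <- function(flags) {
  best <- 0L
  n <- length(flags)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(flags[i:j]) && (j - i + 1L) > best) best <- j - i + 1L
    }
  }
  best
}

# Exact one-sample signed-rank pseudomedian + CI oracle for small tie-free
# samples: the pseudomedian is the median of explicitly enumerated Walsh
# averages, and the CI is the definitional test inversion -- the closure of
# the set of centres mu whose exact two-sided signed-rank p-value (null
# distribution enumerated over all 2^n sign assignments) exceeds alpha,
# clamped to the Walsh range when the level is unattainable at tiny n.
oracle_pseudomedian_ci <- function(x, conf.level = 0.95) {
  n <- length(x)
  stopifnot(n <= 12, !anyDuplicated(x))
  o <- outer(x, x, "+")
  walsh <- sort(o[lower.tri(o, diag = TRUE)] / 2)
  M <- length(walsh)
  ranks <- 1:n
  w_vals <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[1:n]
    sum(ranks[signs == 1])
  }, numeric(1))
  pval <- function(mu) {
    d <- x - mu
    rk <- rank(abs(d))
    w <- sum(rk[d > 0])
    min(2 * min(mean(w_vals <= w), mean(w_vals >= w)), 1)
  }
  alpha <- 1 - conf.level
  mids <- c(walsh[1] - 1, (head(walsh, -1) + tail(walsh, -1)) / 2,
            walsh[M] + 1)
  idx <- which(vapply(mids, pval, numeric(1)) > alpha)
  list(pseudomedian = median(walsh),
       lower = walsh[max(min(idx) - 1, 1)],
       upper = walsh[min(max(idx), M)])
}

# Small Markov parameter set used by several projection tests.
test_markov <- function() {
  markov_params(p_init = 0.4, ddt = 0.5, nddt = 0.71,
                length_dist = c(rep(1 / 6, 6), rep(0, 6)))
}
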