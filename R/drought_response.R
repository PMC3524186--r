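#' Mixed-effects regression of growth rate on a drought index
#'
#' Fits `r ~ index` with crossed random intercepts for population location
#' and species, by maximum likelihood (so single-predictor fits are
#' comparable across indices). The fixed slope `b` is the per-drought-month
#' change in annual log growth rate and is the quantity carried forward
#' into the projection model. When the data contain a single species the
#' species random term is dropped automatically (its variance is not
#' identifiable) and a message is emitted; likewise for a single location.
#'
#' p-values are Wald z tests on the fixed slope.
#'
#' @param observations growth observations joined to drought indices
#'   ([join_drought()]); rows with `NA` in the predictor or response are
#'   dropped.
#' @param predictor one of `"C"`, `"T"`, `"C_t2"`, `"T_t2"` (or any numeric
#'   column of `observations`).
#' @param group optional life-history group label; when given,
#'   `observations` must carry a `group` column and only that group is
#'   fitted.
#' @return object of class `drought_response_fit`: list with `group`,
#'   `predictor`, `slope`, `intercept`, `se`, `p`, `n`, `var_location`,
#'   `var_species`, `var_resid`, and the underlying `lme4` fit in `model`.
#' @examples
#' \donttest{
#' world <- generate_world(synthetic_world_spec(seed = 1))
#' fit_drought_response(world$observations, predictor = "C", group = "SG")
#' }
#' @export
fit_drought_response <- function(observations, predictor = "C", group = NULL) {
  if (!predictor %in% names(observations)) {
    stop("predictor column '", predictor, "' not found", call. = FALSE)
  }
  obs <- observations
  if (!is.null(group)) {
    if (!"group" %in% names(obs)) {
      stop("observations carry no 'group' column", call. = FALSE)
    }
    obs <- obs[!is.na(obs$group) & obs$group == group, , drop = FALSE]
  }
  obs <- obs[!is.na(obs[[predictor]]) & !is.na(obs$r), , drop = FALSE]
  if (nrow(obs) < 3) {
    stop("fewer than 3 usable observations", call. = FALSE)
  }
  x <- obs[[predictor]]
  if (length(unique(x)) < 2) {
    stop("predictor '", predictor, "' is constant in the fitted data",
         call. = FALSE)
  }

  terms <- character(0)
  if (length(unique(obs$location_id)) > 1) {
    terms <- c(terms, "(1 | location_id)")
  } else {
    message("single location: location random term dropped")
  }
  if (length(unique(obs$species)) > 1) {
    terms <- c(terms, "(1 | species)")
  } else {
    message("single species: species random term dropped")
  }
  if (length(terms) == 0) {
    stop("need at least two locations or two species for a mixed fit",
         call. = FALSE)
  }
  form <- as.formula(paste("r ~", predictor, "+", paste(terms, collapse = " + ")))
  model <- tryCatch(
    lme4::lmer(form, data = obs, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) {
      stop("mixed-model fit failed to converge: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  fe <- lme4::fixef(model)
  vc <- as.data.frame(lme4::VarCorr(model))
  pick_var <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 0) 0 else v[1]
  }
  se <- sqrt(diag(as.matrix(stats::vcov(model))))[predictor]
  z <- unname(fe[predictor] / se)
  structure(
    list(
      group = if (is.null(group)) "all" else group,
      predictor = predictor,
      slope = unname(fe[predictor]),
      intercept = unname(fe["(Intercept)"]),
      se = unname(se),
      p = 2 * pnorm(-abs(z)),
      n = nrow(obs),
      var_location = pick_var("location_id"),
      var_species = pick_var("species"),
      var_resid = pick_var("Residual"),
      model = model
    ),
    class = "drought_response_fit"
  )
}

#' @export
print.drought_response_fit <- function(x, ...) {
  cat(sprintf("Drought response fit  [group: %s]\n", x$group))
  cat(sprintf("  %s  (ML, n = %d)\n",
              deparse(stats::formula(x$model)), x$n))
  cat(sprintf("  slope b  = %+.5f  (SE %.5f, Wald p = %.4g)\n",
              x$slope, x$se, x$p))
  cat(sprintf("  intercept = %+.5f\n", x$intercept))
  cat(sprintf("  variances: location %.5f, species %.5f, residual %.5f\n",
              x$var_location, x$var_species, x$var_resid))
  invisible(x)
}

#' Coerce a drought-response fit to a one-row tibble
#' @param x a `drought_response_fit`.
#' @return one-row tibble with the fit's scalar summaries.
#' @export
tidy_fit <- function(x) {
  stopifnot(inherits(x, "drought_response_fit"))
  tibble::tibble(group = x$group, predictor = x$predictor, slope = x$slope,
                 intercept = x$intercept, se = x$se, p = x$p, n = x$n,
                 var_location = x$var_location, var_species = x$var_species,
                 var_resid = x$var_resid)
}

#' Compare the four drought-intensity indices as growth predictors
#'
#' Fits the single-predictor mixed model once per index (`C`, `T`, `C_t2`,
#' `T_t2`) on the same observations, and computes the pairwise Spearman
#' rank correlations between the indices (pairwise-complete).
#'
#' @param observations growth observations with all four index columns.
#' @param predictors character vector of index columns to compare.
#' @inheritParams fit_drought_response
#' @return list of class `index_comparison`: `fits` (tibble, one row per
#'   predictor) and `spearman` (correlation matrix).
#' @export
compare_indices <- function(observations,
                            predictors = c("C", "T", "C_t2", "T_t2"),
                            group = NULL) {
  fits <- lapply(predictors, function(p)
    tidy_fit(fit_drought_response(observations, predictor = p, group = group)))
  idx <- as.matrix(observations[, predictors])
  rho <- cor(idx, method = "spearman", use = "pairwise.complete.obs")
  structure(list(fits = dplyr::bind_rows(fits), spearman = rho),
            class = "index_comparison")
}

#' @export
print.index_comparison <- function(x, ...) {
  cat("Single-predictor drought-response fits:\n")
  print(as.data.frame(x$fits), digits = 4, row.names = FALSE)
  cat("\nSpearman rank correlations between indices:\n")
  print(round(x$spearman, 3))
  invisible(x)
}

#' Spearman correlation of the drought index with annual PDSI summaries
#'
#' Rank correlation (tie-corrected mid-ranks, two-sided p) between the
#' chosen drought index and the annual mean and annual modal PDSI — a check
#' that the thresholded index still tracks the underlying severity scale.
#' More intense drought (larger `C`) should accompany lower (drier) PDSI,
#' so rho is expected negative.
#'
#' @param C drought-index values (one per location-year).
#' @param mean_pdsi,modal_pdsi matching annual summaries
#'   ([annual_summary_pdsi()]).
#' @return tibble with rows `mean_pdsi` and `modal_pdsi`: `rho` and `p`.
#' @export
spearman_index_vs_pdsi <- function(C, mean_pdsi, modal_pdsi) {
  stopifnot(length(C) == length(mean_pdsi), length(C) == length(modal_pdsi))
  one <- function(y, label) {
    ok <- !is.na(C) & !is.na(y)
    if (sum(ok) < 5) stop("need at least 5 complete pairs", call. = FALSE)
    if (var(C[ok]) == 0 || var(y[ok]) == 0) {
      stop("zero variance in ", label, " comparison", call. = FALSE)
    }
    ct <- suppressWarnings(cor.test(C[ok], y[ok], method = "spearman",
                                    exact = FALSE))
    tibble::tibble(comparison = label, rho = unname(ct$estimate),
                   p = ct$p.value, n = sum(ok))
  }
  dplyr::bind_rows(one(mean_pdsi, "mean_pdsi"), one(modal_pdsi, "modal_pdsi"))
}

#' Scatter of growth rate against a drought index with the fitted line
#'
#' @param observations growth observations.
#' @param fit a `drought_response_fit` for the same predictor.
#' @return a ggplot object.
#' @export
plot_drought_response <- function(observations, fit) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  stopifnot(inherits(fit, "drought_response_fit"))
  obs <- observations[!is.na(observations[[fit$predictor]]) &
                        !is.na(observations$r), ]
  ggplot2::ggplot(obs, ggplot2::aes(x = .data[[fit$predictor]], y = .data$r)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         colour = "firebrick") +
    ggplot2::labs(x = sprintf("%s (drought months)", fit$predictor),
                  y = "annual log growth rate r") +
    ggplot2::theme_minimal()
}
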