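#' Enumerate the model grid
#'
#' Full cross-product of exposures, single-day lags and analysis strata,
#' for each outcome block, in the deterministic order (exposure, lag,
#' stratum). The default grid — 8 exposures x 15 lags x 18 strata —
#' contains 2,160 model specifications per block.
#'
#' @param exposures Character vector of exposures, a subset of
#'   [exposure_names()].
#' @param lags Integer vector of lags in days, within 0-14.
#' @param strata Stratum tibble, see [enumerate_strata()].
#' @param blocks Outcome blocks to run, default the episodic and
#'   paroxysmal block.
#' @return Tibble of model specs: `exposure`, `lag`, `stratum_id`,
#'   `block`.
#' @export
enumerate_models <- function(exposures = exposure_names(),
                             lags = 0:14,
                             strata = enumerate_strata(),
                             blocks = "G40-G47") {
  bad <- setdiff(exposures, exposure_names())
  if (length(bad) > 0) {
    stop("enumerate_models: unknown exposure(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(lags < 0 | lags > 14)) {
    stop("enumerate_models: lags must lie in 0-14")
  }
  tidyr::expand_grid(block = blocks, exposure = exposures,
                     lag = as.integer(lags),
                     stratum_id = strata$stratum_id) |>
    dplyr::select("exposure", "lag", "stratum_id", "block")
}

#' Run the case-crossover model grid
#'
#' Fits one conditional quasi-Poisson model per specification: the
#' stratum-and-block daily count series is joined to the lagged exposure
#' and weather via [attach_lags()], fitted with [fit_model()], and
#' summarised as an IQR-scaled relative risk. Failures (non-convergence,
#' non-identifiable cells) are recorded as rows with `converged = FALSE`,
#' never dropped.
#'
#' @param specs Model specs from [enumerate_models()].
#' @param counts Daily count series from [build_counts()] (must cover the
#'   strata and blocks named in `specs`).
#' @param exposures Daily exposure/weather tibble.
#' @param iqr_scope `"all_days"` (default) computes each exposure's IQR
#'   once from the full daily series; `"per_stratum"` recomputes it from
#'   the days entering each model.
#' @param spline_df Weather spline degrees of freedom, default 3.
#' @param level Confidence level for the RR interval.
#' @return Tibble with one row per spec: the spec columns plus `beta`,
#'   `se_beta`, `dispersion`, `iqr`, `rr`, `lower`, `upper`, `p_value`,
#'   `significant_positive` (lower CI bound > 1), `converged`, `n_days`,
#'   `n_dropped`.
#' @export
run_grid <- function(specs, counts, exposures,
                     iqr_scope = c("all_days", "per_stratum"),
                     spline_df = 3, level = 0.95) {
  iqr_scope <- match.arg(iqr_scope)
  if (nrow(specs) == 0) {
    return(tibble::tibble(
      exposure = character(0), lag = integer(0), stratum_id = character(0),
      block = character(0), beta = numeric(0), se_beta = numeric(0),
      dispersion = numeric(0), iqr = numeric(0), rr = numeric(0),
      lower = numeric(0), upper = numeric(0), p_value = numeric(0),
      significant_positive = logical(0), converged = logical(0),
      n_days = integer(0), n_dropped = integer(0)
    ))
  }
  global_iqr <- vapply(unique(specs$exposure), function(e) {
    v <- exposures[[e]]
    if (sum(!is.na(v)) >= 4) compute_iqr(v) else NA_real_
  }, numeric(1))
  res <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    cell <- counts[counts$stratum_id == sp$stratum_id &
                     counts$block == sp$block,
                   c("date", "count")]
    row <- tibble::tibble(
      exposure = sp$exposure, lag = sp$lag, stratum_id = sp$stratum_id,
      block = sp$block, beta = NA_real_, se_beta = NA_real_,
      dispersion = NA_real_, iqr = NA_real_, rr = NA_real_,
      lower = NA_real_, upper = NA_real_, p_value = NA_real_,
      significant_positive = FALSE, converged = FALSE,
      n_days = 0L, n_dropped = 0L
    )
    md <- tryCatch(attach_lags(cell, exposures, sp$exposure, sp$lag),
                   error = function(e) NULL)
    if (!is.null(md) && nrow(md) > 0) {
      row$n_dropped <- attr(md, "n_dropped")
      fit <- tryCatch(fit_model(md, spline_df = spline_df),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        iqr <- if (iqr_scope == "all_days") global_iqr[[sp$exposure]]
               else compute_iqr(md$exposure)
        row$beta <- fit$beta[1]
        row$se_beta <- fit$se_beta[1]
        row$dispersion <- fit$dispersion
        row$converged <- fit$converged
        row$n_days <- fit$n_days
        row$iqr <- iqr
        if (fit$converged && is.finite(iqr) && iqr > 0) {
          rr <- rr_from_fit(fit, delta = iqr, level = level)
          row$rr <- rr$rr
          row$lower <- rr$lower
          row$upper <- rr$upper
          z <- fit$beta[1] / fit$se_beta[1]
          row$p_value <- 2 * stats::pnorm(-abs(z))
          row$significant_positive <- rr$lower > 1
        }
      }
    }
    res[[i]] <- row
  }
  dplyr::bind_rows(res)
}

#' Count significant positive associations across the grid
#'
#' Arranges the number of models whose IQR-scaled RR has a lower
#' confidence bound above 1 into the three standard summary layouts:
#' strata x exposures, exposures x lags and strata x lags. Marginal
#' totals of every arrangement equal the overall number of flagged
#' models.
#'
#' @param results Grid result tibble from [run_grid()].
#' @return List of class `association_counts` with integer matrices
#'   `strata_by_exposure`, `exposure_by_lag`, `strata_by_lag`, the scalar
#'   `total`, and `flagged` (the flagged result rows).
#' @export
significance_counts <- function(results) {
  stopifnot(all(c("exposure", "lag", "stratum_id",
                  "significant_positive") %in% names(results)))
  strata_lv <- unique(results$stratum_id)
  expo_lv <- unique(results$exposure)
  lag_lv <- sort(unique(results$lag))
  f <- results[results$significant_positive %in% TRUE, ]
  tab <- function(r, c, rl, cl) {
    m <- table(factor(r, levels = rl), factor(c, levels = cl))
    matrix(as.integer(m), nrow = length(rl),
           dimnames = list(rl, as.character(cl)))
  }
  structure(
    list(
      strata_by_exposure = tab(f$stratum_id, f$exposure, strata_lv, expo_lv),
      exposure_by_lag = tab(f$exposure, f$lag, expo_lv, lag_lv),
      strata_by_lag = tab(f$stratum_id, f$lag, strata_lv, lag_lv),
      total = nrow(f),
      flagged = f
    ),
    class = "association_counts"
  )
}

#' @export
print.association_counts <- function(x, ...) {
  cat("Significant positive associations:", x$total, "models\n")
  cat("Exposure x lag counts:\n")
  print(x$exposure_by_lag)
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values for a grid result
#'
#' Optional multiplicity summary: adds a `p_adjusted` column (BH false
#' discovery rate over the converged models). The primary analysis
#' reports unadjusted per-model tests; this column is a sensitivity aid,
#' off the main path.
#'
#' @param results Grid result tibble from [run_grid()].
#' @return `results` with a `p_adjusted` column.
#' @export
adjust_grid_pvalues <- function(results) {
  p <- results$p_value
  adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  results$p_adjusted <- adj
  results
}
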