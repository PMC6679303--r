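#' Agreement statistics between predicted and reference series
#'
#' The three comparison statistics used throughout: root mean square error,
#' mean relative error (mean of absolute relative deviations, in percent) and
#' R-squared. R-squared defaults to the squared Pearson correlation; a
#' goodness-of-fit form `1 - SSE/SST` is available behind `r2_method`.
#'
#' @param predicted,reference numeric vectors of equal length >= 2.
#' @param r2_method `"pearson"` (squared correlation) or `"gof"`
#'   (`1 - SSE/SST`).
#' @return list with `r2`, `mre` (percent, `NA` with a warning if any
#'   reference value is zero), `rmse` and `n`.
#' @export
fit_metrics <- function(predicted, reference,
                        r2_method = c("pearson", "gof")) {
  r2_method <- match.arg(r2_method)
  stopifnot(length(predicted) == length(reference))
  if (length(predicted) < 2) stop("need n >= 2 paired values")
  if (!all(is.finite(predicted)) || !all(is.finite(reference))) {
    stop("metrics need finite inputs")
  }
  rmse <- sqrt(mean((predicted - reference)^2))
  if (any(reference == 0)) {
    warning("reference contains zero values; MRE undefined, reported NA")
    mre <- NA_real_
  } else {
    mre <- mean(abs(predicted - reference) / abs(reference)) * 100
  }
  r2 <- if (r2_method == "pearson") {
    if (stats::sd(predicted) == 0 || stats::sd(reference) == 0) NA_real_
    else stats::cor(predicted, reference)^2
  } else {
    1 - sum((predicted - reference)^2) / sum((reference - mean(reference))^2)
  }
  list(r2 = r2, mre = mre, rmse = rmse, n = length(predicted))
}

#' Scheme comparison table
#'
#' One metrics row per scheme against a common reference yield set, plus the
#' RMSE change versus the open-loop row (reported unrounded). The machine
#' analogue of a scheme-performance table.
#'
#' @param yields named list of per-scheme predicted yield vectors (names are
#'   scheme labels; all the same length).
#' @param reference reference (true or measured) yields, matching each
#'   vector.
#' @param r2_method passed to [fit_metrics()].
#' @return data.frame `scheme,r2,mre_pct,rmse_kg_ha,n,delta_rmse_vs_open_loop`
#'   (delta column present when an `open_loop` entry exists). Row order
#'   follows the input; the statistics are invariant to it.
#' @export
compare_schemes <- function(yields, reference, r2_method = "pearson") {
  if (is.null(names(yields)) || any(names(yields) == "")) {
    stop("yields must be a named list of scheme vectors")
  }
  lens <- vapply(yields, length, 0L)
  if (any(lens != length(reference))) {
    stop("every scheme must cover the same reference set")
  }
  rows <- do.call(rbind, lapply(names(yields), function(sc) {
    m <- fit_metrics(yields[[sc]], reference, r2_method = r2_method)
    data.frame(scheme = sc, r2 = m$r2, mre_pct = m$mre,
               rmse_kg_ha = m$rmse, n = m$n)
  }))
  if ("open_loop" %in% rows$scheme) {
    base <- rows$rmse_kg_ha[rows$scheme == "open_loop"][1]
    rows$delta_rmse_vs_open_loop <- base - rows$rmse_kg_ha
  }
  rows
}

#' Write a scheme comparison CSV
#'
#' @param comparison output of [compare_schemes()].
#' @param path output path (`scheme,r2,mre_pct,rmse_kg_ha,n`).
#' @export
write_comparison_csv <- function(comparison, path) {
  utils::write.csv(comparison, path, row.names = FALSE, quote = FALSE)
}

#' Regional masked run
#'
#' Applies the wheat-fraction mask (cells simulated only when the fraction
#' strictly exceeds the threshold), runs the configured scheme on every
#' compliant cell with its own parameters and observations — each cell's
#' observations are averaged per date and variable before assimilation — and
#' returns the per-cell yield table with a spatial summary. The regional
#' open-loop is the deterministic base-parameter run per cell (no ensemble),
#' matching its role as the no-update baseline.
#'
#' @param region output of [generate_region()] (or the same structure read
#'   from files).
#' @param config a [scheme_config()]; `ensemble_size` may be reduced for
#'   regional work.
#' @return list with `cells` (data.frame `cell_id,row,col,wheat_fraction,
#'   included,yield_kg_ha`) and `summary` (compliant cell count, mean yield,
#'   spatial s.d. and coefficient of variation).
#' @export
regional_run <- function(region, config) {
  cells <- region$cells
  included <- which(cells$included)
  if (!length(included)) stop("no grid cell exceeds the wheat fraction threshold")
  cells$yield_kg_ha <- NA_real_
  for (i in included) {
    p <- region$params[[i]]
    obs <- region$observations[[i]]
    if (!is.null(obs) && nrow(obs)) {
      obs <- stats::aggregate(cbind(value, rel_error) ~ date + variable,
                              data = obs, FUN = mean)
      obs <- obs[order(obs$date, obs$variable), ]
    }
    if (config$scheme == "open_loop") {
      cells$yield_kg_ha[i] <-
        run_season(p$crop, p$soil, region$weather)$yield_kg_ha
    } else {
      r <- run_scheme(config, p$crop, p$soil, region$weather, obs)
      cells$yield_kg_ha[i] <- r$yield_mean
    }
  }
  y <- cells$yield_kg_ha[included]
  list(cells = cells,
       summary = list(n_included = length(included),
                      mean_yield = mean(y),
                      sd_yield = stats::sd(y),
                      cv_yield = stats::sd(y) / mean(y)))
}

#' Write regional per-cell yields to CSV
#'
#' @param regional output of [regional_run()].
#' @param path output path
#'   (`cell_id,row,col,wheat_fraction,included,yield_kg_ha`).
#' @export
write_regional_csv <- function(regional, path) {
  utils::write.csv(regional$cells, path, row.names = FALSE, quote = FALSE)
}
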