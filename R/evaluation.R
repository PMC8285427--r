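#' Modelled rate matrix from a fit
#'
#' mu_it = E_it * mean_s exp(eta_it^(s)); with `per_100k = TRUE` the
#' modelled counts are converted to rates per 100,000 population.
#'
#' @param fit a `bym_fit`.
#' @param panel the `panel_data` the model was fitted to.
#' @param per_100k return rates per 100,000 instead of counts.
#' @return an R x T matrix.
#' @export
modelled_rates <- function(fit, panel, per_100k = FALSE) {
  if (!identical(fit$region_ids, panel$region_ids) ||
      length(fit$month_index) != ncol(panel$cases)) {
    stop("fit and panel are misaligned")
  }
  mu <- panel$E * fit$mean_exp_eta
  if (per_100k) mu / panel$population * 1e5 else mu
}

#' Pearson correlation of region-level multi-year mean rates
#'
#' Each region contributes its time-mean observed rate and time-mean
#' modelled rate; the statistic is the Pearson correlation across regions.
#'
#' @param observed,modelled R x T rate (or count) matrices.
#' @return correlation in [-1, 1].
#' @export
spatial_correlation <- function(observed, modelled) {
  if (!all(dim(observed) == dim(modelled))) stop("dimension mismatch")
  if (nrow(observed) < 3L) stop("need at least 3 regions")
  a <- rowMeans(observed); b <- rowMeans(modelled)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero variance")
  stats::cor(a, b)
}

#' Pearson correlation of nationally aggregated monthly rates
#'
#' Observed and modelled counts are aggregated across all regions each
#' month and converted to rates with the summed population; the statistic
#' is the Pearson correlation across months.
#'
#' @param observed,modelled R x T count matrices.
#' @param population R x T population matrix used as the denominator.
#' @return correlation in [-1, 1].
#' @export
temporal_correlation <- function(observed, modelled, population = NULL) {
  if (!all(dim(observed) == dim(modelled))) stop("dimension mismatch")
  if (ncol(observed) < 3L) stop("need at least 3 months")
  if (is.null(population)) population <- matrix(1, nrow(observed), ncol(observed))
  a <- colSums(observed) / colSums(population)
  b <- colSums(modelled) / colSums(population)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero variance")
  stats::cor(a, b)
}

#' Pearson correlation of region-by-year rates (model-comparison statistic)
#'
#' Observed and modelled counts are summed within calendar-year blocks per
#' region and converted to rates; the statistic is the Pearson correlation
#' across all region-year cells. This is the aggregation level on which
#' competing models are compared: time-constant spatial effects and
#' region-constant temporal effects cannot express region-by-year
#' interaction, so improvements here reflect genuine covariate signal
#' rather than random-effect flexibility.
#'
#' @param observed,modelled R x T count matrices.
#' @param population R x T population matrix.
#' @param year_block months per block (default 12).
#' @return correlation in [-1, 1].
#' @export
comparison_correlation <- function(observed, modelled, population,
                                   year_block = 12L) {
  if (!all(dim(observed) == dim(modelled))) stop("dimension mismatch")
  T <- ncol(observed)
  ny <- T %/% year_block
  if (ny < 1L) stop("fewer months than one year block")
  blocks <- function(m) {
    vapply(seq_len(ny), function(yy) {
      rowSums(m[, ((yy - 1) * year_block + 1):(yy * year_block), drop = FALSE])
    }, numeric(nrow(m)))
  }
  o <- blocks(observed) / blocks(population)
  m <- blocks(modelled) / blocks(population)
  if (stats::sd(as.vector(o)) == 0 || stats::sd(as.vector(m)) == 0) {
    stop("zero variance")
  }
  stats::cor(as.vector(o), as.vector(m))
}

#' Observed-versus-modelled evaluation report
#'
#' Compares modelled and observed incidence the way the headline
#' correlation diagnostics do: across regions (multi-year means of rates
#' per 100,000) and across months (nationally aggregated rates).
#'
#' @param fit a `bym_fit`.
#' @param panel the fitted `panel_data`.
#' @return an object of class `kd_eval` with `spatial_correlation`,
#'   `temporal_correlation` and per-region / per-month tables.
#' @export
evaluate_fit <- function(fit, panel) {
  mu <- modelled_rates(fit, panel)
  obs_rate <- panel$cases / panel$population * 1e5
  mod_rate <- mu / panel$population * 1e5
  sp <- spatial_correlation(obs_rate, mod_rate)
  tc <- temporal_correlation(panel$cases, mu, panel$population)
  cc <- if (ncol(panel$cases) >= 12L) {
    comparison_correlation(panel$cases, mu, panel$population)
  } else NA_real_
  per_region <- data.frame(region_id = panel$region_ids,
                           observed = rowMeans(obs_rate),
                           modelled = rowMeans(mod_rate))
  pop_t <- colSums(panel$population)
  per_month <- data.frame(month_index = panel$month_index,
                          observed = colSums(panel$cases) / pop_t * 1e5,
                          modelled = colSums(mu) / pop_t * 1e5)
  structure(list(spatial_correlation = sp,
                 temporal_correlation = tc,
                 comparison_correlation = cc,
                 per_region = per_region,
                 per_month = per_month),
            class = "kd_eval")
}

#' @export
print.kd_eval <- function(x, ...) {
  cat("Observed vs modelled incidence\n")
  cat("  spatial correlation (across regions):",
      round(x$spatial_correlation, 3), "\n")
  cat("  temporal correlation (across months):",
      round(x$temporal_correlation, 3), "\n")
  if (!is.na(x$comparison_correlation)) {
    cat("  region-by-year correlation (model comparison):",
        round(x$comparison_correlation, 3), "\n")
  }
  invisible(x)
}
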