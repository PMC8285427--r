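#' WAIC ladder over temporal structures
#'
#' Fits the model with increasing temporal structure — linear trend only,
#' plus a first-order random walk, plus the period-12 seasonal term — and
#' returns the WAIC of each rung. The rung with the lowest WAIC is the base
#' model of the subsequent covariate analysis.
#'
#' @param panel a `panel_data`.
#' @param map a `region_map`.
#' @param config a `kd_config`; per-rung seeds derive from `config$seed`.
#' @param adjust covariates forced into every rung (default none).
#' @param include_iid_time carry an unstructured monthly effect in every
#'   rung (default FALSE).
#' @return list with `ladder` (data.frame model/waic), `best` (name of the
#'   arg-min rung) and `fits` (the three fits).
#' @export
build_temporal_ladder <- function(panel, map, config = kd_config(),
                                  adjust = character(0),
                                  include_iid_time = FALSE) {
  rungs <- list(
    linear = model_spec(adjust, TRUE, FALSE, FALSE, include_iid_time),
    linear_rw1 = model_spec(adjust, TRUE, TRUE, FALSE, include_iid_time),
    linear_rw1_seasonal = model_spec(adjust, TRUE, TRUE, TRUE,
                                     include_iid_time))
  fits <- vector("list", length(rungs))
  names(fits) <- names(rungs)
  waics <- numeric(length(rungs))
  for (i in seq_along(rungs)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 100L + i)
    fits[[i]] <- kd_bym(panel, map, rungs[[i]], cfg)
    waics[i] <- fits[[i]]$waic$waic
  }
  ladder <- data.frame(model = names(rungs), waic = waics,
                       stringsAsFactors = FALSE)
  list(ladder = ladder, best = names(rungs)[which.min(waics)], fits = fits)
}

#' Univariable WAIC screening of candidate covariates
#'
#' Fits the adjusted base model (adjustment covariates always present, never
#' subject to selection), then one model per candidate added alone (together
#' with its companion adjustment column, when declared). A candidate is
#' screened into the multivariable model when it lowers the WAIC of the
#' adjusted base model by more than `config$screening_delta` (default 1).
#'
#' @param panel a `panel_data`.
#' @param map a `region_map`.
#' @param candidates character vector of candidate covariate names.
#' @param config a `kd_config`.
#' @param adjust adjustment covariates forced into every model.
#' @param companions named list: `companions[[cand]]` is a covariate that
#'   must co-enter any model containing `cand`.
#' @param spec_base template `model_spec` fixing the temporal structure.
#' @return list with `base_fit`, `base_waic` and `rows` (a data.frame with
#'   per-candidate WAIC, delta, screened_in flag, the five univariable SIR
#'   percentiles and the per-fit seed).
#' @export
screen_univariable <- function(panel, map, candidates,
                               config = kd_config(),
                               adjust = character(0),
                               companions = list(),
                               spec_base = model_spec()) {
  for (nm in c(candidates, adjust, unlist(companions))) {
    if (is.null(panel$covariates[[nm]])) stop("candidate absent from panel: ", nm)
  }
  base_spec <- spec_with_covariates(spec_base, adjust)
  cfg <- config
  cfg$seed <- derive_seed(config$seed, 200L)
  base_fit <- kd_bym(panel, map, base_spec, cfg)
  base_waic <- base_fit$waic$waic

  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[i]
    covs <- unique(c(adjust, cand, companions[[cand]]))
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 200L + i)
    f <- kd_bym(panel, map, spec_with_covariates(spec_base, covs), cfg)
    pr <- summarize_sir(f, cand)
    rows[[i]] <- data.frame(name = cand,
                            univariable_waic = f$waic$waic,
                            delta_vs_adjusted_base = base_waic - f$waic$waic,
                            screened_in = (base_waic - f$waic$waic) >
                              config$screening_delta,
                            p2.5 = pr[1], p25 = pr[2], p50 = pr[3],
                            p75 = pr[4], p97.5 = pr[5],
                            fit_seed = cfg$seed,
                            stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  rows <- rows[order(rows$univariable_waic), , drop = FALSE]
  list(base_fit = base_fit, base_waic = base_waic, rows = rows)
}

#' Greedy backward elimination by multivariable WAIC
#'
#' Starting from the screened-in covariates (plus forced adjustment
#' covariates), repeatedly tests the deletion of each removable covariate,
#' removes the deletion that most lowers the WAIC if any deletion lowers
#' it, and stops when every deletion raises the WAIC.
#'
#' @param panel a `panel_data`.
#' @param map a `region_map`.
#' @param screened character vector of screened-in covariate names.
#' @param config a `kd_config`.
#' @param adjust forced adjustment covariates (never eliminable).
#' @param companions named list of companion adjustments per covariate.
#' @param spec_base template `model_spec` for the temporal structure.
#' @return list with `final_covariates`, `final_fit`, `final_waic`,
#'   `sir` (multivariable SIR percentiles for the retained covariates) and
#'   `trace` (data.frame of removals with WAIC before/after and seeds).
#' @export
backward_eliminate <- function(panel, map, screened,
                               config = kd_config(),
                               adjust = character(0),
                               companions = list(),
                               spec_base = model_spec()) {
  current <- unique(screened)
  counter <- 300L
  fit_model <- function(covs, k) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, k)
    all_covs <- unique(c(adjust, covs,
                         unlist(companions[intersect(names(companions), covs)])))
    kd_bym(panel, map, spec_with_covariates(spec_base, all_covs), cfg)
  }
  fit <- fit_model(current, counter)
  current_waic <- fit$waic$waic
  trace <- list()
  repeat {
    if (!length(current)) break
    best_drop <- NULL; best_waic <- current_waic; best_fit <- NULL
    best_seed <- NA_integer_
    for (cand in current) {
      counter <- counter + 1L
      f <- fit_model(setdiff(current, cand), counter)
      if (f$waic$waic < best_waic) {
        best_drop <- cand; best_waic <- f$waic$waic; best_fit <- f
        best_seed <- derive_seed(config$seed, counter)
      }
    }
    if (is.null(best_drop)) break
    trace[[length(trace) + 1L]] <- data.frame(
      removed = best_drop, waic_before = current_waic,
      waic_after = best_waic, fit_seed = best_seed,
      stringsAsFactors = FALSE)
    current <- setdiff(current, best_drop)
    current_waic <- best_waic
    fit <- best_fit
  }
  sir <- if (length(current)) {
    t(vapply(current, function(nm) summarize_sir(fit, nm), numeric(5)))
  } else matrix(numeric(0), 0, 5)
  list(final_covariates = current, final_fit = fit,
       final_waic = current_waic, sir = sir,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(removed = character(0)))
}

#' Full covariate-selection pipeline
#'
#' Temporal ladder, adjusted base model, univariable WAIC screening and
#' greedy backward elimination, reproducing the model-building ladder of
#' the analysis (base model, adjusted base model, main regression model).
#' Deterministic for a given `config$seed`.
#'
#' @inheritParams screen_univariable
#' @return an object of class `selection_report`.
#' @export
kd_select <- function(panel, map, candidates, config = kd_config(),
                      adjust = character(0), companions = list(),
                      spec_base = model_spec()) {
  ladder <- build_temporal_ladder(panel, map, config, adjust = character(0))
  screening <- screen_univariable(panel, map, candidates, config, adjust,
                                  companions, spec_base)
  screened <- screening$rows$name[screening$rows$screened_in]
  elim <- backward_eliminate(panel, map, screened, config, adjust,
                             companions, spec_base)
  structure(list(ladder = ladder$ladder,
                 base_model = ladder$best,
                 adjusted_base_waic = screening$base_waic,
                 screening = screening$rows,
                 elimination_trace = elim$trace,
                 final_covariates = elim$final_covariates,
                 final_waic = elim$final_waic,
                 final_sir = elim$sir,
                 final_fit = elim$final_fit),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Covariate selection report\n\nTemporal ladder:\n")
  print(x$ladder, row.names = FALSE)
  cat("\nAdjusted base WAIC:", round(x$adjusted_base_waic, 1), "\n")
  cat("\nUnivariable screening (delta > threshold screened in):\n")
  print(x$screening[, c("name", "univariable_waic",
                        "delta_vs_adjusted_base", "screened_in")],
        row.names = FALSE)
  cat("\nFinal model:",
      if (length(x$final_covariates)) paste(x$final_covariates, collapse = ", ")
      else "(no covariates)",
      " WAIC:", round(x$final_waic, 1), "\n")
  invisible(x)
}

spec_with_covariates <- function(spec, covariates) {
  model_spec(covariates = covariates,
             include_linear_trend = spec$include_linear_trend,
             include_rw1 = spec$include_rw1,
             include_seasonal = spec$include_seasonal,
             include_iid_time = spec$include_iid_time)
}
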