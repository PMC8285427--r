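#' Write fit summaries to disk
#'
#' Writes a JSON summary (WAIC; per-covariate SIR percentile landmarks at
#' 2.5/25/50/75/97.5; fixed-effect posterior means; convergence diagnostics)
#' plus CSVs of the per-region and per-month posterior mean SIR. Reading the
#' summary back with [read_fit_summary()] reproduces it exactly.
#'
#' @param fit a `bym_fit`.
#' @param path output directory (created if needed).
#' @return the summary list, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "bym_fit"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sir <- fit$sir_summaries
  fixed <- as.list(coef(fit))
  summary <- list(
    waic = fit$waic,
    n_draws = nrow(fit$draws),
    fixed_effects = fixed,
    sir_percentiles = if (nrow(sir)) {
      stats::setNames(lapply(seq_len(nrow(sir)), function(i) {
        as.list(stats::setNames(sir[i, ],
                                c("p2.5", "p25", "p50", "p75", "p97.5")))
      }), rownames(sir))
    } else stats::setNames(list(), character(0)),
    diagnostics = list(max_rhat = fit$diagnostics$max_rhat,
                       converged = fit$diagnostics$converged))
  # 17 significant digits: doubles survive the write/read round trip exactly
  jsonlite::write_json(summary, file.path(path, "fit_summary.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  utils::write.csv(fit$spatial_sir, file.path(path, "sir_region.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$temporal_sir, file.path(path, "sir_month.csv"),
                   row.names = FALSE)
  invisible(summary)
}

#' Read a fit summary written by [write_fit()]
#'
#' @param path directory containing `fit_summary.json`.
#' @return the summary list.
#' @export
read_fit_summary <- function(path) {
  f <- file.path(path, "fit_summary.json")
  if (!file.exists(f)) stop("no fit summary at ", path)
  jsonlite::fromJSON(f, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Write a region map to GeoJSON
#'
#' Emits a FeatureCollection with a `region_id` and `population` property
#' per feature. Regions without polygons get a null geometry.
#'
#' @param map a `region_map`.
#' @param file output path.
#' @export
write_region_geojson <- function(map, file) {
  stopifnot(inherits(map, "region_map"))
  features <- lapply(map$ids, function(id) {
    geom <- if (!is.null(map$polygons) && !is.null(map$polygons[[id]])) {
      ring <- close_ring(map$polygons[[id]])
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)), function(i) {
             c(ring[i, 1], ring[i, 2])
           })))
    } else NULL
    list(type = "Feature",
         properties = list(region_id = id,
                           population = unname(map$population[[id]])),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' Write a panel to long-format CSV
#'
#' @param panel a `panel_data`.
#' @param file output path.
#' @export
write_panel <- function(panel, file) {
  utils::write.csv(as.data.frame(panel), file, row.names = FALSE)
  invisible(file)
}
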