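#' Region-by-month observation panel
#'
#' The model's observation table: a dense region x month grid of case
#' counts, at-risk populations, expected counts and covariates. Covariates
#' are stored as named region x month matrices so the linear predictor is a
#' plain sum of matrices.
#'
#' @param cases integer matrix (regions x months) of case counts.
#' @param population numeric matrix (or vector recycled over months) of
#'   at-risk populations.
#' @param covariates named list of numeric region x month matrices.
#' @param E optional matrix of expected counts; computed by
#'   [expected_counts()] when `NULL`.
#' @param region_ids,month_index row/column labels; defaults seq along dims.
#' @param month0 (year, month) anchor for time index 1 (default April 2004).
#' @return an object of class `panel_data`.
#' @export
panel_data <- function(cases, population, covariates = list(), E = NULL,
                       region_ids = NULL, month_index = NULL,
                       month0 = c(2004L, 4L)) {
  cases <- as.matrix(cases)
  R <- nrow(cases); T <- ncol(cases)
  if (is.null(dim(population))) {
    if (length(population) != R) stop("population length must match regions")
    population <- matrix(population, R, T)
  }
  population <- as.matrix(population)
  if (!all(dim(population) == c(R, T))) stop("population dimension mismatch")
  if (any(cases < 0)) stop("negative case counts")
  if (any(cases != round(cases))) stop("case counts must be integers")
  if (any(population < 0)) stop("negative populations")
  if (anyNA(cases) || anyNA(population)) stop("incomplete panel")
  if (length(covariates)) {
    if (is.null(names(covariates)) || any(!nzchar(names(covariates)))) {
      stop("covariates must be a named list")
    }
    for (nm in names(covariates)) {
      covariates[[nm]] <- as.matrix(covariates[[nm]])
      if (!all(dim(covariates[[nm]]) == c(R, T))) {
        stop("covariate ", nm, " dimension mismatch")
      }
    }
  }
  if (is.null(region_ids)) region_ids <- rownames(cases) %||% as.character(seq_len(R))
  if (is.null(month_index)) month_index <- seq_len(T)
  obj <- structure(list(cases = unname(cases),
                        population = unname(population),
                        covariates = lapply(covariates, unname),
                        E = NULL,
                        region_ids = as.character(region_ids),
                        month_index = as.integer(month_index),
                        month0 = as.integer(month0)),
                   class = "panel_data")
  obj$E <- if (is.null(E)) expected_counts(obj) else {
    E <- as.matrix(E)
    if (!all(dim(E) == c(R, T))) stop("E dimension mismatch")
    if (any(E <= 0)) stop("expected counts must be positive")
    unname(E)
  }
  obj
}

#' @export
print.panel_data <- function(x, ...) {
  cat("panel_data:", nrow(x$cases), "regions x", ncol(x$cases), "months\n")
  cat("  total cases:", sum(x$cases),
      " mean count/cell:", signif(mean(x$cases), 3), "\n")
  if (length(x$covariates)) {
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.panel_data <- function(x) dim(x$cases)

#' @export
as.data.frame.panel_data <- function(x, ...) {
  R <- nrow(x$cases); T <- ncol(x$cases)
  out <- data.frame(region_id = rep(x$region_ids, T),
                    month_index = rep(x$month_index, each = R),
                    cases = as.vector(x$cases),
                    population = as.vector(x$population),
                    E = as.vector(x$E))
  for (nm in names(x$covariates)) out[[nm]] <- as.vector(x$covariates[[nm]])
  out
}

#' Read a long-format panel CSV
#'
#' Expects columns `region_id, month_index, cases, population`; every other
#' numeric column is taken as a covariate. The panel must be complete: every
#' (region, month) pair present exactly once.
#'
#' @param file path to a CSV file (comma separator, header, '.' decimal).
#' @param month0 calendar anchor passed to [panel_data()].
#' @return a `panel_data` object.
#' @export
read_panel <- function(file, month0 = c(2004L, 4L)) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  required <- c("region_id", "month_index", "cases", "population")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  regions <- sort(unique(as.character(df$region_id)))
  months <- sort(unique(as.integer(df$month_index)))
  R <- length(regions); T <- length(months)
  key <- paste(df$region_id, df$month_index)
  if (anyDuplicated(key)) stop("duplicated (region, month) keys")
  if (nrow(df) != R * T) stop("incomplete panel: expected ", R * T,
                              " rows, got ", nrow(df))
  ri <- match(as.character(df$region_id), regions)
  ti <- match(as.integer(df$month_index), months)
  fill <- function(v) {
    m <- matrix(NA_real_, R, T)
    m[cbind(ri, ti)] <- v
    m
  }
  if (any(df$cases < 0)) stop("negative case counts")
  if (any(df$population < 0)) stop("negative populations")
  cov_cols <- setdiff(names(df), c(required, "E"))
  cov_cols <- cov_cols[vapply(df[cov_cols], is.numeric, logical(1))]
  covs <- stats::setNames(lapply(cov_cols, function(nm) fill(df[[nm]])), cov_cols)
  panel_data(cases = fill(df$cases), population = fill(df$population),
             covariates = covs,
             E = if ("E" %in% names(df)) fill(df$E) else NULL,
             region_ids = regions, month_index = months, month0 = month0)
}

#' Expected counts by internal standardization
#'
#' Computes the model offset E: each cell's population times the panel-wide
#' overall rate, so that `sum(E) == sum(cases)` exactly. Regions with larger
#' child populations get proportionally larger expected counts.
#'
#' @param panel a `panel_data` object.
#' @return numeric matrix of expected counts, same shape as `panel$cases`.
#' @export
expected_counts <- function(panel) {
  stopifnot(inherits(panel, "panel_data"))
  tot_pop <- sum(panel$population)
  if (tot_pop <= 0) stop("zero total population")
  panel$population * (sum(panel$cases) / tot_pop)
}
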