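#' Run configuration for the analysis pipeline
#'
#' Bundles the knobs shared across the pipeline stages: the RNG seed, the
#' aggregation target (the analysis collapses small spatial units into a
#' fixed number of regions, 100 by default), MCMC settings, prior
#' hyperparameters, the WAIC screening threshold, and the calendar anchor
#' mapping time index 1 to a (year, month).
#'
#' @param seed integer RNG seed used to derive all per-fit seeds.
#' @param n_target_regions number of analysis regions the aggregation stops
#'   at (default 100).
#' @param mcmc list overriding any of `n_chains`, `n_warmup`, `n_samples`,
#'   `thin` (defaults 4, 2000, 2000, 1).
#' @param priors list overriding any of `precision_gamma_shape`,
#'   `precision_gamma_rate` (Gamma prior on all precisions, default
#'   Gamma(1, 5e-5)) and `fixed_effect_sd` (Normal sd for intercept, slopes
#'   and trend, default 31.6).
#' @param screening_delta WAIC improvement a candidate covariate must exceed
#'   to enter the multivariable model (default 1).
#' @param month0 length-2 integer vector (year, month) for time index 1;
#'   default April 2004.
#' @param paths optional named list of input/output locations.
#' @return an object of class `kd_config`.
#' @export
kd_config <- function(seed = 1L,
                      n_target_regions = 100L,
                      mcmc = list(),
                      priors = list(),
                      screening_delta = 1,
                      month0 = c(2004L, 4L),
                      paths = list()) {
  mcmc <- utils::modifyList(
    list(n_chains = 4L, n_warmup = 2000L, n_samples = 2000L, thin = 1L), mcmc)
  priors <- utils::modifyList(
    list(precision_gamma_shape = 1, precision_gamma_rate = 5e-5,
         fixed_effect_sd = 31.6), priors)
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (n_target_regions < 1L) stop("n_target_regions must be >= 1")
  for (nm in c("n_chains", "n_warmup", "n_samples", "thin")) {
    if (mcmc[[nm]] < 1L) stop("mcmc$", nm, " must be >= 1")
  }
  if (screening_delta <= 0) stop("screening_delta must be > 0")
  if (length(month0) != 2L || month0[2L] < 1L || month0[2L] > 12L) {
    stop("month0 must be c(year, month) with month in 1..12")
  }
  if (priors$fixed_effect_sd <= 0 || priors$precision_gamma_shape <= 0 ||
      priors$precision_gamma_rate <= 0) {
    stop("prior hyperparameters must be positive")
  }
  structure(list(seed = as.integer(seed),
                 n_target_regions = as.integer(n_target_regions),
                 mcmc = lapply(mcmc, as.integer),
                 priors = priors,
                 screening_delta = screening_delta,
                 month0 = as.integer(month0),
                 paths = paths),
            class = "kd_config")
}

#' @export
print.kd_config <- function(x, ...) {
  cat("Run configuration\n")
  cat("  seed:", x$seed, " target regions:", x$n_target_regions, "\n")
  cat("  mcmc:", x$mcmc$n_chains, "chains,", x$mcmc$n_warmup, "warmup +",
      x$mcmc$n_samples, "samples, thin", x$mcmc$thin, "\n")
  cat("  priors: tau ~ Gamma(", x$priors$precision_gamma_shape, ",",
      x$priors$precision_gamma_rate, "); fixed effects ~ N(0,",
      x$priors$fixed_effect_sd, "^2)\n")
  cat("  screening delta:", x$screening_delta,
      " month0:", paste(x$month0, collapse = "-"), "\n")
  invisible(x)
}
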