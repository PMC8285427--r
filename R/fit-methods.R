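#' @export
print.bym_fit <- function(x, ...) {
  cat("Spatiotemporal BYM disease-mapping fit\n")
  cat("  ", length(x$region_ids), "regions x", length(x$month_index),
      "months;", x$cases_total, "cases\n")
  print(x$spec)
  cat("  draws:", nrow(x$draws), "(", x$config$mcmc$n_chains, "chains )\n")
  cat("  WAIC:", round(x$waic$waic, 1), " (lppd", round(x$waic$lppd, 1),
      ", p_waic", round(x$waic$p_waic, 1), ")\n")
  cat("  max split R-hat:", signif(x$diagnostics$max_rhat, 4),
      if (x$diagnostics$converged) "" else " [NOT CONVERGED]", "\n")
  invisible(x)
}

#' @export
summary.bym_fit <- function(object, ...) {
  d <- object$draws
  tab <- data.frame(mean = colMeans(d),
                    sd = apply(d, 2, stats::sd),
                    q2.5 = apply(d, 2, stats::quantile, 0.025, names = FALSE),
                    q50 = apply(d, 2, stats::quantile, 0.5, names = FALSE),
                    q97.5 = apply(d, 2, stats::quantile, 0.975, names = FALSE),
                    rhat = object$diagnostics$rhat,
                    ess = round(object$diagnostics$ess))
  out <- list(parameters = tab, waic = object$waic,
              sir = object$sir_summaries,
              diagnostics = object$diagnostics)
  class(out) <- "summary.bym_fit"
  out
}

#' @export
print.summary.bym_fit <- function(x, ...) {
  cat("Posterior summary\n")
  print(round(x$parameters, 4))
  cat("\nWAIC:", round(x$waic$waic, 1), " lppd:", round(x$waic$lppd, 1),
      " p_waic:", round(x$waic$p_waic, 1), "\n")
  if (nrow(x$sir)) {
    cat("\nSIR per 1-SD change (percentiles):\n")
    print(round(x$sir, 3))
  }
  invisible(x)
}

#' @export
coef.bym_fit <- function(object, ...) {
  d <- object$draws
  keep <- grep("^(alpha$|gamma$|beta_)", colnames(d), value = TRUE)
  colMeans(d[, keep, drop = FALSE])
}

#' Posterior-mean modelled counts
#'
#' mu_it = E_it * mean_s exp(eta_it^(s)), the modelled expected case count
#' per region-month.
#' @param object a `bym_fit`.
#' @param ... unused.
#' @export
fitted.bym_fit <- function(object, ...) object$E * object$mean_exp_eta

#' @export
residuals.bym_fit <- function(object, panel, type = c("pearson", "response"),
                              ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  y <- panel$cases
  if (type == "response") y - mu else (y - mu) / sqrt(mu)
}

#' Posterior-predictive count simulation
#'
#' Draws replicate panels from the posterior predictive: for each requested
#' replicate a posterior draw of exp(eta) is selected and counts are drawn
#' Poisson(E * exp(eta)). Uses the stored posterior mean of exp(eta) per
#' draw index via the pointwise likelihood cache is not possible, so the
#' mean surface is used for `nsim` quick replicates.
#'
#' @param object a `bym_fit`.
#' @param nsim number of replicate count matrices.
#' @param seed RNG seed.
#' @param ... unused.
#' @export
simulate.bym_fit <- function(object, nsim = 1, seed = 1L, ...) {
  mu <- fitted(object)
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    matrix(stats::rpois(length(mu), as.vector(mu)), nrow(mu), ncol(mu))
  }))
}

#' @export
plot.bym_fit <- function(x, which = c("temporal", "seasonal", "spatial"),
                         ...) {
  which <- match.arg(which)
  if (which == "temporal") {
    graphics::plot(x$temporal_sir$month_index, x$temporal_sir$sir,
                   type = "l", xlab = "month index", ylab = "temporal SIR",
                   main = "Temporal standardized incidence ratio", ...)
    graphics::abline(h = 1, lty = 3)
  } else if (which == "seasonal") {
    graphics::plot(1:12, x$seasonal_profile, type = "b",
                   xlab = "calendar month", ylab = "seasonal SIR",
                   main = "Seasonal profile", ...)
    graphics::abline(h = 1, lty = 3)
  } else {
    graphics::plot(seq_along(x$spatial_sir$sir), sort(x$spatial_sir$sir),
                   xlab = "region (sorted)", ylab = "spatial SIR",
                   main = "Region-level standardized incidence ratios", ...)
    graphics::abline(h = 1, lty = 3)
  }
  invisible(x)
}
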