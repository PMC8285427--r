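#' Declarative model specification
#'
#' Describes which terms enter the log-linear predictor of the hierarchical
#' Poisson disease-mapping model. The spatial convolution (a structured ICAR
#' effect plus an unstructured iid effect, the Besag-York-Mollie model) is
#' always present; temporal structure (linear trend, first-order random
#' walk, period-12 seasonal term, and optionally an unstructured iid monthly
#' effect) and covariates are switchable.
#'
#' @param covariates character vector of covariate names (must exist in the
#'   panel the model is fitted to).
#' @param include_linear_trend,include_rw1,include_seasonal logicals for the
#'   temporal components (all default TRUE, the full temporal structure).
#' @param include_iid_time logical; add an unstructured iid monthly effect
#'   (default FALSE).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(covariates = character(0),
                       include_linear_trend = TRUE,
                       include_rw1 = TRUE,
                       include_seasonal = TRUE,
                       include_iid_time = FALSE) {
  structure(list(covariates = as.character(covariates),
                 include_linear_trend = isTRUE(include_linear_trend),
                 include_rw1 = isTRUE(include_rw1),
                 include_seasonal = isTRUE(include_seasonal),
                 include_iid_time = isTRUE(include_iid_time)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  terms <- c("intercept", "BYM spatial (ICAR + iid)",
             if (x$include_linear_trend) "linear trend",
             if (x$include_rw1) "RW1 trend",
             if (x$include_seasonal) "seasonal (period 12)",
             if (x$include_iid_time) "iid monthly",
             x$covariates)
  cat("model_spec:", paste(terms, collapse = " + "), "\n")
  invisible(x)
}

#' Latent state of the hierarchical model
#'
#' Collects every latent quantity of the linear predictor: intercept
#' `alpha`, covariate effects `beta` (per standard deviation of the
#' covariate), linear slope `gamma`, spatially structured effects `u`
#' (ICAR), unstructured spatial effects `v`, random-walk trend `phi`,
#' seasonal effects `s` (length T with period-12 structure), optional iid
#' monthly effects `psi`, and the precisions of each random-effect block.
#'
#' @param alpha,beta,gamma fixed effects (beta named by covariate).
#' @param u,v length-R spatial effects.
#' @param phi,s,psi length-T temporal effects (NULL when absent).
#' @param tau_u,tau_v,tau_phi,tau_s,tau_psi positive precisions.
#' @return an object of class `latent_state`.
#' @export
latent_state <- function(alpha = 0, beta = numeric(0), gamma = 0,
                         u = numeric(0), v = numeric(0),
                         phi = NULL, s = NULL, psi = NULL,
                         tau_u = 1, tau_v = 1, tau_phi = 1, tau_s = 1,
                         tau_psi = 1) {
  taus <- c(tau_u, tau_v, tau_phi, tau_s, tau_psi)
  if (any(taus <= 0)) stop("precisions must be > 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, u = u, v = v,
                 phi = phi, s = s, psi = psi,
                 tau_u = tau_u, tau_v = tau_v, tau_phi = tau_phi,
                 tau_s = tau_s, tau_psi = tau_psi),
            class = "latent_state")
}

#' Centered time index
#'
#' Time enters the linear trend as t - mean(t) so the slope is orthogonal to
#' the intercept.
#' @param T number of months.
#' @return numeric vector of length T.
#' @export
centered_time <- function(T) seq_len(T) - (T + 1) / 2

#' Linear predictor of the disease-mapping model
#'
#' eta_it = alpha + x_it' beta + u_i + v_i + gamma * (t - mean(t)) + phi_t
#' + s_t (+ psi_t); terms switched off in `spec` contribute zero.
#'
#' @param state a `latent_state`.
#' @param panel a `panel_data`.
#' @param spec a `model_spec`.
#' @return an R x T matrix.
#' @export
linear_predictor <- function(state, panel, spec) {
  R <- nrow(panel$cases); T <- ncol(panel$cases)
  eta <- matrix(state$alpha, R, T)
  if (length(spec$covariates)) {
    if (length(state$beta) != length(spec$covariates)) {
      stop("beta length does not match spec covariates")
    }
    for (k in seq_along(spec$covariates)) {
      nm <- spec$covariates[k]
      X <- panel$covariates[[nm]]
      if (is.null(X)) stop("covariate not in panel: ", nm)
      eta <- eta + state$beta[k] * X
    }
  }
  if (length(state$u)) {
    if (length(state$u) != R || length(state$v) != R) {
      stop("spatial effect length mismatch")
    }
    eta <- eta + state$u + state$v  # recycled down columns
  }
  if (spec$include_linear_trend) {
    eta <- eta + rep(state$gamma * centered_time(T), each = R)
  }
  if (spec$include_rw1) {
    if (length(state$phi) != T) stop("phi length mismatch")
    eta <- eta + rep(state$phi, each = R)
  }
  if (spec$include_seasonal) {
    if (length(state$s) != T) stop("seasonal effect length mismatch")
    eta <- eta + rep(state$s, each = R)
  }
  if (spec$include_iid_time) {
    if (length(state$psi) != T) stop("psi length mismatch")
    eta <- eta + rep(state$psi, each = R)
  }
  eta
}

#' Poisson log-likelihood with expected-count offset
#'
#' l_it = y_it (log E_it + eta_it) - E_it exp(eta_it) - log(y_it!).
#'
#' @param y counts (matrix or vector).
#' @param eta linear predictor, same shape.
#' @param E positive expected counts, same shape.
#' @return list with `pointwise` (same shape as `y`) and `total`.
#' @export
poisson_loglik <- function(y, eta, E) {
  if (any(y < 0)) stop("negative counts")
  if (any(E <= 0)) stop("expected counts must be positive")
  pw <- y * (log(E) + eta) - E * exp(eta) - lgamma(y + 1)
  list(pointwise = pw, total = sum(pw))
}

# Undirected edge matrix (2 cols of integer indices) from an adjacency
# structure: a region_map, a named adjacency list, or a symmetric matrix.
adjacency_edges <- function(adjacency, ids = NULL) {
  if (inherits(adjacency, "region_map")) {
    ids <- adjacency$ids
    adjacency <- adjacency$adjacency
  }
  if (is.matrix(adjacency)) {
    if (!isSymmetric(unname(adjacency))) stop("asymmetric adjacency")
    idx <- which(adjacency != 0 & upper.tri(adjacency), arr.ind = TRUE)
    return(list(edges = idx, n = nrow(adjacency),
                adj_list = apply_adj_list(adjacency)))
  }
  if (is.list(adjacency)) {
    if (is.null(ids)) ids <- names(adjacency)
    # symmetry check
    for (id in names(adjacency)) {
      for (j in adjacency[[id]]) {
        if (!(id %in% adjacency[[j]])) stop("asymmetric adjacency")
      }
    }
    ii <- match(names(adjacency), ids)
    ea <- integer(0); eb <- integer(0)
    for (k in seq_along(adjacency)) {
      jj <- match(adjacency[[k]], ids)
      keep <- jj > ii[k]
      ea <- c(ea, rep(ii[k], sum(keep))); eb <- c(eb, jj[keep])
    }
    return(list(edges = cbind(ea, eb), n = length(ids),
                adj_list = adjacency))
  }
  stop("unsupported adjacency type")
}

apply_adj_list <- function(m) {
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  stats::setNames(lapply(seq_len(nrow(m)), function(i) ids[which(m[i, ] != 0)]),
                  ids)
}

#' Intrinsic CAR (ICAR) log-density
#'
#' The spatially structured effect penalizes squared differences between
#' adjacent regions: -(tau/2) sum_{i~j} (u_i - u_j)^2 with each undirected
#' pair counted once, plus the normalizing exponent ((R - c)/2) log tau
#' where c is the number of connected components (the ICAR precision matrix
#' tau (D - W) has rank R - c).
#'
#' @param u sum-to-zero effect vector (per connected component).
#' @param tau_u positive precision.
#' @param adjacency a `region_map`, named adjacency list, or symmetric
#'   matrix.
#' @return log-density up to an additive constant.
#' @export
icar_logdensity <- function(u, tau_u, adjacency) {
  if (tau_u <= 0) stop("tau_u must be > 0")
  ae <- adjacency_edges(adjacency)
  if (length(u) != ae$n) stop("u length does not match adjacency")
  q <- sum((u[ae$edges[, 1]] - u[ae$edges[, 2]])^2)
  n_comp <- max(connected_components(ae$adj_list))
  -(tau_u / 2) * q + ((ae$n - n_comp) / 2) * log(tau_u)
}

#' Random-walk-of-order-1 log-density
#'
#' -(tau/2) sum_t (phi_{t+1} - phi_t)^2 + ((T-1)/2) log tau.
#'
#' @param phi effect vector, length >= 2.
#' @param tau_phi positive precision.
#' @return log-density up to an additive constant.
#' @export
rw1_logdensity <- function(phi, tau_phi) {
  if (length(phi) < 2L) stop("RW1 needs length >= 2")
  if (tau_phi <= 0) stop("tau_phi must be > 0")
  -(tau_phi / 2) * sum(diff(phi)^2) + ((length(phi) - 1) / 2) * log(tau_phi)
}

#' Seasonal-model log-density (period 12 by default)
#'
#' The seasonal prior penalizes the sums of every `period` consecutive
#' effects: -(tau/2) sum_{t=1}^{T-period+1} (s_t + ... + s_{t+period-1})^2
#' + ((T - period + 1)/2) log tau.
#'
#' @param s effect vector of length T >= period.
#' @param tau_s positive precision.
#' @param period seasonal cycle length (default 12 months).
#' @return log-density up to an additive constant.
#' @export
seasonal_logdensity <- function(s, tau_s, period = 12L) {
  T <- length(s)
  if (T < period) stop("series shorter than the seasonal period")
  if (tau_s <= 0) stop("tau_s must be > 0")
  w <- seasonal_window_sums(s, period)
  -(tau_s / 2) * sum(w^2) + ((T - period + 1) / 2) * log(tau_s)
}

seasonal_window_sums <- function(s, period = 12L) {
  cs <- cumsum(c(0, s))
  T <- length(s)
  cs[(period + 1L):(T + 1L)] - cs[1L:(T - period + 1L)]
}

#' Joint log-posterior (up to a constant)
#'
#' Sum of the Poisson log-likelihood, the active latent-field log-densities
#' (ICAR, iid spatial, RW1, seasonal, iid monthly), Normal(0, sd^2) priors on
#' alpha, beta and gamma, and Gamma(shape, rate) log-priors on every active
#' precision. Violated identifiability constraints return -Inf with a
#' warning.
#'
#' @param state a `latent_state`.
#' @param panel a `panel_data`.
#' @param spec a `model_spec`.
#' @param adjacency adjacency for the ICAR term (`region_map`, list, or
#'   matrix).
#' @param priors list with `precision_gamma_shape`, `precision_gamma_rate`,
#'   `fixed_effect_sd` (see [kd_config()]).
#' @return scalar log-posterior up to an additive constant.
#' @export
log_posterior <- function(state, panel, spec, adjacency,
                          priors = kd_config()$priors) {
  tol <- 1e-6
  comps <- connected_components(
    if (inherits(adjacency, "region_map")) adjacency$adjacency
    else adjacency_edges(adjacency)$adj_list)
  for (cc in unique(comps)) {
    if (abs(sum(state$u[comps == cc])) > tol * max(1, length(state$u))) {
      warning("sum-to-zero constraint violated for u")
      return(-Inf)
    }
  }
  for (nm in c("phi", "s", "psi")) {
    f <- state[[nm]]
    active <- switch(nm, phi = spec$include_rw1, s = spec$include_seasonal,
                     psi = spec$include_iid_time)
    if (active && abs(sum(f)) > tol * max(1, length(f))) {
      warning("sum-to-zero constraint violated for ", nm)
      return(-Inf)
    }
  }
  eta <- linear_predictor(state, panel, spec)
  lp <- poisson_loglik(panel$cases, eta, panel$E)$total
  sh <- priors$precision_gamma_shape; ra <- priors$precision_gamma_rate
  sd0 <- priors$fixed_effect_sd
  lp <- lp + icar_logdensity(state$u, state$tau_u, adjacency) +
    sum(stats::dnorm(state$v, 0, 1 / sqrt(state$tau_v), log = TRUE)) +
    stats::dgamma(state$tau_u, sh, ra, log = TRUE) +
    stats::dgamma(state$tau_v, sh, ra, log = TRUE)
  if (spec$include_rw1) {
    lp <- lp + rw1_logdensity(state$phi, state$tau_phi) +
      stats::dgamma(state$tau_phi, sh, ra, log = TRUE)
  }
  if (spec$include_seasonal) {
    lp <- lp + seasonal_logdensity(state$s, state$tau_s) +
      stats::dgamma(state$tau_s, sh, ra, log = TRUE)
  }
  if (spec$include_iid_time) {
    lp <- lp + sum(stats::dnorm(state$psi, 0, 1 / sqrt(state$tau_psi),
                                log = TRUE)) +
      stats::dgamma(state$tau_psi, sh, ra, log = TRUE)
  }
  lp <- lp + stats::dnorm(state$alpha, 0, sd0, log = TRUE) +
    sum(stats::dnorm(state$beta, 0, sd0, log = TRUE))
  if (spec$include_linear_trend) {
    lp <- lp + stats::dnorm(state$gamma, 0, sd0, log = TRUE)
  }
  lp
}
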