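#' Simulate a lattice region map
#'
#' Generates a rectangular lattice of unit-square cells with queen
#' adjacency (8 neighbours in the interior) and log-normal populations, so
#' that a long tail of very small units exists, as with real postal
#' geography units (which average roughly 20,000 people). Deterministic for
#' a given seed.
#'
#' @param n_units number of cells (>= 2).
#' @param seed RNG seed.
#' @param pop_meanlog,pop_sdlog log-normal population parameters; defaults
#'   give a median near 20,000 with a heavy lower tail.
#' @return a `region_map` with polygons and unit areas.
#' @export
simulate_map <- function(n_units, seed = 1L, pop_meanlog = log(20000),
                         pop_sdlog = 1.3) {
  if (n_units < 2L) stop("n_units must be >= 2")
  nc <- ceiling(sqrt(n_units))
  nr <- ceiling(n_units / nc)
  k <- seq_len(n_units)
  row <- ((k - 1L) %/% nc) + 1L
  col <- ((k - 1L) %% nc) + 1L
  ids <- sprintf("U%04d", k)
  pop <- with_seed(seed, round(stats::rlnorm(n_units, pop_meanlog, pop_sdlog)))
  pop <- pmax(pop, 1)
  cell_index <- matrix(NA_integer_, nr, nc)
  cell_index[cbind(row, col)] <- k
  adj <- vector("list", n_units)
  for (i in k) {
    r <- row[i]; cc <- col[i]
    nb <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; ccc <- cc + dc
      if (rr >= 1L && rr <= nr && ccc >= 1L && ccc <= nc) {
        j <- cell_index[rr, ccc]
        if (!is.na(j)) nb <- c(nb, j)
      }
    }
    adj[[i]] <- ids[sort(nb)]
  }
  names(adj) <- ids
  polys <- stats::setNames(lapply(k, function(i) {
    x0 <- col[i] - 1; y0 <- row[i] - 1
    rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1), c(x0, y0 + 1))
  }), ids)
  region_map(ids, pop, adj, polygons = polys)
}

#' Simulate the generative truth of the disease-mapping model
#'
#' Draws every latent block of the hierarchical model with known parameters:
#' ICAR spatial effects `u` (joint Gaussian with precision tau_u (D - W),
#' sum-to-zero per connected component), iid spatial effects `v`, an RW1
#' trend `phi` re-centered to sum zero, seasonal effects `s` generated by
#' the period-12 recursion s_t = -(s_{t-1} + ... + s_{t-11}) + eps_t (so
#' every run of 12 consecutive values sums to its innovation draw), and
#' covariates simulated as spatially smoothed AR(1)-in-time fields, then
#' standardized exactly (mean 0, population variance 1). Expected counts are
#' time-constant: E_it = pop_i * base_rate, with the default base rate
#' chosen so the mean count per region-month is about 0.35 — the sparsity
#' regime that motivates the hierarchical model.
#'
#' @param map a `region_map`.
#' @param T number of months (>= 13).
#' @param k_covariates number of covariates to simulate.
#' @param seed RNG seed.
#' @param hyperparams list overriding any of `alpha`, `beta` (recycled to
#'   `k_covariates`), `gamma`, `tau_u`, `tau_v`, `tau_phi`, `tau_s`,
#'   `mean_count` (target mean count per cell) or `base_rate` (direct
#'   rate per person-month; overrides `mean_count`), `ar_rho` (temporal
#'   autocorrelation of the covariate fields).
#' @return an object of class `sim_truth`.
#' @export
simulate_truth <- function(map, T, k_covariates = 2L, seed = 1L,
                           hyperparams = list()) {
  stopifnot(inherits(map, "region_map"))
  if (T < 13L) stop("T must be >= 13 (one full seasonal cycle + 1)")
  hp <- utils::modifyList(
    list(alpha = 0, beta = NULL, gamma = 0.002,
         tau_u = 4, tau_v = 25, tau_phi = 1000, tau_s = 400,
         mean_count = 0.35, base_rate = NULL, ar_rho = 0.7),
    hyperparams)
  R <- length(map$ids)
  if (is.null(hp$beta)) {
    hp$beta <- if (k_covariates > 0) {
      rep_len(c(0.15, -0.15), k_covariates)
    } else numeric(0)
  } else hp$beta <- rep_len(hp$beta, max(k_covariates, 0L))

  comps <- connected_components(map$adjacency)
  n_comp <- max(comps)
  if (n_comp > 1L) {
    warning("map is not connected; sum-to-zero applied per component")
  }
  with_seed(seed, {
    # ICAR draw via eigendecomposition of Q = D - W on each component
    ae <- adjacency_edges(map)
    Q <- matrix(0, R, R)
    if (nrow(ae$edges)) {
      for (e in seq_len(nrow(ae$edges))) {
        i <- ae$edges[e, 1]; j <- ae$edges[e, 2]
        Q[i, j] <- Q[i, j] - 1; Q[j, i] <- Q[j, i] - 1
        Q[i, i] <- Q[i, i] + 1; Q[j, j] <- Q[j, j] + 1
      }
    }
    eg <- eigen(Q, symmetric = TRUE)
    pos <- eg$values > 1e-9 * max(eg$values, 1)
    u <- as.vector(eg$vectors[, pos, drop = FALSE] %*%
                     (stats::rnorm(sum(pos)) /
                        sqrt(hp$tau_u * eg$values[pos])))
    for (cc in unique(comps)) {          # exact sum-to-zero per component
      idx <- comps == cc
      u[idx] <- u[idx] - mean(u[idx])
    }
    v <- stats::rnorm(R, 0, 1 / sqrt(hp$tau_v))
    phi <- cumsum(c(0, stats::rnorm(T - 1L, 0, 1 / sqrt(hp$tau_phi))))
    phi <- phi - mean(phi)
    # seasonal recursion; innovations recorded for the window-sum invariant
    s <- numeric(T)
    s[1:11] <- stats::rnorm(11, 0, 1 / sqrt(hp$tau_s))
    s_innov <- stats::rnorm(T - 11L, 0, 1 / sqrt(hp$tau_s))
    for (t in 12:T) s[t] <- -sum(s[(t - 11):(t - 1)]) + s_innov[t - 11L]
    # covariates: AR(1) in time, one spatial smoothing pass, standardized
    X <- list()
    nb_idx <- lapply(map$adjacency, match, map$ids)
    if (k_covariates > 0) {
      for (kk in seq_len(k_covariates)) {
        z <- matrix(0, R, T)
        z[, 1] <- stats::rnorm(R)
        for (t in 2:T) {
          z[, t] <- hp$ar_rho * z[, t - 1] +
            sqrt(1 - hp$ar_rho^2) * stats::rnorm(R)
        }
        zs <- z
        for (i in seq_len(R)) {
          nb <- nb_idx[[i]]
          if (length(nb)) {
            zs[i, ] <- (z[i, ] + colMeans(z[nb, , drop = FALSE])) / 2
          }
        }
        X[[paste0("x", kk)]] <- standardize(zs, name = paste0("x", kk))
      }
    }
  })
  base_rate <- hp$base_rate %||% (hp$mean_count / mean(map$population))
  E <- matrix(map$population * base_rate, R, T)
  structure(list(map = map, T = as.integer(T),
                 alpha = hp$alpha, beta = hp$beta, gamma = hp$gamma,
                 u = u, v = v, phi = phi, s = s, s_innov = s_innov,
                 tau_u = hp$tau_u, tau_v = hp$tau_v,
                 tau_phi = hp$tau_phi, tau_s = hp$tau_s,
                 X = X, E = E, base_rate = base_rate),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", length(x$map$ids), "regions x", x$T, "months,",
      length(x$beta), "covariates\n")
  cat("  beta:", paste(signif(x$beta, 3), collapse = ", "),
      " gamma:", x$gamma, "\n")
  cat("  mean expected count/cell:", signif(mean(x$E), 3), "\n")
  invisible(x)
}

#' Simulate case counts from a generative truth
#'
#' Draws y_it ~ Poisson(E_it exp(eta_it)) with
#' eta_it = alpha + x_it' beta + u_i + v_i + gamma (t - mean(t)) + phi_t
#' + s_t. The linear predictor is clipped at +/- 20 (with a warning) as an
#' overflow guard.
#'
#' @param truth a `sim_truth`.
#' @param seed RNG seed.
#' @return a complete `panel_data` including covariates and E.
#' @export
simulate_counts <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  eta <- truth_linear_predictor(truth)
  if (any(abs(eta) > 20)) {
    warning("linear predictor clipped at +/- 20")
    eta <- pmin(pmax(eta, -20), 20)
  }
  mu <- truth$E * exp(eta)
  y <- with_seed(seed,
                 matrix(stats::rpois(length(mu), as.vector(mu)),
                        nrow(mu), ncol(mu)))
  panel_data(cases = y, population = matrix(truth$map$population,
                                            nrow(mu), ncol(mu)),
             covariates = truth$X, E = truth$E,
             region_ids = truth$map$ids)
}

# Linear predictor implied by a sim_truth (the truth always carries the
# full temporal structure).
truth_linear_predictor <- function(truth) {
  R <- length(truth$map$ids); T <- truth$T
  eta <- matrix(truth$alpha, R, T)
  for (k in seq_along(truth$beta)) {
    eta <- eta + truth$beta[k] * truth$X[[k]]
  }
  eta <- eta + truth$u + truth$v
  eta + rep(truth$gamma * centered_time(T) + truth$phi + truth$s, each = R)
}

#' Simulate a full synthetic panel in one call
#'
#' Convenience wrapper: lattice map, generative truth, and counts, with
#' seeds derived from one master seed.
#'
#' @param n_units lattice size before aggregation (used directly as regions
#'   when `n_target` is NULL).
#' @param T months.
#' @param k_covariates covariates.
#' @param seed master seed.
#' @param n_target optional aggregation target applied to the lattice first.
#' @param hyperparams passed to [simulate_truth()].
#' @return list with `map`, `truth`, `panel`.
#' @export
simulate_panel <- function(n_units = 100L, T = 156L, k_covariates = 2L,
                           seed = 1L, n_target = NULL, hyperparams = list()) {
  map <- simulate_map(n_units, seed = derive_seed(seed, 1L))
  if (!is.null(n_target)) {
    map <- aggregate_regions(map, n_target)$map
  }
  truth <- simulate_truth(map, T, k_covariates,
                          seed = derive_seed(seed, 2L),
                          hyperparams = hyperparams)
  panel <- simulate_counts(truth, seed = derive_seed(seed, 3L))
  list(map = map, truth = truth, panel = panel)
}
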