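# Shared fixtures, all built in code.

# Unit-square ring at offset (x0, y0).
square_ring <- function(x0, y0, w = 1) {
  rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + w), c(x0, y0 + w))
}

# Path-graph region map with given populations (ids A, B, C, ...).
path_map <- function(pops) {
  n <- length(pops)
  ids <- LETTERS[seq_len(n)]
  edges <- if (n > 1) data.frame(id_a = ids[-n], id_b = ids[-1]) else
    data.frame(id_a = character(0), id_b = character(0))
  region_map(ids, pops, edges)
}

# The worked merging example: a minimum-population unit R1B (10 people)
# with neighbours R1A and R3C (1620 people).
worked_example_map <- function() {
  region_map(ids = c("R1A", "R1B", "R3C"),
             population = c(30000, 10, 1620),
             adjacency = data.frame(id_a = c("R1A", "R1B"),
                                    id_b = c("R1B", "R3C")))
}

# Small complete panel with k covariates, deterministic.
tiny_panel <- function(R = 4, T = 14, seed = 42, k = 1) {
  set.seed(seed)
  covs <- stats::setNames(lapply(seq_len(k), function(j) {
    standardize(matrix(rnorm(R * T), R, T))
  }), paste0("x", seq_len(k)))
  panel_data(cases = matrix(rpois(R * T, 3), R, T),
             population = rep(1000, R),
             covariates = covs)
}

# Random latent state consistent with a map/panel, constraints satisfied.
random_state <- function(map, T, k = 0, seed = 1, spec = model_spec()) {
  set.seed(seed)
  R <- length(map$ids)
  comps <- kdbym:::connected_components(map$adjacency)
  u <- rnorm(R, 0, 0.3)
  for (cc in unique(comps)) u[comps == cc] <- u[comps == cc] - mean(u[comps == cc])
  ctr <- function(x) x - mean(x)
  latent_state(alpha = rnorm(1, 0, 0.2),
               beta = rnorm(k, 0, 0.2),
               gamma = rnorm(1, 0, 0.01),
               u = u, v = rnorm(R, 0, 0.2),
               phi = if (spec$include_rw1) ctr(cumsum(rnorm(T, 0, 0.05))) else NULL,
               s = if (spec$include_seasonal) ctr(rnorm(T, 0, 0.1)) else NULL,
               psi = if (spec$include_iid_time) ctr(rnorm(T, 0, 0.1)) else NULL,
               tau_u = rgamma(1, 2, 0.5), tau_v = rgamma(1, 2, 0.5),
               tau_phi = rgamma(1, 2, 0.5), tau_s = rgamma(1, 2, 0.5),
               tau_psi = rgamma(1, 2, 0.5))
}

# Short-chain config for tests that need a real (but cheap) fit.
test_config <- function(seed = 1, n_chains = 2, n_warmup = 300,
                        n_samples = 300, ...) {
  kd_config(seed = seed,
            mcmc = list(n_chains = n_chains, n_warmup = n_warmup,
                        n_samples = n_samples),
            ...)
}

# Dense-matrix oracle for the ICAR quadratic form: u' tau (D - W) u / 2.
icar_dense_oracle <- function(u, tau, adj_matrix) {
  D <- diag(rowSums(adj_matrix))
  Q <- tau * (D - adj_matrix)
  n_comp <- igraph_components(adj_matrix)
  -0.5 * as.numeric(t(u) %*% Q %*% u) +
    ((nrow(adj_matrix) - n_comp) / 2) * log(tau)
}

igraph_components <- function(adj_matrix) {
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_adjacency_matrix(adj_matrix != 0, mode = "undirected")
    igraph::components(g)$no
  } else {
    adj <- kdbym:::apply_adj_list(adj_matrix != 0)
    max(kdbym:::connected_components(adj))
  }
}

# Adjacency matrix of a region_map.
adjacency_matrix <- function(map) {
  n <- length(map$ids)
  m <- matrix(0, n, n, dimnames = list(map$ids, map$ids))
  for (id in map$ids) m[id, map$adjacency[[id]]] <- 1
  m
}
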