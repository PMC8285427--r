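test_that("spatial correlation is Pearson on region means", {
  set.seed(60)
  obs <- matrix(runif(50, 0, 10), 10, 5)
  expect_equal(spatial_correlation(obs, obs), 1)
  # affine invariance
  expect_equal(spatial_correlation(obs, 2.5 * obs + 3), 1)
  # direct-formula oracle
  mod <- matrix(runif(50, 0, 10), 10, 5)
  a <- rowMeans(obs); b <- rowMeans(mod)
  want <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(spatial_correlation(obs, mod), want, tolerance = 1e-12)
  expect_error(spatial_correlation(obs[1:2, ], mod[1:2, ]), "3 regions")
  expect_error(spatial_correlation(matrix(1, 5, 4), mod[1:5, 1:4]),
               "zero variance")
})

test_that("temporal correlation is Pearson on nationally aggregated rates", {
  set.seed(61)
  obs <- matrix(rpois(60, 5), 5, 12)
  expect_equal(temporal_correlation(obs, obs), 1)
  # anti-phase seasonal mock is negatively correlated
  s <- sin(2 * pi * (1:12) / 12)
  o2 <- outer(rep(1, 5), 10 + 3 * s)
  m2 <- outer(rep(1, 5), 10 - 3 * s)
  expect_lt(temporal_correlation(o2, m2), 0)
  # invariance to a common population scale factor
  pop <- matrix(runif(60, 1e3, 1e4), 5, 12)
  mod <- matrix(rpois(60, 5) + 0.5, 5, 12)
  expect_equal(temporal_correlation(obs, mod, pop),
               temporal_correlation(obs, mod, 2 * pop), tolerance = 1e-12)
})

test_that("modelled rates equal the draw-averaged oracle", {
  sim <- simulate_panel(n_units = 9, T = 14, k_covariates = 1, seed = 70)
  fit <- suppressWarnings(kd_bym(sim$panel, sim$map, model_spec("x1"),
                                 test_config(n_warmup = 100, n_samples = 100)))
  mu <- modelled_rates(fit, sim$panel)
  expect_true(all(is.finite(mu)) && all(mu > 0))
  expect_equal(mu, sim$panel$E * fit$mean_exp_eta, tolerance = 1e-12)
  # recomputation oracle from the stored draws
  S <- nrow(fit$draws)
  acc <- matrix(0, 9, 14)
  tc <- centered_time(14)
  for (s in seq_len(S)) {
    st <- latent_state(alpha = fit$draws[s, "alpha"],
                       beta = fit$draws[s, "beta_x1"],
                       gamma = fit$draws[s, "gamma"],
                       u = fit$fields$u[s, ], v = fit$fields$v[s, ],
                       phi = fit$fields$phi[s, ], s = fit$fields$s[s, ])
    acc <- acc + exp(linear_predictor(st, sim$panel, fit$spec))
  }
  expect_equal(fit$mean_exp_eta, acc / S, tolerance = 1e-8)
  # per-100k scaling
  mu100 <- modelled_rates(fit, sim$panel, per_100k = TRUE)
  expect_equal(mu100, mu / sim$panel$population * 1e5, tolerance = 1e-12)
})

test_that("all-zero-effect draws give modelled rates equal to E", {
  fit <- structure(list(mean_exp_eta = matrix(1, 4, 6),
                        region_ids = as.character(1:4),
                        month_index = 1:6),
                   class = "bym_fit")
  p <- panel_data(cases = matrix(1, 4, 6), population = rep(100, 4),
                  region_ids = as.character(1:4))
  expect_equal(modelled_rates(fit, p), p$E, tolerance = 1e-12)
})

test_that("evaluate_fit returns a coherent report", {
  sim <- simulate_panel(n_units = 16, T = 24, k_covariates = 1, seed = 71,
                        hyperparams = list(mean_count = 5))
  fit <- suppressWarnings(kd_bym(sim$panel, sim$map, model_spec("x1"),
                                 test_config(n_warmup = 200, n_samples = 200)))
  ev <- evaluate_fit(fit, sim$panel)
  expect_s3_class(ev, "kd_eval")
  expect_true(abs(ev$spatial_correlation) <= 1)
  expect_true(abs(ev$temporal_correlation) <= 1)
  expect_true(abs(ev$comparison_correlation) <= 1)
  expect_equal(nrow(ev$per_region), 16)
  expect_equal(nrow(ev$per_month), 24)
  # the hierarchical fit should track the data far better than chance
  expect_gt(ev$spatial_correlation, 0.3)
  expect_gt(ev$temporal_correlation, 0.3)
})

test_that("comparison correlation is Pearson on region-year rates", {
  set.seed(62)
  obs <- matrix(rpois(10 * 24, 4), 10, 24)
  mod <- matrix(runif(10 * 24, 2, 6), 10, 24)
  pop <- matrix(runif(10 * 24, 1e3, 1e4), 10, 24)
  got <- comparison_correlation(obs, mod, pop)
  # direct oracle
  oy <- cbind(rowSums(obs[, 1:12]) / rowSums(pop[, 1:12]),
              rowSums(obs[, 13:24]) / rowSums(pop[, 13:24]))
  my <- cbind(rowSums(mod[, 1:12]) / rowSums(pop[, 1:12]),
              rowSums(mod[, 13:24]) / rowSums(pop[, 13:24]))
  expect_equal(got, cor(as.vector(oy), as.vector(my)), tolerance = 1e-12)
  expect_equal(comparison_correlation(obs, obs, pop), 1)
  expect_error(comparison_correlation(obs[, 1:6], mod[, 1:6], pop[, 1:6]),
               "fewer months")
})

test_that("self-consistency: truth evaluated on rich data approaches r = 1", {
  # scale E up 100x: with abundant counts the generating surface must
  # correlate with the observations nearly perfectly
  map <- simulate_map(25, seed = 72)
  tr <- simulate_truth(map, T = 24, k_covariates = 0, seed = 73,
                       hyperparams = list(mean_count = 35))
  p <- simulate_counts(tr, seed = 74)
  mu <- tr$E * exp(kdbym:::truth_linear_predictor(tr))
  obs_rate <- p$cases / p$population * 1e5
  mod_rate <- mu / p$population * 1e5
  expect_gt(spatial_correlation(obs_rate, mod_rate), 0.95)
  expect_gt(temporal_correlation(p$cases, mu, p$population), 0.9)
})
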