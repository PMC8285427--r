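test_that("WAIC matches closed forms and a naive double-loop oracle", {
  # point-mass posterior: identical draws -> p_waic = 0, waic = -2 sum(l)
  ll <- matrix(rep(c(-1.3, -0.7, -2.1), each = 4), nrow = 4)
  w <- waic(ll)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * sum(ll[1, ]))

  # 2 draws, 1 observation: closed form
  ll2 <- matrix(c(log(0.5), log(0.25)), 2, 1)
  w2 <- waic(ll2)
  expect_equal(w2$lppd, log(0.375), tolerance = 1e-12)
  expect_equal(w2$p_waic, (log(2))^2 / 2, tolerance = 1e-12)
  expect_equal(w2$waic, -2 * (log(0.375) - (log(2))^2 / 2), tolerance = 1e-12)

  # brute-force double-loop oracle on random 50 x 100 matrices
  naive_waic <- function(m) {
    S <- nrow(m); N <- ncol(m)
    lppd <- 0; p <- 0
    for (n in seq_len(N)) {
      lppd <- lppd + log(mean(exp(m[, n])))
      p <- p + var(m[, n])
    }
    list(lppd = lppd, p_waic = p, waic = -2 * (lppd - p))
  }
  set.seed(21)
  for (r in 1:3) {
    m <- matrix(rnorm(50 * 100, -2, 1), 50, 100)
    got <- waic(m)
    want <- naive_waic(m)
    expect_equal(got$lppd, want$lppd, tolerance = 1e-10)
    expect_equal(got$p_waic, want$p_waic, tolerance = 1e-10)
    expect_equal(got$waic, want$waic, tolerance = 1e-10)
  }
  expect_error(waic(matrix(0, 1, 5)), "at least 2")
})

test_that("SIR percentiles are order statistics of exp(beta) draws", {
  fit <- structure(list(draws = cbind(beta_x1 = rep(0, 100))),
                   class = "bym_fit")
  expect_equal(unname(summarize_sir(fit, "x1")), rep(1, 5))

  fit2 <- structure(list(draws = cbind(beta_x1 = log(1:100))),
                    class = "bym_fit")
  got <- summarize_sir(fit2, "x1")
  # order-statistic oracle: type-1 quantiles of 1..100
  want <- quantile(1:100, c(0.025, 0.25, 0.5, 0.75, 0.975), type = 1,
                   names = FALSE)
  expect_equal(unname(got), want, tolerance = 1e-12)
  expect_true(all(diff(got) >= 0))
  expect_error(summarize_sir(fit2, "nope"), "unknown covariate")
})

test_that("posterior maps report mean SIR and counting-oracle exceedance", {
  S <- 200; R <- 6; T <- 24
  set.seed(22)
  fields <- list(u = matrix(rnorm(S * R, 0, 0.1), S, R),
                 v = matrix(rnorm(S * R, 0, 0.1), S, R),
                 phi = matrix(rnorm(S * T, 0, 0.05), S, T))
  draws <- cbind(alpha = rnorm(S), gamma = rnorm(S, 0, 0.001))
  fit <- structure(list(fields = fields, draws = draws,
                        region_ids = as.character(1:R),
                        month_index = 1:T, month0 = c(2004L, 4L),
                        spec = model_spec(include_seasonal = FALSE)),
                   class = "bym_fit")
  maps <- posterior_maps(fit)
  sir_draws <- exp(fields$u + fields$v)
  expect_equal(maps$spatial$sir, colMeans(sir_draws), tolerance = 1e-12)
  # counting oracle for exceedance
  expect_equal(maps$spatial$pr_exceed,
               apply(sir_draws, 2, function(x) mean(x > 1)),
               tolerance = 1e-12)

  # all spatial draws at zero: SIR 1, exceedance 0.5 (tie midpoint)
  fit0 <- fit
  fit0$fields$u[] <- 0; fit0$fields$v[] <- 0
  maps0 <- posterior_maps(fit0)
  expect_equal(maps0$spatial$sir, rep(1, R))
  expect_equal(maps0$spatial$pr_exceed, rep(0.5, R))

  # a region with all draws positive has exceedance 1
  fit1 <- fit
  fit1$fields$u[, 1] <- abs(fit$fields$u[, 1]) + 0.01
  fit1$fields$v[, 1] <- abs(fit$fields$v[, 1])
  expect_equal(posterior_maps(fit1)$spatial$pr_exceed[1], 1)
})

test_that("fit validation and determinism", {
  sim <- simulate_panel(n_units = 9, T = 14, k_covariates = 1, seed = 30)
  cfg <- test_config(n_warmup = 60, n_samples = 60)
  bad <- cfg; bad$mcmc$n_samples <- 0L
  expect_error(kd_bym(sim$panel, sim$map, model_spec("x1"), bad),
               "no sampling requested")
  expect_error(kd_bym(sim$panel, sim$map, model_spec("nope"), cfg),
               "covariate not in panel")

  f1 <- suppressWarnings(kd_bym(sim$panel, sim$map, model_spec("x1"), cfg))
  f2 <- suppressWarnings(kd_bym(sim$panel, sim$map, model_spec("x1"), cfg))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$waic, f2$waic)
})

test_that("intercept-only single-region fit matches the Poisson-Gamma", {
  # Poisson-Gamma oracle: with a flat-ish prior the rate multiplier
  # lambda = exp(alpha + u + v) has posterior ~ Gamma(sum(y), sum(E));
  # the fitted posterior mean must agree within Monte-Carlo error.
  T <- 60
  set.seed(31)
  E <- matrix(2, 1, T)
  y <- matrix(rpois(T, 2 * 1.3), 1, T)
  panel <- panel_data(cases = y, population = matrix(1e5, 1, T), E = E,
                      region_ids = "A")
  map <- region_map("A", 1e5, list())
  spec <- model_spec(include_linear_trend = FALSE, include_rw1 = FALSE,
                     include_seasonal = FALSE)
  fit <- suppressWarnings(
    kd_bym(panel, map, spec,
           test_config(seed = 2, n_chains = 2, n_warmup = 500,
                       n_samples = 1000)))
  lam <- exp(fit$draws[, "alpha"] + fit$fields$u[, 1] + fit$fields$v[, 1])
  oracle_mean <- sum(y) / sum(E)          # Gamma(sum y, sum E) mean
  ess <- min(fit$diagnostics$ess["alpha"], length(lam))
  mc_se <- sd(lam) / sqrt(ess)
  expect_lt(abs(mean(lam) - oracle_mean), 3 * mc_se + 0.01 * oracle_mean)
})

test_that("known effects are recovered on simulated data", {
  sim <- simulate_panel(n_units = 36, T = 36, k_covariates = 2, seed = 41,
                        hyperparams = list(beta = c(0.3, -0.2)))
  fit <- suppressWarnings(
    kd_bym(sim$panel, sim$map, model_spec(c("x1", "x2")),
           test_config(seed = 3, n_chains = 2, n_warmup = 500,
                       n_samples = 500)))
  for (j in 1:2) {
    col <- paste0("beta_x", j)
    pm <- mean(fit$draws[, col]); psd <- sd(fit$draws[, col])
    expect_lt(abs(pm - sim$truth$beta[j]), 3 * psd)
  }
})
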