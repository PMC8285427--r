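test_that("linear predictor equals a term-by-term brute-force sum", {
  map <- simulate_map(12, seed = 2)
  T <- 15
  panel <- tiny_panel(R = 12, T = T, seed = 3, k = 2)
  spec <- model_spec(c("x1", "x2"), include_iid_time = TRUE)
  st <- random_state(map, T, k = 2, seed = 5, spec = spec)

  eta <- linear_predictor(st, panel, spec)
  # naive summation oracle
  want <- matrix(NA_real_, 12, T)
  tc <- seq_len(T) - (T + 1) / 2
  for (i in 1:12) for (t in 1:T) {
    want[i, t] <- st$alpha + st$beta[1] * panel$covariates$x1[i, t] +
      st$beta[2] * panel$covariates$x2[i, t] + st$u[i] + st$v[i] +
      st$gamma * tc[t] + st$phi[t] + st$s[t] + st$psi[t]
  }
  expect_equal(eta, want, tolerance = 1e-12)

  # all latent zero except the intercept
  st0 <- latent_state(alpha = 0.3, u = numeric(12), v = numeric(12))
  spec0 <- model_spec(include_linear_trend = FALSE, include_rw1 = FALSE,
                      include_seasonal = FALSE)
  expect_true(all(linear_predictor(st0, panel, spec0) == 0.3))

  # linearity in a covariate: +1 SD shifts eta by beta_j exactly
  panel2 <- panel
  panel2$covariates$x1 <- panel$covariates$x1 + 1
  expect_equal(linear_predictor(st, panel2, spec) - eta,
               matrix(st$beta[1], 12, T), tolerance = 1e-12)
})

test_that("Poisson log-likelihood matches closed forms and dpois", {
  expect_equal(poisson_loglik(0, 0, 1)$total, -1)
  expect_equal(poisson_loglik(2, 0, 1)$total, -1 - log(2), tolerance = 1e-12)
  set.seed(8)
  y <- matrix(rpois(30, 2), 5, 6)
  eta <- matrix(rnorm(30, 0, 0.5), 5, 6)
  E <- matrix(runif(30, 0.5, 3), 5, 6)
  got <- poisson_loglik(y, eta, E)
  expect_equal(got$pointwise, dpois(y, E * exp(eta), log = TRUE),
               tolerance = 1e-12)
  expect_equal(got$total, sum(got$pointwise))
  expect_error(poisson_loglik(-1, 0, 1), "negative")
})

test_that("ICAR log-density matches the dense quadratic-form oracle", {
  # closed form: path A-B-C with u = (-1, 0, 1), tau = 2 -> quadratic -2
  m3 <- path_map(c(1, 1, 1))
  expect_equal(icar_logdensity(c(-1, 0, 1), 2, m3),
               -2 + (2 / 2) * log(2), tolerance = 1e-12)
  # constant u has zero quadratic term
  expect_equal(icar_logdensity(rep(0, 3), 5, m3), (2 / 2) * log(5),
               tolerance = 1e-12)

  set.seed(10)
  for (rep in 1:5) {
    map <- simulate_map(sample(10:50, 1), seed = rep)
    R <- length(map$ids)
    u <- rnorm(R); u <- u - mean(u)
    tau <- runif(1, 0.5, 5)
    amat <- adjacency_matrix(map)
    expect_equal(icar_logdensity(u, tau, map),
                 icar_dense_oracle(u, tau, amat), tolerance = 1e-10)
  }
  # invariance to an added constant after re-centering
  map <- simulate_map(20, seed = 4)
  u <- rnorm(20); u <- u - mean(u)
  shifted <- u + 3.7
  expect_equal(icar_logdensity(shifted - mean(shifted), 1.3, map),
               icar_logdensity(u, 1.3, map), tolerance = 1e-10)
  expect_error(icar_logdensity(u, -1, map), "tau_u")
})

test_that("RW1 log-density matches the difference-matrix oracle", {
  expect_equal(rw1_logdensity(c(0, 1, 3), 1), -2.5 + log(1),
               tolerance = 1e-12)
  expect_equal(rw1_logdensity(rep(4, 6), 3), (5 / 2) * log(3),
               tolerance = 1e-12)
  set.seed(11)
  for (T in c(5, 20, 50)) {
    phi <- rnorm(T); tau <- runif(1, 0.5, 4)
    D <- diff(diag(T))          # (T-1) x T first-difference matrix
    want <- -(tau / 2) * as.numeric(t(phi) %*% crossprod(D) %*% phi) +
      ((T - 1) / 2) * log(tau)
    expect_equal(rw1_logdensity(phi, tau), want, tolerance = 1e-10)
  }
  expect_error(rw1_logdensity(1, 1), "length")
})

test_that("seasonal log-density matches the window-sum structure matrix", {
  # period 2, s = (1,1,1): window sums (2,2), tau 1 -> -4 (+ log-tau term)
  expect_equal(seasonal_logdensity(c(1, 1, 1), 1, period = 2), -4,
               tolerance = 1e-12)
  # every 12-window summing to zero -> only the normalizing term
  s0 <- rep(c(1, -1), 12)   # any 12 consecutive sum to 0
  expect_equal(seasonal_logdensity(s0, 2, period = 12),
               ((24 - 12 + 1) / 2) * log(2), tolerance = 1e-12)
  set.seed(12)
  for (T in c(14, 30, 50)) {
    s <- rnorm(T); tau <- runif(1, 0.5, 4)
    A <- matrix(0, T - 11, T)
    for (w in seq_len(T - 11)) A[w, w:(w + 11)] <- 1
    want <- -(tau / 2) * as.numeric(t(s) %*% crossprod(A) %*% s) +
      ((T - 11) / 2) * log(tau)
    expect_equal(seasonal_logdensity(s, tau), want, tolerance = 1e-10)
  }
  expect_error(seasonal_logdensity(rnorm(5), 1), "shorter")
})

test_that("log-posterior is exactly additive in its published components", {
  map <- simulate_map(10, seed = 6)
  T <- 14
  set.seed(13)
  covs <- list(x1 = standardize(matrix(rnorm(10 * T), 10, T)))
  panel <- panel_data(cases = matrix(rpois(10 * T, 1), 10, T),
                      population = rep(2000, 10), covariates = covs)
  spec <- model_spec("x1", include_iid_time = TRUE)
  priors <- kd_config()$priors
  st <- random_state(map, T, k = 1, seed = 14, spec = spec)

  got <- log_posterior(st, panel, spec, map, priors)
  eta <- linear_predictor(st, panel, spec)
  want <- poisson_loglik(panel$cases, eta, panel$E)$total +
    icar_logdensity(st$u, st$tau_u, map) +
    sum(dnorm(st$v, 0, 1 / sqrt(st$tau_v), log = TRUE)) +
    rw1_logdensity(st$phi, st$tau_phi) +
    seasonal_logdensity(st$s, st$tau_s) +
    sum(dnorm(st$psi, 0, 1 / sqrt(st$tau_psi), log = TRUE)) +
    dnorm(st$alpha, 0, priors$fixed_effect_sd, log = TRUE) +
    sum(dnorm(st$beta, 0, priors$fixed_effect_sd, log = TRUE)) +
    dnorm(st$gamma, 0, priors$fixed_effect_sd, log = TRUE) +
    sum(dgamma(c(st$tau_u, st$tau_v, st$tau_phi, st$tau_s, st$tau_psi),
               priors$precision_gamma_shape, priors$precision_gamma_rate,
               log = TRUE))
  expect_equal(got, want, tolerance = 1e-10)

  # removing a covariate whose coefficient is zero leaves the value unchanged
  st0 <- st; st0$beta <- 0
  spec_no <- model_spec(character(0), include_iid_time = TRUE)
  st_no <- st0; st_no$beta <- numeric(0)
  delta <- log_posterior(st0, panel, spec, map, priors) -
    log_posterior(st_no, panel, spec_no, map, priors)
  expect_equal(delta, dnorm(0, 0, priors$fixed_effect_sd, log = TRUE),
               tolerance = 1e-10)

  # constraint violation returns -Inf with a warning
  st_bad <- st; st_bad$u <- st$u + 1
  expect_warning(lp <- log_posterior(st_bad, panel, spec, map, priors),
                 "sum-to-zero")
  expect_identical(lp, -Inf)
})
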