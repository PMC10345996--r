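test_that("the sampler is deterministic given seed and config", {
  region <- make_region("grid", 3)
  panel <- small_panel(region, T = 3, J = 2, seed = 1)
  spec <- small_spec()
  s1 <- fit_mcmc(panel, region, spec, n_chains = 1, n_iter = 25,
                 n_warmup = 10, seed = 99, quiet = TRUE)
  s2 <- fit_mcmc(panel, region, spec, n_chains = 1, n_iter = 25,
                 n_warmup = 10, seed = 99, quiet = TRUE)
  expect_identical(s1$latent, s2$latent)
  expect_identical(s1$hyper, s2$hyper)
  expect_error(fit_mcmc(panel, region, spec, n_iter = 5, n_warmup = 1),
               "seed is mandatory")
})

test_that("all retained draws satisfy the constraints", {
  region <- make_region("grid", 3)
  panel <- small_panel(region, T = 3, J = 2, seed = 2)
  spec <- small_spec()
  s <- fit_mcmc(panel, region, spec, n_chains = 1, n_iter = 40,
                n_warmup = 20, seed = 5, quiet = TRUE)
  expect_lt(max(abs(s$model$A %*% t(s$latent))), 1e-8)
})

test_that("the core block update reproduces a conjugate Poisson posterior", {
  # single cell, flat prior on the log rate: posterior of R = exp(eta) is
  # Gamma(O, E) exactly
  O <- 23; E <- 10
  set.seed(42)
  v <- 0
  keep <- numeric(8000)
  for (it in seq_along(keep)) {
    r <- mvpspline:::newton_block_mh(v, off = log(E), Oc = O, Ec = 1,
                                     H = matrix(1), Qb = matrix(0),
                                     A = matrix(0, 0, 1), eps = 1e-10)
    v <- r$v
    keep[it] <- exp(v)
  }
  keep <- keep[-(1:500)]
  expect_lt(abs(mean(keep) - O / E) / (O / E), 0.01)
  expect_lt(abs(var(keep) - O / E^2) / (O / E^2), 0.1)
})

test_that("prior-only sampling reproduces the prior block correlation", {
  region <- make_region("grid", 3)
  panel <- small_panel(region, T = 4, J = 2, seed = 3)
  spec <- small_spec()
  hyper <- list(Sigma_psi = build_covariance(c(0.5, 0.5), 0.8)$Sigma,
                Sigma_gamma = build_covariance(c(0.5, 0.5), 0.6)$Sigma,
                lambda1 = 1, tau = c(25, 25))
  s <- fit_mcmc(panel, region, spec, n_chains = 1, n_iter = 1500,
                n_warmup = 0, seed = 7, likelihood = FALSE,
                init = list(hyper = hyper), quiet = TRUE)
  lay <- s$model$layout
  ks <- s$model$dims$ks
  b1 <- as.numeric(s$latent[, lay$psi_block(1)])
  b2 <- as.numeric(s$latent[, lay$psi_block(2)])
  expect_lt(abs(cor(b1, b2) - 0.8), 0.05)
  # hyperparameters stay fixed in prior mode
  expect_equal(unique(s$hyper[, "lambda1"]), 1)
})

test_that("constrained penalized WLS agrees with closed-form constrained GLS", {
  set.seed(8)
  n <- 30; p <- 7
  X <- Matrix::Matrix(matrix(rnorm(n * p), n), sparse = TRUE)
  W <- runif(n, 0.5, 2)
  z <- rnorm(n)
  Q0 <- crossprod(matrix(rnorm(p * p), p)) / 5
  A <- matrix(rnorm(2 * p), 2)
  sol <- mvpspline:::constrained_pwls(Matrix::Matrix(Q0, sparse = TRUE),
                                      X, W, z, A, eps = 0)
  # KKT oracle
  Qs <- Q0 + t(as.matrix(X)) %*% (W * as.matrix(X))
  b <- t(as.matrix(X)) %*% (W * z)
  K <- rbind(cbind(Qs, t(A)), cbind(A, matrix(0, 2, 2)))
  xo <- solve(K, c(b, 0, 0))[1:p]
  expect_equal(sol$x, xo, tolerance = 1e-8)
  expect_lt(max(abs(A %*% sol$x)), 1e-10)
})

test_that("the Gaussian approximation is a fixed point at convergence and
           tracks MCMC in the large-count regime", {
  region <- make_region("grid", 3)
  scen_spec <- small_spec()
  hyper <- list(alpha = c(0, 0),
                Sigma_psi = build_covariance(c(0.4, 0.4), 0.5)$Sigma,
                Sigma_gamma = build_covariance(c(0.3, 0.3), 0.3)$Sigma,
                lambda1 = 1, tau = c(25, 25))
  tr <- sample_latent(region, scen_spec, hyper, 1:6, c("u", "v"), seed = 9)
  cnt <- sample_counts(tr, populations = 5e5, overall_rates = c(1e-3, 1e-3),
                       seed = 10)  # E = 500 per cell
  fit <- fit_gaussian_approx(cnt$panel, region, scen_spec)
  refit <- fit_gaussian_approx(cnt$panel, region, scen_spec, max_outer = 0,
                               init = fit)
  expect_identical(refit$mode, fit$mode)

  s <- fit_mcmc(cnt$panel, region, scen_spec, n_chains = 1, n_iter = 300,
                n_warmup = 150, seed = 11, quiet = TRUE)
  g <- gaussian_summaries(fit, "risk")
  m <- summarize_samples(s, "risk")
  expect_lt(max(abs(g$median - m$median) / m$median), 0.02)
})

test_that("posterior summaries use linear-interpolation quantiles", {
  draws <- c(0.5, 1.5, 2.0, 0.8)
  expect_equal(unname(stats::quantile(draws, 0.5, type = 7)), 1.15)
  # exceedance is the fraction of draws above threshold
  expect_equal(mean(draws > 1), 0.5)

  region <- make_region("grid", 2)
  panel <- small_panel(region, T = 3, J = 1, seed = 4)
  s <- fit_mcmc(panel, region, small_spec(), n_chains = 1, n_iter = 20,
                n_warmup = 10, seed = 12, quiet = TRUE)
  sm <- summarize_samples(s, c("risk", "sigma_delta"))
  expect_true(all(sm$lower <= sm$median & sm$median <= sm$upper))
  ex <- exceedance(s, "risk", threshold = 0)
  expect_equal(unname(ex), rep(1, panel$I * panel$T))
  # oracle: indicator mean
  vals <- mvpspline:::functional_draws(s, "risk")
  expect_equal(exceedance(s, "risk", 1), colMeans(vals > 1))
  # single draw: degenerate interval
  s1 <- s; s1$latent <- s$latent[1, , drop = FALSE]
  s1$hyper <- s$hyper[1, , drop = FALSE]; s1$chain <- 1L
  sm1 <- summarize_samples(s1, "risk")
  expect_equal(sm1$median, sm1$lower)
  expect_error(summarize_samples(s, "no_such"), "unknown functional")
})

test_that("risk draws satisfy the multiplicative identity cellwise", {
  region <- make_region("grid", 2)
  panel <- small_panel(region, T = 3, J = 2, seed = 5)
  s <- fit_mcmc(panel, region, small_spec(), n_chains = 1, n_iter = 15,
                n_warmup = 10, seed = 13, quiet = TRUE)
  risk <- mvpspline:::functional_draws(s, "risk")
  al <- mvpspline:::functional_draws(s, "alpha")
  fsp <- mvpspline:::functional_draws(s, "spatial_risk")
  fte <- mvpspline:::functional_draws(s, "temporal_risk")
  fin <- mvpspline:::functional_draws(s, "interaction_risk")
  I <- 4; T <- 3
  for (j in 1:2) for (t in 1:T) for (i in 1:I) {
    cell <- cell_index(i, t, j, I, T)
    want <- exp(al[, j]) * fsp[, (j - 1) * I + i] * fte[, (j - 1) * T + t] *
      fin[, cell]
    expect_equal(risk[, cell], want, tolerance = 1e-10)
  }
  # per-draw centering of the smooth functions (constraint echo)
  lf <- log(fsp)
  expect_lt(max(abs(rowMeans(lf[, 1:I]))), 1e-8)
})
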