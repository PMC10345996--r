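# Conjugate Poisson-gamma toy: a single Poisson rate R with Gamma(a, b)
# prior observed through cells with known expected counts. The posterior is
# Gamma(a + sum O, b + sum E), so every criterion has an exact or
# quadrature oracle independent of the sampling code.

post_draws <- function(a, b, O, E, S, seed) {
  set.seed(seed)
  stats::rgamma(S, shape = a + sum(O), rate = b + sum(E))
}

ll_mat <- function(R, O, E) {
  out <- vapply(R, function(r) stats::dpois(O, E * r, log = TRUE),
                numeric(length(O)))
  matrix(out, nrow = length(R), ncol = length(O), byrow = TRUE)
}

test_that("DIC matches a quadrature oracle on the conjugate toy", {
  a <- 2; b <- 1; O <- 7; E <- 2
  R <- post_draws(a, b, O, E, S = 1e4, seed = 1)
  ll <- ll_mat(R, O, E)
  got <- mvpspline:::dic_from_parts(ll, O, mubar = mean(E * R))

  ap <- a + O; bp <- b + E
  Dbar_exact <- stats::integrate(function(r)
    -2 * stats::dpois(O, E * r, log = TRUE) * stats::dgamma(r, ap, bp),
    0, Inf)$value
  mubar_exact <- E * ap / bp
  pD_exact <- Dbar_exact + 2 * stats::dpois(O, mubar_exact, log = TRUE)
  expect_equal(got$Dbar, Dbar_exact, tolerance = 0.01)
  expect_equal(got$DIC, Dbar_exact + pD_exact, tolerance = 0.01)
  expect_equal(got$DIC, got$Dbar + got$pD)          # identity, exact

  # single draw: pD = 0, DIC = Dbar
  ll1 <- ll_mat(R[1], O, E)
  got1 <- mvpspline:::dic_from_parts(ll1, O, mubar = E * R[1])
  expect_equal(got1$pD, 0)
  expect_equal(got1$DIC, got1$Dbar)
})

test_that("the DIC identity reproduces printed deviance summaries", {
  expect_equal(dic_identity(12567.139, 685.262), 13252.401)
  expect_equal(dic_identity(12205.419, 883.941), 13089.360)
})

test_that("WAIC matches the exact posterior predictive on the conjugate toy", {
  a <- 2; b <- 1; O <- 7; E <- 2
  R <- post_draws(a, b, O, E, S = 1e4, seed = 2)
  ll <- ll_mat(R, O, E)
  got <- mvpspline:::waic_from_ll(ll)

  # exact lppd: log posterior predictive = negative binomial
  ap <- a + O; bp <- b + E
  lppd_exact <- lgamma(ap + O) - lgamma(ap) - lgamma(O + 1) +
    ap * log(bp / (bp + E)) + O * log(E / (bp + E))
  p_exact <- stats::integrate(function(r)
    (stats::dpois(O, E * r, log = TRUE))^2 * stats::dgamma(r, ap, bp),
    0, Inf)$value -
    stats::integrate(function(r)
      stats::dpois(O, E * r, log = TRUE) * stats::dgamma(r, ap, bp),
      0, Inf)$value^2
  expect_equal(got$lppd, lppd_exact, tolerance = 0.01)
  # the posterior variance of the log likelihood is heavy-tailed: its Monte
  # Carlo error at 1e4 draws is several percent
  expect_equal(got$p_waic, p_exact, tolerance = 0.1)
  expect_equal(got$WAIC, -2 * (lppd_exact - p_exact), tolerance = 0.02)

  # zero posterior variance: p_waic = 0, WAIC = -2 lppd
  llc <- ll_mat(rep(1.5, 50), O, E)
  gc <- mvpspline:::waic_from_ll(llc)
  expect_equal(gc$p_waic, 0)
  expect_equal(gc$WAIC, -2 * gc$lppd)

  # duplicated cell doubles the lppd contribution
  ll2 <- cbind(ll, ll)
  expect_equal(mvpspline:::waic_from_ll(ll2)$lppd, 2 * got$lppd)
})

test_that("the harmonic-mean CPO matches exact leave-one-out refits", {
  a <- 2; b <- 1
  O <- c(5, 9); E <- c(2, 3)
  R <- post_draws(a, b, O, E, S = 2e4, seed = 3)
  ll <- ll_mat(R, O, E)
  got <- mvpspline:::ls_from_ll(ll, cap_quantile = 1)

  # exact CPO_i = p(O_i | O_{-i}): negative binomial from the
  # leave-one-out posterior Gamma(a + O_-i, b + E_-i)
  exact_log_cpo <- sapply(1:2, function(i) {
    ai <- a + sum(O[-i]); bi <- b + sum(E[-i])
    lgamma(ai + O[i]) - lgamma(ai) - lgamma(O[i] + 1) +
      ai * log(bi / (bi + E[i])) + O[i] * log(E[i] / (bi + E[i]))
  })
  expect_equal(got$log_cpo, exact_log_cpo, tolerance = 0.01)
  expect_equal(got$LS, -mean(exact_log_cpo), tolerance = 0.01)

  # invariance to draw order; single draw reduces to -mean log lik
  expect_equal(mvpspline:::ls_from_ll(ll[sample(nrow(ll)), ],
                                      cap_quantile = 1)$LS,
               got$LS, tolerance = 1e-6)
  ll1 <- ll_mat(R[1], O, E)
  expect_equal(mvpspline:::ls_from_ll(ll1)$LS, -mean(ll1))
})

test_that("criteria agree between engines on a fitted model", {
  region <- make_region("grid", 3)
  panel <- small_panel(region, T = 4, J = 2, seed = 1)
  spec <- small_spec()
  s <- fit_mcmc(panel, region, spec, n_chains = 1, n_iter = 150,
                n_warmup = 100, seed = 2, quiet = TRUE)
  crit <- model_criteria(s)
  expect_equal(crit$DIC, crit$Dbar + crit$pD)
  expect_gt(crit$pD, 0)
  expect_gt(crit$p_waic, 0)
  # on a well-identified model DIC and WAIC agree to a few percent
  expect_lt(abs(crit$DIC - crit$WAIC) / crit$WAIC, 0.05)
})
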