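test_that("expected counts follow indirect standardization", {
  df <- expand.grid(area_id = c("A", "B"), time = 1:2, outcome = "x",
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$count <- c(2L, 5L, 3L, 4L)          # sums to 14
  df$population <- c(100, 400, 150, 350) # sums to 1000
  p <- panel_counts(df)
  ec <- expected_counts(p)
  expect_equal(unname(ec$m), 0.014)
  expect_equal(unname(ec$E["A", "1", "x"]), 1.4)
  # totals match per outcome by construction
  expect_equal(sum(ec$E), sum(p$O))

  set.seed(11)
  p2 <- small_panel(make_region("grid", 3), T = 4, J = 3)
  ec2 <- expected_counts(p2)
  for (j in 1:3)
    expect_equal(sum(ec2$E[, , j]), sum(p2$O[, , j]), tolerance = 1e-10)
})

test_that("design blocks have canonical shapes and reproduce basis columns", {
  region <- make_region("fixture")
  df <- expand.grid(area_id = region$area_ids, time = 2001:2013,
                    outcome = c("r", "a", "c", "k"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$count <- 0L; df$population <- 1e5
  panel <- panel_counts(df)
  spec <- model_spec()   # 10 spatial knots, 5 temporal, cubic
  d <- build_design(region, panel, spec)
  expect_equal(d$dims$N, 34 * 13 * 4)
  expect_equal(dim(d$B_s), c(34, 144))
  expect_equal(d$B3$k, 7)
  expect_equal(nrow(d$X), 1768)
  expect_equal(ncol(d$X), d$dims$p)

  # indicator on one spatial coefficient reproduces that basis column
  lay <- mvpspline:::latent_layout(d$dims)
  v <- numeric(d$dims$p)
  v[lay$psi_block(2)[5]] <- 1
  eta <- as.numeric(d$X %*% v)
  j <- 2; col <- rep(d$B_s[, 5], 13)
  cells <- (j - 1) * 34 * 13 + seq_len(34 * 13)
  expect_equal(eta[cells], col)
  expect_equal(eta[-cells], rep(0, length(eta) - length(cells)))
})

test_that("single-outcome reduction gives alpha + spatial + temporal terms", {
  region <- make_region("grid", 3)
  panel <- small_panel(region, T = 5, J = 1)
  spec <- small_spec()
  d <- build_design(region, panel, spec)
  lay <- mvpspline:::latent_layout(d$dims)
  set.seed(5)
  v <- numeric(d$dims$p)
  v[lay$alpha] <- 0.3
  psi <- rnorm(d$dims$ks); gam <- rnorm(d$dims$k3)
  v[lay$psi_block(1)] <- psi
  v[lay$gamma_block(1)] <- gam
  eta <- as.numeric(d$X %*% v)
  want <- 0.3 + rep(as.numeric(d$B_s %*% psi), 5) +
    rep(as.numeric(d$B3$B %*% gam), each = 9)
  expect_equal(eta, want)
})

test_that("latent prior log kernel matches a dense brute-force oracle", {
  region <- make_region("grid", 3)
  panel <- small_panel(region, T = 4, J = 2)
  spec <- small_spec()
  model <- assemble_model(region, panel, spec)
  lay <- model$layout
  set.seed(6)
  hyper <- list(Sigma_psi = build_covariance(c(0.6, 0.8), 0.5)$Sigma,
                Sigma_gamma = build_covariance(c(0.4, 0.3), -0.2)$Sigma,
                lambda1 = 1.7, tau = c(3, 8))
  state <- list(alpha = rnorm(2), Psi = rnorm(length(lay$psi)),
                Gamma = rnorm(length(lay$gamma)),
                Delta = rnorm(length(lay$delta)))

  got <- latent_prior_logdensity(state, hyper, model)

  Ps <- as.matrix(hyper$lambda1 * model$spatial$K1 + model$spatial$K2)
  Qpsi <- kronecker(solve(hyper$Sigma_psi), Ps)
  Qgam <- kronecker(solve(hyper$Sigma_gamma), as.matrix(model$P3))
  M <- as.matrix(model$M_struct)
  Qdel <- as.matrix(Matrix::bdiag(hyper$tau[1] * M, hyper$tau[2] * M))
  oracle <- -0.5 * (state$Psi %*% Qpsi %*% state$Psi +
                    state$Gamma %*% Qgam %*% state$Gamma +
                    state$Delta %*% Qdel %*% state$Delta)
  expect_equal(got, as.numeric(oracle), tolerance = 1e-10)

  zero <- list(alpha = c(1, -1), Psi = 0 * state$Psi, Gamma = 0 * state$Gamma,
               Delta = 0 * state$Delta)
  expect_equal(latent_prior_logdensity(zero, hyper, model), 0)
})

test_that("diagonal between-outcome covariances factorize over outcomes", {
  region <- make_region("grid", 3)
  panel <- small_panel(region, T = 4, J = 2)
  model <- assemble_model(region, panel, small_spec())
  lay <- model$layout
  set.seed(8)
  hyper <- list(Sigma_psi = diag(c(0.5, 1.5)), Sigma_gamma = diag(c(0.7, 0.9)),
                lambda1 = 1, tau = c(2, 5))
  state <- list(alpha = c(0, 0), Psi = rnorm(length(lay$psi)),
                Gamma = rnorm(length(lay$gamma)),
                Delta = rnorm(length(lay$delta)))
  joint <- latent_prior_logdensity(state, hyper, model)

  panel1 <- small_panel(region, T = 4, J = 1)
  model1 <- assemble_model(region, panel1, small_spec())
  ks <- model$dims$ks; k3 <- model$dims$k3; IT <- 9 * 4
  per <- sum(sapply(1:2, function(j) {
    st <- list(alpha = 0,
               Psi = state$Psi[(j - 1) * ks + seq_len(ks)],
               Gamma = state$Gamma[(j - 1) * k3 + seq_len(k3)],
               Delta = state$Delta[(j - 1) * IT + seq_len(IT)])
    hy <- list(Sigma_psi = diag(hyper$Sigma_psi[j, j], 1),
               Sigma_gamma = diag(hyper$Sigma_gamma[j, j], 1),
               lambda1 = 1, tau = hyper$tau[j])
    latent_prior_logdensity(st, hy, model1)
  }))
  expect_equal(joint, per, tolerance = 1e-8)
})

test_that("hyperpriors use df = 2J+1 Wishart and the truncated uniform", {
  expect_equal(wishart_df(4), 9L)
  spec <- model_spec()
  hyper <- list(Sigma_psi = diag(4), Sigma_gamma = diag(4),
                lambda1 = 1, tau = rep(1, 4))
  expect_true(is.finite(hyperprior_logdensity(hyper, spec, J = 4)))

  # 1/sqrt(lambda1) = 150 is outside (0, 100)
  h2 <- hyper; h2$lambda1 <- 1 / 150^2
  expect_equal(hyperprior_logdensity(h2, spec, J = 4), -Inf)
  h3 <- hyper; h3$tau <- c(-1, 1, 1, 1)
  expect_equal(hyperprior_logdensity(h3, spec, J = 4), -Inf)

  # Wishart density oracle: in one dimension Wishart(df, s) is
  # Gamma(df/2, rate 1/(2s))
  for (w in c(0.3, 1, 2.7)) {
    got <- mvpspline:::dwishart_log(matrix(w), 5, matrix(0.8))
    want <- stats::dgamma(w, shape = 5 / 2, rate = 1 / (2 * 0.8), log = TRUE)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # covariance vs precision placement differ unless Sigma = I
  spec_prec <- model_spec(wishart_mode = "precision")
  h4 <- hyper; h4$Sigma_psi <- diag(2, 4)
  expect_false(isTRUE(all.equal(hyperprior_logdensity(h4, spec, 4),
                                hyperprior_logdensity(h4, spec_prec, 4))))
})

test_that("covariance build/extract round trips exactly", {
  cv <- build_covariance(c(1, 1), 0.8)
  expect_equal(cv$Sigma, rbind(c(1, 0.8), c(0.8, 1)))
  x <- extract_covariance(cv$Sigma)
  expect_equal(x$sigmas, c(1, 1))
  expect_equal(x$rhos[1, 2], 0.8)

  set.seed(9)
  for (rep in 1:5) {
    A <- matrix(rnorm(9), 3); S <- crossprod(A) + diag(3)
    e <- extract_covariance(S)
    back <- build_covariance(e$sigmas, e$rhos)
    expect_equal(back$Sigma, S, tolerance = 1e-12)
  }
  expect_error(build_covariance(c(1, 1), 1.2), "invalid correlation")
  expect_error(build_covariance(c(1, 1, 1), c(0.9, 0.9, -0.9)),
               "invalid correlation")
  expect_equal(n_covariance_params(4), 10L)
  expect_equal(n_covariance_params(5), 15L)
})

test_that("constraint matrices annihilate projected vectors and count rows", {
  region <- make_region("fixture")
  df <- expand.grid(area_id = region$area_ids, time = 2001:2013,
                    outcome = c("r", "a", "c", "k"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$count <- 0L; df$population <- 1e5
  panel <- panel_counts(df)
  A <- constraint_matrix(region, panel, model_spec())
  # 8 smooth rows + 34*4 type II RW1 interaction rows
  expect_equal(nrow(A), 8 + 136)

  set.seed(10)
  x <- rnorm(ncol(A))
  xp <- x - as.numeric(t(A) %*% solve(tcrossprod(A), A %*% x))
  expect_lt(max(abs(A %*% xp)), 1e-8)
})

test_that("model spec serializes to JSON and back", {
  s <- model_spec(spatial_order = 2, interaction = "IV",
                  constraint_mode = "sumzero", temporal_correlation = FALSE)
  f <- tempfile(fileext = ".json")
  spec_to_json(s, f)
  s2 <- spec_from_json(f)
  expect_equal(s2, s)
})
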