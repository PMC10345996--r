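# Fast approximate fit: penalized iteratively reweighted least squares for
# the latent mode under linear constraints, Gaussian credible intervals from
# the curvature at the mode, hyperparameters estimated by conditional
# posterior-mean updates at the mode. Documented as approximate; the MCMC
# engine is the reference.

# Solve min_x 1/2 (z - X x)' W (z - X x) + 1/2 x' Qprior x  s.t. A x = 0.
# W is a diagonal weight vector. Returns the constrained minimizer and the
# Cholesky factor of the (jittered) unconstrained precision.
constrained_pwls <- function(Qprior, X, W, z, A, eps) {
  Qstar <- Matrix::forceSymmetric(
    Qprior + Matrix::crossprod(Matrix::Diagonal(x = sqrt(W)) %*% X))
  b <- as.numeric(Matrix::crossprod(X, W * z))
  Ch <- Matrix::Cholesky(Qstar, perm = TRUE, LDL = FALSE, Imult = eps)
  m <- as.numeric(Matrix::solve(Ch, b, system = "A"))
  SigAt <- as.matrix(Matrix::solve(Ch, t(A), system = "A"))
  V <- A %*% SigAt
  V <- (V + t(V)) / 2
  x <- m - as.numeric(SigAt %*% solve(V, as.numeric(A %*% m)))
  list(x = x, Ch = Ch, V = V, SigAt = SigAt)
}

# Variance of rows of L (q x p) under the constrained Gaussian with
# unconstrained precision factored in Ch and constraint rows A.
constrained_var <- function(Ch, A, L) {
  S1 <- as.matrix(Matrix::solve(Ch, t(L), system = "A"))   # p x q
  base <- colSums(as.matrix(t(L)) * S1)
  G <- A %*% S1                                            # r x q
  V <- A %*% as.matrix(Matrix::solve(Ch, t(A), system = "A"))
  V <- (V + t(V)) / 2
  corr <- colSums(G * solve(V, G))
  pmax(base - corr, 0)
}

#' Fast Gaussian-approximation fit
#'
#' Finds the joint mode of the latent field by constrained penalized IWLS,
#' alternating with conditional posterior-mean updates of the
#' hyperparameters evaluated at the mode, then reports Gaussian credible
#' intervals from the curvature at the mode. Mirrors the "Gaussian
#' strategy" of nested-Laplace software: much faster than MCMC, less
#' precise, and documented as approximate.
#'
#' @inheritParams fit_mcmc
#' @param max_outer maximum hyperparameter/mode alternations; `0` performs
#'   no update and returns `init` (a converged state is a fixed point).
#' @param max_inner maximum IWLS iterations per outer step.
#' @param tol convergence tolerance on the latent mode (max absolute
#'   change).
#' @param hyper optional fixed hyperparameters (list as in
#'   [latent_prior_logdensity()]); when supplied they are not updated.
#' @param init optional previous `mvps_gaussian_fit` to continue from.
#' @return object of class `mvps_gaussian_fit` with the latent `mode`,
#'   hyperparameter estimates, convergence info and the assembled model;
#'   use [gaussian_summaries()] for functional summaries.
#' @export
fit_gaussian_approx <- function(panel, region, spec, max_outer = 25,
                                max_inner = 50, tol = 1e-9, hyper = NULL,
                                init = NULL, jitter = 1e-6, quiet = TRUE) {
  model <- assemble_model(region, panel, spec)
  dims <- model$dims
  J <- dims$J; p <- dims$p
  A <- model$A
  fixed_hyper <- !is.null(hyper)
  hyper <- hyper %||% init$hyper %||% list(
    Sigma_psi = diag(0.25, J), Sigma_gamma = diag(0.25, J),
    lambda1 = spec$lambda1, tau = rep(10, J))
  x <- init$mode %||% numeric(p)
  X <- model$design$X
  converged <- FALSE
  outer_used <- 0L
  Ch <- NULL
  for (outer in seq_len(max(max_outer, 1))) {
    if (max_outer == 0) break
    outer_used <- outer
    Qprior <- build_Qprior(model, hyper)
    eps <- jitter * (1 + mean(Matrix::diag(Qprior)))
    # inner IWLS for the latent mode at fixed hyperparameters
    for (inner in seq_len(max_inner)) {
      eta <- as.numeric(X %*% x)
      mu <- pmin(model$E * exp(eta), 1e12)
      z <- eta + (model$O - mu) / mu
      sol <- constrained_pwls(Qprior, X, mu, z, A, eps)
      delta <- max(abs(sol$x - x))
      x <- sol$x
      Ch <- sol$Ch
      if (delta < tol) break
    }
    if (fixed_hyper) { converged <- delta < sqrt(tol); break }
    new_hyper <- hyper_mode_update(model, hyper, x)
    hchange <- max(abs(unlist(new_hyper[c("lambda1", "tau")]) -
                       unlist(hyper[c("lambda1", "tau")])),
                   abs(new_hyper$Sigma_psi - hyper$Sigma_psi),
                   abs(new_hyper$Sigma_gamma - hyper$Sigma_gamma))
    hyper <- new_hyper
    if (hchange < 1e-6 && delta < sqrt(tol)) { converged <- TRUE; break }
  }
  if (max_outer == 0 && !is.null(init)) {
    return(structure(list(model = model, mode = init$mode, hyper = init$hyper,
                          Ch = init$Ch, converged = init$converged,
                          outer_iterations = 0L),
                     class = "mvps_gaussian_fit"))
  }
  if (!converged && max_outer > 0 && !quiet)
    warning("Gaussian approximation: no full convergence after max_outer")
  structure(list(model = model, mode = x, hyper = hyper, Ch = Ch,
                 converged = converged, outer_iterations = outer_used),
            class = "mvps_gaussian_fit")
}

# Conditional posterior-mean updates of the hyperparameters at the latent
# mode (the mode-plug-in analogue of the conjugate MCMC updates).
hyper_mode_update <- function(model, hyper, x) {
  spec <- model$spec
  J <- model$dims$J
  Ps <- hyper$lambda1 * model$spatial$K1 + model$spatial$K2
  S <- coef_crossprod(x, model$layout$psi, model$dims$ks, J, Ps)
  r <- model$dims$ks - spec$spatial_order^2
  df <- wishart_df(J) + r
  Sigma_psi <- (diag(1 / spec$sigma2_psi, J) + S) / max(df - J - 1, 1)
  Sg <- coef_crossprod(x, model$layout$gamma, model$dims$k3, J, model$P3)
  rg <- model$dims$k3 - spec$temporal_order
  dfg <- wishart_df(J) + rg
  if (spec$temporal_correlation) {
    Sigma_gamma <- (diag(1 / spec$sigma2_gamma, J) + Sg) / max(dfg - J - 1, 1)
  } else {
    Sigma_gamma <- diag((1 / spec$sigma2_gamma + diag(Sg)) / max(dfg - 2, 1), J)
  }
  IT <- model$dims$I * model$dims$T
  d0 <- model$layout$delta[1] - 1
  tau <- numeric(J)
  shape <- model$M_rank / 2 - 1 / 2
  for (j in seq_len(J)) {
    d <- x[d0 + (j - 1) * IT + seq_len(IT)]
    q <- max(as.numeric(d %*% (model$M_struct %*% d)), 1e-10)
    tau[j] <- shape / (q / 2)   # conditional mean
  }
  Om <- solve_pd(Sigma_psi)
  S1 <- coef_crossprod(x, model$layout$psi, model$dims$ks, J, model$spatial$K1)
  q1 <- sum(Om * S1)
  opt <- stats::optimize(function(ll) {
    lambda1_logpost(model, exp(ll), q1, J, spec$lambda1_bound)
  }, interval = log(c(1e-5, 1e5)), maximum = TRUE)
  list(Sigma_psi = Sigma_psi, Sigma_gamma = Sigma_gamma,
       lambda1 = exp(opt$maximum), tau = tau)
}

#' Summaries from a Gaussian-approximation fit
#'
#' Gaussian posterior summaries (median = mode, 95% interval from the
#' curvature, exceedance probabilities for risk functionals) for the same
#' functionals as [summarize_samples()], excluding the hyperparameter
#' correlations (the Gaussian approximation conditions on point estimates
#' of the hyperparameters).
#'
#' @param fit a `mvps_gaussian_fit`.
#' @param functional one of `"risk"`, `"spatial_risk"`, `"temporal_risk"`,
#'   `"interaction_risk"`, `"linear_predictor"`.
#' @param threshold exceedance threshold on the risk scale.
#' @return data.frame with `name`, `median`, `lower`, `upper`,
#'   `exceedance`.
#' @export
gaussian_summaries <- function(fit, functional = "risk", threshold = 1) {
  L <- functional_rows(fit$model, functional)
  est <- as.numeric(L$L %*% fit$mode)
  v <- constrained_var(fit$Ch, fit$model$A, L$L)
  sd <- sqrt(v)
  lo <- est - 1.959963984540054 * sd
  hi <- est + 1.959963984540054 * sd
  if (L$exp_scale) {
    data.frame(name = L$names, median = exp(est), lower = exp(lo),
               upper = exp(hi),
               exceedance = stats::pnorm((est - log(threshold)) / pmax(sd, 1e-300)),
               row.names = NULL)
  } else {
    data.frame(name = L$names, median = est, lower = lo, upper = hi,
               exceedance = stats::pnorm((est - threshold) / pmax(sd, 1e-300)),
               row.names = NULL)
  }
}

#' @export
print.mvps_gaussian_fit <- function(x, ...) {
  cat(sprintf("mvps_gaussian_fit: converged=%s after %d outer iterations\n",
              x$converged, x$outer_iterations))
  invisible(x)
}
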