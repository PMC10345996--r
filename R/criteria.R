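# Model-selection criteria from posterior draws: DIC, WAIC and the
# logarithmic score via conditional predictive ordinates (CPO).

# Per-draw Poisson log-likelihood matrix (draws x cells), full density
# including the factorial term so that WAIC/CPO are proper predictive
# densities.
loglik_matrix <- function(samples, panel = NULL) {
  model <- samples$model
  O <- if (is.null(panel)) model$O else as.vector(panel$O)
  E <- if (is.null(panel)) model$E else as.vector(expected_counts(panel)$E)
  eta <- as.matrix(Matrix::tcrossprod(samples$latent, model$design$X))
  mu <- sweep(exp(eta), 2, E, `*`)
  ll <- sweep(log(mu), 2, O, `*`) - mu
  sweep(ll, 2, lgamma(O + 1), `-`)
}

mu_matrix <- function(samples, panel = NULL) {
  model <- samples$model
  E <- if (is.null(panel)) model$E else as.vector(expected_counts(panel)$E)
  eta <- as.matrix(Matrix::tcrossprod(samples$latent, model$design$X))
  sweep(exp(eta), 2, E, `*`)
}

# Criteria cores operating on a draws x cells log-likelihood matrix; the
# exported wrappers extract it from fitted samples, the test oracles feed
# matrices built from closed-form conjugate posteriors.

dic_from_parts <- function(ll, O, mubar) {
  Dbar <- mean(-2 * rowSums(ll))
  Dhat <- -2 * sum(stats::dpois(O, mubar, log = TRUE))
  pD <- Dbar - Dhat
  list(Dbar = Dbar, pD = pD, DIC = Dbar + pD)
}

waic_from_ll <- function(ll) {
  S <- nrow(ll)
  mx <- apply(ll, 2, max)
  lppd_cell <- mx + log(colMeans(exp(sweep(ll, 2, mx, `-`))))
  v_cell <- if (S == 1) rep(0, ncol(ll)) else apply(ll, 2, stats::var)
  lppd <- sum(lppd_cell)
  p_waic <- sum(v_cell)
  list(lppd = lppd, p_waic = p_waic, WAIC = -2 * (lppd - p_waic))
}

ls_from_ll <- function(ll, cap_quantile = 0.999) {
  S <- nrow(ll)
  nl <- -ll
  n_capped <- 0L
  log_cpo <- numeric(ncol(ll))
  for (cell in seq_len(ncol(ll))) {
    w <- nl[, cell]
    if (S > 10) {
      cap <- stats::quantile(w, cap_quantile, names = FALSE, type = 7)
      over <- w > cap
      n_capped <- n_capped + sum(over)
      w[over] <- cap
    }
    mx <- max(w)
    log_cpo[cell] <- -(mx + log(mean(exp(w - mx))))
  }
  bad <- !is.finite(log_cpo)
  if (any(bad)) {
    warning(sprintf("%d cell(s) with non-finite CPO excluded", sum(bad)))
    log_cpo <- log_cpo[!bad]
  }
  list(LS = -mean(log_cpo), log_cpo = log_cpo, n_capped = n_capped)
}

#' Deviance information criterion
#'
#' `Dbar` is the posterior mean deviance `D = -2 log p(O | mu)`; the
#' effective number of parameters `pD = Dbar - D(mu_bar)` plugs in the
#' posterior mean of the Poisson means `mu` (predictor-scale plug-in, the
#' convention of the nested-Laplace toolchain); `DIC = Dbar + pD`.
#'
#' @param samples an `mvps_samples` object.
#' @param panel optional [panel_counts] to evaluate on (defaults to the
#'   fitted panel).
#' @param plugin `"mu"` (default, plug in the posterior mean of mu) or
#'   `"latent"` (plug in the posterior mean of the latent field).
#' @return list with `Dbar`, `pD`, `DIC`.
#' @export
dic <- function(samples, panel = NULL, plugin = c("mu", "latent")) {
  plugin <- match.arg(plugin)
  ll <- loglik_matrix(samples, panel)
  if (nrow(ll) < 1) stop("zero draws")
  O <- if (is.null(panel)) samples$model$O else as.vector(panel$O)
  if (plugin == "mu") {
    mubar <- colMeans(mu_matrix(samples, panel))
  } else {
    xbar <- colMeans(samples$latent)
    E <- if (is.null(panel)) samples$model$E else as.vector(expected_counts(panel)$E)
    mubar <- E * exp(as.numeric(samples$model$design$X %*% xbar))
  }
  dic_from_parts(ll, O, mubar)
}

#' DIC from its components
#'
#' The defining identity `DIC = Dbar + pD`, exposed so reported deviance
#' summaries can be combined or checked.
#'
#' @param Dbar posterior mean deviance.
#' @param pD effective number of parameters.
#' @return `Dbar + pD`.
#' @export
dic_identity <- function(Dbar, pD) Dbar + pD

#' Watanabe-Akaike information criterion
#'
#' `lppd = sum_cells log mean_draws p(O | mu)`;
#' `p_waic = sum_cells var_draws log p(O | mu)`;
#' `WAIC = -2 (lppd - p_waic)`.
#'
#' @inheritParams dic
#' @return list with `lppd`, `p_waic`, `WAIC`.
#' @export
waic <- function(samples, panel = NULL) {
  ll <- loglik_matrix(samples, panel)
  if (nrow(ll) < 1) stop("zero draws")
  waic_from_ll(ll)
}

#' Logarithmic score via conditional predictive ordinates
#'
#' The CPO of a cell is estimated by the harmonic mean of its per-draw
#' likelihoods (the estimator computed by the nested-Laplace toolchain),
#' stabilized in log space with the inverse-likelihood weights capped at
#' their 99.9th percentile; the number of capped draws is reported. The
#' score is `LS = -mean_cells log CPO` (a mean, matching the magnitude of
#' published tables).
#'
#' @inheritParams dic
#' @param cap_quantile cap for the inverse-likelihood weights.
#' @return list with `LS`, `log_cpo` (per cell), `n_capped`.
#' @export
log_score <- function(samples, panel = NULL, cap_quantile = 0.999) {
  ll <- loglik_matrix(samples, panel)
  if (nrow(ll) < 1) stop("zero draws")
  ls_from_ll(ll, cap_quantile)
}

#' All model-selection criteria in one row
#'
#' @inheritParams dic
#' @return one-row data.frame with `Dbar`, `pD`, `DIC`, `lppd`, `p_waic`,
#'   `WAIC`, `LS`.
#' @export
model_criteria <- function(samples, panel = NULL) {
  d <- dic(samples, panel)
  w <- waic(samples, panel)
  l <- log_score(samples, panel)
  data.frame(Dbar = d$Dbar, pD = d$pD, DIC = d$DIC,
             lppd = w$lppd, p_waic = w$p_waic, WAIC = w$WAIC, LS = l$LS)
}
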