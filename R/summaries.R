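# Posterior functionals and their summaries.

# Linear-functional rows L (q x p, sparse) mapping the latent vector to the
# requested quantity on the log scale (exp_scale = TRUE) or directly.
functional_rows <- function(model, functional) {
  dims <- model$dims
  lay <- model$layout
  J <- dims$J; I <- dims$I; T <- dims$T
  p <- dims$p
  jn <- model$panel$outcome_ids
  an <- model$panel$area_ids
  tn <- model$panel$times
  sparse0 <- function(q) Matrix::Matrix(0, q, p, sparse = TRUE)
  switch(functional,
    risk = ,
    linear_predictor = list(
      L = model$design$X,
      names = paste(rep(an, T * J), rep(rep(tn, each = I), J),
                    rep(jn, each = I * T), sep = ":"),
      exp_scale = functional == "risk"),
    spatial_risk = {
      L <- sparse0(I * J)
      for (j in seq_len(J))
        L[(j - 1) * I + seq_len(I), lay$psi_block(j)] <- model$design$B_s
      list(L = methods::as(L, "CsparseMatrix"),
           names = paste(rep(an, J), rep(jn, each = I), sep = ":"),
           exp_scale = TRUE)
    },
    temporal_risk = {
      L <- sparse0(T * J)
      for (j in seq_len(J))
        L[(j - 1) * T + seq_len(T), lay$gamma_block(j)] <- model$design$B3$B
      list(L = methods::as(L, "CsparseMatrix"),
           names = paste(rep(tn, J), rep(jn, each = T), sep = ":"),
           exp_scale = TRUE)
    },
    interaction_risk = {
      L <- sparse0(I * T * J)
      L[, lay$delta] <- Matrix::Diagonal(I * T * J)
      list(L = methods::as(L, "CsparseMatrix"),
           names = paste(rep(an, T * J), rep(rep(tn, each = I), J),
                         rep(jn, each = I * T), sep = ":"),
           exp_scale = TRUE)
    },
    alpha = {
      L <- sparse0(J)
      L[cbind(seq_len(J), lay$alpha)] <- 1
      list(L = methods::as(L, "CsparseMatrix"), names = jn, exp_scale = FALSE)
    },
    stop("unknown functional name: ", functional))
}

# Correlation draws extracted from the stored covariance entries.
rho_draws <- function(samples, which = c("psi", "gamma")) {
  which <- match.arg(which)
  J <- samples$model$dims$J
  pre <- if (which == "psi") "Sigma_psi" else "Sigma_gamma"
  cols <- paste0(pre, outer(seq_len(J), seq_len(J), paste0))
  Sig <- samples$hyper[, cols, drop = FALSE]
  pairs <- which(lower.tri(diag(J)), arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(Sig), nrow(pairs))
  nm <- character(nrow(pairs))
  for (q in seq_len(nrow(pairs))) {
    j <- pairs[q, 1]; k <- pairs[q, 2]
    sjj <- Sig[, paste0(pre, k, k)] ; skk <- Sig[, paste0(pre, j, j)]
    sjk <- Sig[, paste0(pre, j, k)]
    out[, q] <- sjk / sqrt(sjj * skk)
    nm[q] <- paste(samples$model$panel$outcome_ids[k],
                   samples$model$panel$outcome_ids[j], sep = ":")
  }
  colnames(out) <- nm
  out
}

# Per-draw values of a named functional: draws x q matrix.
functional_draws <- function(samples, functional) {
  model <- samples$model
  if (functional %in% c("risk", "linear_predictor", "spatial_risk",
                        "temporal_risk", "interaction_risk", "alpha")) {
    fr <- functional_rows(model, functional)
    vals <- as.matrix(Matrix::tcrossprod(samples$latent, fr$L))
    if (fr$exp_scale) vals <- exp(vals)
    colnames(vals) <- fr$names
    vals
  } else if (functional == "rho_psi") {
    rho_draws(samples, "psi")
  } else if (functional == "rho_gamma") {
    rho_draws(samples, "gamma")
  } else if (functional == "sigma_delta") {
    J <- model$dims$J
    out <- samples$hyper[, paste0("sigma_delta", seq_len(J)), drop = FALSE]
    colnames(out) <- model$panel$outcome_ids
    out
  } else if (functional == "lambda1") {
    out <- samples$hyper[, "lambda1", drop = FALSE]
    out
  } else {
    stop("unknown functional name: ", functional)
  }
}

#' Posterior summaries of model functionals
#'
#' Posterior medians and equal-tailed credible intervals (linear
#' interpolation quantiles, type 7) for any supported functional:
#' cell relative risks (`"risk"`), area-level spatial risks
#' (`"spatial_risk"` = exp of the spatial smooth), temporal risks
#' (`"temporal_risk"`), interaction risks (`"interaction_risk"` =
#' exp(delta)), intercepts, between-outcome correlations (`"rho_psi"`,
#' `"rho_gamma"`), interaction standard deviations (`"sigma_delta"`) and
#' `"lambda1"`. Risk-type functionals also report exceedance probabilities;
#' correlations carry a `significant` flag (95% interval excluding zero).
#'
#' @param samples an `mvps_samples` object from [fit_mcmc()].
#' @param functionals character vector of functional names.
#' @param prob credible level (default 0.95).
#' @param threshold exceedance threshold for risk functionals.
#' @return data.frame with columns `functional`, `name`, `median`, `lower`,
#'   `upper`, and where applicable `exceedance` and `significant`.
#' @export
summarize_samples <- function(samples, functionals = c("risk", "rho_psi"),
                              prob = 0.95, threshold = 1) {
  if (nrow(samples$latent) < 1) stop("no retained draws")
  a <- (1 - prob) / 2
  out <- lapply(functionals, function(fn) {
    vals <- functional_draws(samples, fn)
    qs <- apply(vals, 2, stats::quantile, probs = c(a, 0.5, 1 - a),
                names = FALSE, type = 7)
    df <- data.frame(functional = fn, name = colnames(vals),
                     median = qs[2, ], lower = qs[1, ], upper = qs[3, ],
                     row.names = NULL)
    if (fn %in% c("risk", "spatial_risk", "temporal_risk", "interaction_risk"))
      df$exceedance <- colMeans(vals > threshold)
    if (fn %in% c("rho_psi", "rho_gamma"))
      df$significant <- df$lower > 0 | df$upper < 0
    df
  })
  do.call(rbind, lapply(out, function(d) {
    base <- data.frame(functional = d$functional, name = d$name,
                       median = d$median, lower = d$lower, upper = d$upper,
                       exceedance = d$exceedance %||% NA_real_,
                       significant = d$significant %||% NA)
    base
  }))
}

#' Posterior exceedance probabilities
#'
#' Fraction of posterior draws of a functional exceeding a threshold,
#' e.g. `P(exp(f_spatial) > 1 | O)`.
#'
#' @inheritParams summarize_samples
#' @param functional single functional name.
#' @return named numeric vector of probabilities in `[0, 1]`.
#' @export
exceedance <- function(samples, functional = "risk", threshold = 1) {
  vals <- functional_draws(samples, functional)
  colMeans(vals > threshold)
}
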