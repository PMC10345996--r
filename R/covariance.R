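#' Between-outcome covariance from standard deviations and correlations
#'
#' Assembles the `J x J` covariance `Sigma[j,k] = rho[j,k] * sigma[j] *
#' sigma[k]` linking the spline coefficients of the different outcomes. The
#' correlations are the identifiable, reportable quantities; the standard
#' deviations are confounded with the fixed marginal smoothing parameters.
#'
#' @param sigmas positive standard deviations (length J).
#' @param rhos either a `J x J` correlation matrix or the strict
#'   lower-triangle entries in column-major order (length `J(J-1)/2`).
#' @return object of class `outcome_covariance`: `Sigma`, `sigmas`, `rhos`
#'   (full correlation matrix), `J`.
#' @export
build_covariance <- function(sigmas, rhos) {
  J <- length(sigmas)
  if (any(sigmas <= 0)) stop("invalid correlation structure: sigmas must be positive")
  if (is.matrix(rhos)) {
    R <- rhos
  } else {
    R <- diag(J)
    R[lower.tri(R)] <- rhos
    R[upper.tri(R)] <- t(R)[upper.tri(R)]
  }
  if (any(abs(R[lower.tri(R)]) >= 1)) stop("invalid correlation structure: |rho| >= 1")
  if (any(diag(R) != 1)) stop("invalid correlation structure: diagonal must be 1")
  Sigma <- R * tcrossprod(sigmas)
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("invalid correlation structure: not positive definite")
  structure(list(Sigma = Sigma, sigmas = sigmas, rhos = R, J = J),
            class = "outcome_covariance")
}

#' Extract standard deviations and correlations from a covariance matrix
#'
#' Inverse of [build_covariance()]; round trip is exact to machine
#' precision.
#'
#' @param Sigma symmetric positive-definite matrix.
#' @return list with `sigmas` and `rhos` (correlation matrix).
#' @export
extract_covariance <- function(Sigma) {
  if (inherits(Sigma, "outcome_covariance")) Sigma <- Sigma$Sigma
  s <- sqrt(diag(Sigma))
  if (any(!is.finite(s)) || any(s <= 0)) stop("invalid covariance")
  R <- Sigma / tcrossprod(s)
  diag(R) <- 1
  list(sigmas = s, rhos = R)
}

#' Number of free parameters of a between-outcome covariance
#'
#' `J` standard deviations plus `J(J-1)/2` correlations.
#'
#' @param J number of outcomes.
#' @return integer `J(J+1)/2`.
#' @export
n_covariance_params <- function(J) {
  as.integer(J * (J + 1) / 2)
}

# Log multivariate gamma function.
lmvgamma <- function(a, p) {
  (p * (p - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# Wishart(df, S) log density at W (both p x p, S the scale matrix).
dwishart_log <- function(W, df, S) {
  p <- nrow(W)
  if (df <= p - 1) stop("Wishart degrees of freedom too small")
  cS <- chol(S)
  cW <- try(chol(W), silent = TRUE)
  if (inherits(cW, "try-error")) return(-Inf)
  ldS <- 2 * sum(log(diag(cS)))
  ldW <- 2 * sum(log(diag(cW)))
  tr <- sum(diag(backsolve(cS, forwardsolve(t(cS), W))))
  (df - p - 1) / 2 * ldW - tr / 2 - df * p / 2 * log(2) - df / 2 * ldS -
    lmvgamma(df / 2, p)
}
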