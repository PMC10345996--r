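#' Model specification
#'
#' Collects every structural choice of the multivariate spatio-temporal
#' P-spline model: penalty orders, knot counts and degree of the marginal
#' bases, the space-time interaction type, the identifiability-constraint
#' mode, whether the temporal coefficients carry a between-outcome
#' correlation, and the hyperprior settings. The Wishart degrees of freedom
#' are always `2J + 1` (set at assembly time from the panel).
#'
#' @param spatial_order,temporal_order random-walk penalty order (1 or 2)
#'   for the spatial margins and the temporal basis. The interaction
#'   structure reuses `temporal_order` for its temporal factor.
#' @param spatial_knots,temporal_knots number of equidistant knots spanning
#'   each covariate range (defaults 10 and 5; cubic splines then give 12
#'   columns per spatial margin and 7 temporal columns).
#' @param degree B-spline degree (default cubic).
#' @param interaction space-time interaction type, `"I"|"II"|"III"|"IV"`.
#' @param constraint_mode `"center"` (smooth functions orthogonal to the
#'   intercept, the default: it yields markedly narrower credible intervals)
#'   or `"sumzero"` (sum-to-zero on the coefficients).
#' @param temporal_correlation logical; `FALSE` forces a diagonal
#'   between-outcome covariance for the temporal coefficients.
#' @param sigma2_psi,sigma2_gamma Wishart scale parameters for the
#'   between-outcome priors of the spatial and temporal coefficients
#'   (default `(1, 10)`, the combination preferred by the model-selection
#'   criteria). Larger values are less informative.
#' @param lambda1 initial value of the spatial anisotropy ratio.
#' @param lambda1_bound upper bound of the uniform prior on `1/sqrt(lambda1)`.
#' @param wishart_mode `"covariance"` (default): Wishart prior with scale
#'   `sigma2 * I` placed on the between-outcome covariance matrix, the
#'   literal reading of the model; its exponential tail in large `Sigma`
#'   anchors the joint scale of `(lambda1, Sigma)`, which is otherwise a
#'   near-flat ridge. `"precision"`: Wishart on the precision (conjugate
#'   Gibbs updates, but scale-ridge prone; see the methods vignette).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(spatial_order = 1, temporal_order = 1,
                       spatial_knots = 10, temporal_knots = 5, degree = 3,
                       interaction = "II",
                       constraint_mode = c("center", "sumzero"),
                       temporal_correlation = TRUE,
                       sigma2_psi = 1, sigma2_gamma = 10,
                       lambda1 = 1, lambda1_bound = 100,
                       wishart_mode = c("covariance", "precision")) {
  stopifnot(spatial_order %in% c(1, 2), temporal_order %in% c(1, 2),
            spatial_knots >= 2, temporal_knots >= 2, degree >= 0,
            sigma2_psi > 0, sigma2_gamma > 0, lambda1 > 0, lambda1_bound > 0)
  interaction <- match.arg(interaction, c("I", "II", "III", "IV"))
  structure(list(spatial_order = spatial_order, temporal_order = temporal_order,
                 spatial_knots = spatial_knots, temporal_knots = temporal_knots,
                 degree = degree, interaction = interaction,
                 constraint_mode = match.arg(constraint_mode),
                 temporal_correlation = isTRUE(temporal_correlation),
                 sigma2_psi = sigma2_psi, sigma2_gamma = sigma2_gamma,
                 lambda1 = lambda1, lambda1_bound = lambda1_bound,
                 wishart_mode = match.arg(wishart_mode)),
            class = "model_spec")
}

#' Wishart degrees of freedom used for the between-outcome priors
#'
#' @param J number of outcomes.
#' @return `2J + 1`.
#' @export
wishart_df <- function(J) 2L * as.integer(J) + 1L

#' Expected counts by indirect standardization
#'
#' `E[i,t,j] = n[i,t] * m[j]` with `m[j]` the overall rate of outcome `j`
#' over all areas and times, so that expected counts match observed totals
#' per outcome by construction.
#'
#' @param panel a [panel_counts] object.
#' @return list with `m` (per-outcome rate) and `E` (I x T x J array).
#' @export
expected_counts <- function(panel) {
  ntot <- sum(panel$n)
  if (ntot <= 0) stop("zero total population")
  m <- apply(panel$O, 3, sum) / ntot
  E <- outer(panel$n, m)
  dimnames(E) <- dimnames(panel$O)
  list(m = m, E = E)
}

#' Sparse design blocks of the latent Gaussian model
#'
#' Maps the stacked latent vector `(alpha, Psi, Gamma, Delta)` to the
#' log-risk of every cell in canonical order (area fastest, then time, then
#' outcome): intercept block `I_J x 1_T x 1_I`, spatial block
#' `I_J x (1_T x B_s)`, temporal block `I_J x (B_3 x 1_I)` and an identity
#' for the interaction.
#'
#' @param region a [study_region].
#' @param panel a [panel_counts].
#' @param spec a [model_spec].
#' @return list with sparse matrices `X_alpha`, `X_psi`, `X_gamma`,
#'   `X_delta`, the combined `X`, the bases `B_s` (I x k1k2), `B1`, `B2`,
#'   `B3` (T x k3), and the block dimensions.
#' @export
build_design <- function(region, panel, spec) {
  I <- panel$I; T <- panel$T; J <- panel$J
  if (length(region$area_ids) != I ||
      !identical(region$area_ids, panel$area_ids))
    stop("dimension mismatch: region areas and panel areas differ")
  b1 <- bspline_basis(region$centroids[, 1], spec$spatial_knots, spec$degree)
  b2 <- bspline_basis(region$centroids[, 2], spec$spatial_knots, spec$degree)
  b3 <- bspline_basis(panel$times, spec$temporal_knots, spec$degree)
  B_s <- row_wise_kronecker(b2, b1)
  ks <- ncol(B_s); k3 <- b3$k
  ones_T <- Matrix::Matrix(1, T, 1)
  ones_I <- Matrix::Matrix(1, I, 1)
  IJ <- Matrix::Diagonal(J)
  X_alpha <- Matrix::kronecker(IJ, Matrix::kronecker(ones_T, ones_I))
  X_psi <- Matrix::kronecker(IJ, Matrix::kronecker(ones_T,
            methods::as(Matrix::Matrix(B_s, sparse = TRUE), "CsparseMatrix")))
  X_gamma <- Matrix::kronecker(IJ, Matrix::kronecker(
            methods::as(Matrix::Matrix(b3$B, sparse = TRUE), "CsparseMatrix"), ones_I))
  X_delta <- Matrix::Diagonal(I * T * J)
  X <- cbind(X_alpha, X_psi, X_gamma, X_delta)
  list(X_alpha = X_alpha, X_psi = X_psi, X_gamma = X_gamma, X_delta = X_delta,
       X = methods::as(X, "CsparseMatrix"),
       B_s = B_s, B1 = b1, B2 = b2, B3 = b3,
       dims = list(I = I, T = T, J = J, ks = ks, k1 = b1$k, k2 = b2$k, k3 = k3,
                   p = J * (1 + ks + k3 + I * T), N = I * T * J))
}

# Column offsets of the latent blocks within the stacked vector.
latent_layout <- function(dims) {
  J <- dims$J; ks <- dims$ks; k3 <- dims$k3; IT <- dims$I * dims$T
  list(alpha = seq_len(J),
       psi = J + seq_len(J * ks),
       gamma = J + J * ks + seq_len(J * k3),
       delta = J + J * ks + J * k3 + seq_len(J * IT),
       psi_block = function(j) J + (j - 1) * ks + seq_len(ks),
       gamma_block = function(j) J + J * ks + (j - 1) * k3 + seq_len(k3),
       delta_block = function(j) J + J * ks + J * k3 + (j - 1) * IT + seq_len(IT))
}

#' Identifiability constraint matrix
#'
#' Rows `A` such that the latent field is restricted to `A x = 0`. In
#' `"center"` mode the smooth functions are made orthogonal to the
#' intercepts (`sum_i f_j = 0`, `sum_t f_j = 0` per outcome); in
#' `"sumzero"` mode the coefficient sums vanish instead. Interaction rows
#' (from [interaction_structure()]) are appended per outcome.
#'
#' @inheritParams build_design
#' @param design optional precomputed [build_design()] result.
#' @return dense constraint matrix with `p` columns.
#' @export
constraint_matrix <- function(region, panel, spec, design = NULL) {
  if (is.null(design)) design <- build_design(region, panel, spec)
  dims <- design$dims
  lay <- latent_layout(dims)
  J <- dims$J
  p <- dims$p
  rows <- list()
  add_row <- function(cols, vals) {
    r <- numeric(p); r[cols] <- vals; rows[[length(rows) + 1]] <<- r
  }
  s_psi <- if (spec$constraint_mode == "center") colSums(design$B_s) else rep(1, dims$ks)
  s_gam <- if (spec$constraint_mode == "center") colSums(design$B3$B) else rep(1, dims$k3)
  for (j in seq_len(J)) add_row(lay$psi_block(j), s_psi)
  for (j in seq_len(J)) add_row(lay$gamma_block(j), s_gam)
  A_smooth <- do.call(rbind, rows)
  vr <- validate_region(region)
  istr <- interaction_structure(spec$interaction, Q_I = icar_precision(region),
                                I = dims$I, T = dims$T,
                                rw_order = spec$temporal_order,
                                components = unname(vr$membership))
  Ad <- istr$constraint_rows
  if (nrow(Ad)) {
    A_int <- matrix(0, nrow(Ad) * J, p)
    for (j in seq_len(J)) {
      rr <- (j - 1) * nrow(Ad) + seq_len(nrow(Ad))
      A_int[rr, lay$delta_block(j)] <- Ad
    }
    A <- rbind(A_smooth, A_int)
  } else {
    A <- A_smooth
  }
  A
}

#' Log kernel of the joint latent prior
#'
#' `-1/2 [ Psi' (Sigma_psi^{-1} x P_s) Psi + Gamma' (Sigma_gamma^{-1} x P_3)
#' Gamma + Delta' Blockdiag(tau_j M_j) Delta ]`, flat over the intercepts.
#' Unnormalized: the value at the zero state is 0.
#'
#' @param state list with `alpha`, `Psi` (length J*ks), `Gamma` (J*k3),
#'   `Delta` (J*I*T), stacked outcome-wise.
#' @param hyper list with `Sigma_psi`, `Sigma_gamma` (J x J covariance
#'   matrices), `lambda1` (> 0), `tau` (length J, > 0).
#' @param model an assembled model from [assemble_model()].
#' @return log kernel value (scalar).
#' @export
latent_prior_logdensity <- function(state, hyper, model) {
  J <- model$dims$J
  Om_psi <- solve_pd(hyper$Sigma_psi)
  Om_gam <- solve_pd(hyper$Sigma_gamma)
  if (any(hyper$tau <= 0) || hyper$lambda1 <= 0) stop("invalid hyperparameters")
  Ps <- hyper$lambda1 * model$spatial$K1 + model$spatial$K2
  q <- quad_form_kron(state$Psi, Om_psi, Ps, model$dims$ks) +
       quad_form_kron(state$Gamma, Om_gam, model$P3, model$dims$k3)
  IT <- model$dims$I * model$dims$T
  for (j in seq_len(J)) {
    d <- state$Delta[(j - 1) * IT + seq_len(IT)]
    q <- q + hyper$tau[j] * as.numeric(d %*% (model$M_struct %*% d))
  }
  -0.5 * q
}

# x' (Om x P) x with x stacked in J blocks of length k.
quad_form_kron <- function(x, Om, P, k) {
  J <- nrow(Om)
  Xm <- matrix(x, nrow = k, ncol = J)  # columns = outcome blocks
  PX <- as.matrix(P %*% Xm)
  S <- crossprod(Xm, PX)               # S[j,l] = x_j' P x_l
  sum(Om * S)
}

solve_pd <- function(S) {
  ch <- try(chol(S), silent = TRUE)
  if (inherits(ch, "try-error")) stop("invalid covariance")
  chol2inv(ch)
}

#' Log density of the hyperprior
#'
#' Wishart priors (degrees of freedom `2J + 1`, scale `sigma2 * I`) on the
#' between-outcome precision matrices (default) or, in `"covariance"` mode,
#' literally on the covariance matrices; a uniform prior on
#' `1/sqrt(lambda1)` truncated at `lambda1_bound`; improper flat priors on
#' the interaction standard deviations `1/sqrt(tau_j)`.
#'
#' @param hyper list with `Sigma_psi`, `Sigma_gamma`, `lambda1`, `tau`.
#' @param spec a [model_spec].
#' @param J number of outcomes.
#' @return log density (up to the flat-prior constant); `-Inf` outside the
#'   support.
#' @export
hyperprior_logdensity <- function(hyper, spec, J) {
  df <- wishart_df(J)
  if (hyper$lambda1 <= 0 || any(hyper$tau <= 0)) return(-Inf)
  u <- 1 / sqrt(hyper$lambda1)
  if (u >= spec$lambda1_bound) return(-Inf)
  lp <- -log(spec$lambda1_bound)
  wish_term <- function(Sigma, sigma2) {
    S0 <- diag(sigma2, nrow(Sigma))
    if (spec$wishart_mode == "precision")
      dwishart_log(solve_pd(Sigma), df, S0)
    else
      dwishart_log(Sigma, df, S0)
  }
  lp <- lp + wish_term(hyper$Sigma_psi, spec$sigma2_psi)
  if (spec$temporal_correlation) {
    lp <- lp + wish_term(hyper$Sigma_gamma, spec$sigma2_gamma)
  } else {
    # independent one-dimensional Wishart (gamma) terms on the diagonal
    for (j in seq_len(J))
      lp <- lp + wish_term(hyper$Sigma_gamma[j, j, drop = FALSE], spec$sigma2_gamma)
  }
  lp
}

#' Assemble the full model for a region, panel and specification
#'
#' Precomputes everything the samplers need: design blocks, penalties and
#' their eigenvalues (for generalized log determinants), the interaction
#' structure, expected counts, the constraint matrix and the canonical data
#' vectors.
#'
#' @inheritParams build_design
#' @return object of class `mvps_model`.
#' @export
assemble_model <- function(region, panel, spec) {
  design <- build_design(region, panel, spec)
  dims <- design$dims
  P1 <- penalty_matrix(dims$k1, spec$spatial_order)
  P2 <- penalty_matrix(dims$k2, spec$spatial_order)
  sp <- spatial_penalty(P1, P2, spec$lambda1)
  P3spec <- penalty_matrix(dims$k3, spec$temporal_order)
  vr <- validate_region(region)
  Q_I <- icar_precision(region)
  istr <- interaction_structure(spec$interaction, Q_I = Q_I,
                                I = dims$I, T = dims$T,
                                rw_order = spec$temporal_order,
                                components = unname(vr$membership))
  ec <- expected_counts(panel)
  # eigenvalues for generalized log-determinants
  ev1 <- eigen(as_dense(P1$P), symmetric = TRUE, only.values = TRUE)$values
  ev2 <- eigen(as_dense(P2$P), symmetric = TRUE, only.values = TRUE)$values
  ev3 <- eigen(as_dense(P3spec$P), symmetric = TRUE, only.values = TRUE)$values
  evM <- eigen(as_dense(istr$M_struct), symmetric = TRUE, only.values = TRUE)$values
  A <- constraint_matrix(region, panel, spec, design)
  model <- list(region = region, panel = panel, spec = spec, design = design,
                dims = dims, layout = latent_layout(dims),
                P1 = P1, P2 = P2, spatial = sp, P3 = P3spec$P,
                P3_rank = P3spec$rank, M_struct = istr$M_struct,
                M_rank = istr$rank, interaction = istr,
                ev1 = ev1, ev2 = ev2, ev3 = ev3, evM = evM,
                E = as.vector(ec$E), m = ec$m, O = as.vector(panel$O),
                A = A, components = vr$components)
  class(model) <- "mvps_model"
  model
}

# Generalized log-determinant of P_s(lambda1) = lambda1 K1 + K2 using the
# marginal penalty eigenvalues: the eigenvalues are lambda1*a + b over all
# pairs; pairs with a = b = 0 form the null space.
spatial_gen_logdet <- function(model, lambda1, tol = 1e-9) {
  a <- pmax(model$ev1, 0); b <- pmax(model$ev2, 0)
  a[a < tol * max(a)] <- 0
  b[b < tol * max(b)] <- 0
  vals <- outer(b, a, function(bb, aa) lambda1 * aa + bb)
  sum(log(vals[vals > 0]))
}

#' Serialize / deserialize a model specification
#'
#' @param spec a [model_spec].
#' @param path JSON file path.
#' @return `spec_to_json` returns `path` invisibly; `spec_from_json`
#'   returns a [model_spec].
#' @export
spec_to_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname spec_to_json
#' @export
spec_from_json <- function(path) {
  v <- jsonlite::fromJSON(path)
  do.call(model_spec, v)
}
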