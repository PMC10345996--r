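#' Forward difference matrix
#'
#' Order-`order` forward differences of a length-`k` coefficient vector;
#' the result has `k - order` rows. `D %*% x` is zero for constant `x`
#' (order 1) or linear-in-index `x` (order 2).
#'
#' @param k number of coefficients.
#' @param order 1 or 2.
#' @return sparse `(k - order) x k` matrix.
#' @export
difference_matrix <- function(k, order = 1) {
  stopifnot(order %in% c(1, 2))
  if (k <= order) stop("too few coefficients")
  D <- Matrix::Diagonal(k)
  for (r in seq_len(order)) {
    m <- nrow(D)
    D <- D[-1, , drop = FALSE] - D[-m, , drop = FALSE]
  }
  methods::as(D, "generalMatrix")
}

#' Random-walk difference penalty
#'
#' The structure matrix `P = D'D` of a first or second order random walk on
#' `k` coefficients: symmetric positive semi-definite with rank `k - order`
#' and a polynomial null space (constants for order 1; constants and the
#' linear ramp for order 2).
#'
#' @param k number of coefficients.
#' @param order 1 or 2.
#' @return list of class `penalty_spec`: `D`, `P` (sparse `k x k`), `order`,
#'   `rank`, `nullspace` (k x order orthonormal basis).
#' @export
penalty_matrix <- function(k, order = 1) {
  D <- difference_matrix(k, order)
  P <- Matrix::crossprod(D)
  idx <- seq_len(k)
  ns <- switch(order, cbind(rep(1, k)), cbind(rep(1, k), idx - mean(idx)))
  ns <- qr.Q(qr(ns))
  structure(list(D = D, P = Matrix::forceSymmetric(P), order = order,
                 k = k, rank = k - order, nullspace = ns),
            class = "penalty_spec")
}

#' Random-walk precision matrix
#'
#' Identical to the structure matrix of [penalty_matrix()]; exported under
#' the name used for the temporal factor of the space-time interaction
#' structures.
#'
#' @param T number of time points.
#' @param order 1 or 2.
#' @return sparse `T x T` matrix of rank `T - order`.
#' @export
rw_precision <- function(T, order = 1) {
  penalty_matrix(T, order)$P
}

#' Two-dimensional spatial penalty
#'
#' `P_s = lambda1 (I_{k2} x P1) + lambda2 (P2 x I_{k1})`, the Kronecker-sum
#' penalty of the surface coefficients with anisotropy ratio `lambda1`
#' (`lambda2` is fixed at 1: only the ratio is identifiable once a
#' between-outcome covariance scales the whole penalty). When both margins
#' share penalty order `r` the rank is `k1*k2 - r^2`.
#'
#' @param P1 penalty for the fast (longitude) margin: `penalty_spec` or
#'   matrix.
#' @param P2 penalty for the slow (latitude) margin.
#' @param lambda1 positive smoothing ratio for the longitude term.
#' @return list of class `spatial_penalty`: `P_s` (sparse), `lambda1`,
#'   `lambda2 = 1`, `k1`, `k2`, and the two Kronecker terms `K1`, `K2`
#'   (so `P_s = lambda1 K1 + K2`).
#' @export
spatial_penalty <- function(P1, P2, lambda1 = 1) {
  if (lambda1 <= 0 || !is.finite(lambda1)) stop("invalid smoothing parameter")
  M1 <- if (inherits(P1, "penalty_spec")) P1$P else methods::as(P1, "CsparseMatrix")
  M2 <- if (inherits(P2, "penalty_spec")) P2$P else methods::as(P2, "CsparseMatrix")
  k1 <- nrow(M1); k2 <- nrow(M2)
  K1 <- Matrix::kronecker(Matrix::Diagonal(k2), M1)
  K2 <- Matrix::kronecker(M2, Matrix::Diagonal(k1))
  structure(list(P_s = Matrix::forceSymmetric(lambda1 * K1 + K2),
                 K1 = Matrix::forceSymmetric(K1), K2 = Matrix::forceSymmetric(K2),
                 lambda1 = lambda1, lambda2 = 1, k1 = k1, k2 = k2),
            class = "spatial_penalty")
}

#' Intrinsic CAR (graph Laplacian) precision matrix
#'
#' Diagonal entries are neighbour counts, off-diagonal entries are -1 for
#' neighbouring areas. Rank is `I - c` for `c` graph components; isolated
#' areas are allowed and simply contribute a zero row/column (one component
#' each).
#'
#' @param region a [study_region] with adjacency loaded.
#' @return sparse symmetric `I x I` matrix with dimnames = area ids.
#' @export
icar_precision <- function(region) {
  ids <- region$area_ids
  I <- length(ids)
  Q <- Matrix::Matrix(0, I, I, sparse = TRUE, dimnames = list(ids, ids))
  if (nrow(region$adjacency)) {
    a <- match(region$adjacency[, 1], ids)
    b <- match(region$adjacency[, 2], ids)
    Q <- Q + Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = -1,
                                  dims = c(I, I), dimnames = list(ids, ids))
    deg <- tabulate(c(a, b), nbins = I)
    Q <- Q + Matrix::Diagonal(I, deg)
  }
  Matrix::forceSymmetric(Q)
}

#' Space-time interaction structure
#'
#' The four classical intrinsic structures for the interaction term: with
#' `Q_T` the random-walk precision (order `rw_order`) and `Q_I` the
#' intrinsic spatial precision,
#' type I is `I_{IT}`, type II is `Q_T x I_I` (time-structured), type III is
#' `I_T x Q_I` (space-structured) and type IV is `Q_T x Q_I`. The precision
#' scale `tau` is factored out. Identifiability constraint rows are
#' generated per type: none for I; for II, per area, the sums over time
#' (plus, for RW2, the linear-in-time contrasts); for III, per time, the
#' sums over areas within each graph component; for IV, both sets with the
#' per-component overlap removed. The interaction vector is indexed area
#' fastest, then time.
#'
#' @param type one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param Q_I sparse spatial precision ([icar_precision()]); may be `NULL`
#'   for types I and II.
#' @param Q_T sparse temporal random-walk precision; may be `NULL` for
#'   types I and III (built internally from `T` and `rw_order` otherwise).
#' @param I,T numbers of areas and time points.
#' @param rw_order temporal random-walk order (1 or 2) used for types II
#'   and IV.
#' @param components integer membership vector of graph components (from
#'   [validate_region()]); defaults to one component.
#' @return list of class `interaction_structure`: `type`, `rw_order`,
#'   `M_struct` (sparse `IT x IT`), `rank`, `constraint_rows` (dense matrix,
#'   possibly 0 rows).
#' @export
interaction_structure <- function(type, Q_I = NULL, Q_T = NULL, I, T,
                                  rw_order = 1, components = NULL) {
  type <- match.arg(type, c("I", "II", "III", "IV"))
  if (is.null(components)) components <- rep(1L, I)
  ncomp <- length(unique(components))
  if (type %in% c("II", "IV") && is.null(Q_T)) Q_T <- rw_precision(T, rw_order)
  if (type %in% c("III", "IV") && is.null(Q_I))
    stop("spatial precision required for types III and IV")
  II_ <- Matrix::Diagonal(I)
  IT_ <- Matrix::Diagonal(T)
  M <- switch(type,
    I   = Matrix::Diagonal(I * T),
    II  = Matrix::kronecker(Q_T, II_),
    III = Matrix::kronecker(IT_, Q_I),
    IV  = Matrix::kronecker(Q_T, Q_I))
  rank <- switch(type,
    I   = I * T,
    II  = I * (T - rw_order),
    III = (I - ncomp) * T,
    IV  = (I - ncomp) * (T - rw_order))
  A <- interaction_constraints(type, I, T, rw_order, components)
  structure(list(type = type, rw_order = rw_order,
                 M_struct = Matrix::forceSymmetric(M), rank = rank,
                 constraint_rows = A),
            class = "interaction_structure")
}

# Constraint rows for one outcome's interaction block (IT columns, area
# fastest then time).
interaction_constraints <- function(type, I, T, rw_order, components) {
  ncomp <- length(unique(components))
  rows <- list()
  tt <- seq_len(T)
  if (type %in% c("II", "IV")) {
    for (i in seq_len(I)) {           # sum over time, per area
      r <- numeric(I * T); r[i + (tt - 1) * I] <- 1; rows[[length(rows) + 1]] <- r
    }
    if (rw_order == 2) {
      for (i in seq_len(I)) {         # linear-in-time contrast, per area
        r <- numeric(I * T); r[i + (tt - 1) * I] <- tt - mean(tt)
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  if (type %in% c("III", "IV")) {
    comp_ids <- unique(components)
    # For type IV the span of the per-area rows already contains the
    # component-wise constant (and, for RW2, linear) time profiles, so the
    # last rw_order area-sum rows per component are redundant and dropped.
    tmax <- if (type == "IV") T - rw_order else T
    for (g in comp_ids) {
      areas <- which(components == g)
      for (t in seq_len(tmax)) {      # sum over the component's areas, per time
        r <- numeric(I * T); r[areas + (t - 1) * I] <- 1
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  if (!length(rows)) return(matrix(0, 0, I * T))
  do.call(rbind, rows)
}
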