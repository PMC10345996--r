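#' Equidistant B-spline basis
#'
#' Builds a degree-`degree` B-spline basis on `num_knots` equally spaced
#' knots spanning `[min(x), max(x)]` inclusive (`num_knots - 1` segments),
#' with `degree` extra knots appended on each side at the same spacing
#' (equally spaced extension, not coincident boundary knots, so that the
#' equidistant difference penalty keeps its random-walk interpretation).
#' The basis then has `num_knots - 1 + degree` columns: 10 knots with cubic
#' splines give 12 columns, 5 knots give 7.
#'
#' @param x numeric vector of covariate values (need not be sorted).
#' @param num_knots integer >= 2, number of equidistant knots spanning the
#'   data range.
#' @param degree polynomial degree >= 0 (3 = cubic).
#' @return An object of class `bspline_basis`: list with `B` (length(x) x k
#'   matrix), `k`, `knots` (full extended mesh), `degree`, `range`.
#' @export
bspline_basis <- function(x, num_knots, degree = 3) {
  stopifnot(num_knots >= 2, degree >= 0)
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("covariate values must be finite")
  rng <- range(x)
  if (rng[1] == rng[2]) stop("degenerate covariate range")
  h <- diff(rng) / (num_knots - 1)
  idx <- (-degree):(num_knots - 1 + degree)
  knots <- rng[1] + idx * h
  # pin the upper boundary knot exactly so x = max(x) stays inside
  knots[idx == num_knots - 1] <- rng[2]
  B <- splines::splineDesign(knots, x, ord = degree + 1)
  k <- num_knots - 1 + degree
  stopifnot(ncol(B) == k)
  structure(list(B = B, k = k, knots = knots, degree = degree, range = rng),
            class = "bspline_basis")
}

#' @export
print.bspline_basis <- function(x, ...) {
  cat(sprintf("bspline_basis: degree %d, %d columns, %d evaluation points\n",
              x$degree, x$k, nrow(x$B)))
  invisible(x)
}

#' Row-wise Kronecker (box) product of two bases
#'
#' For matrices with equal row counts, row r of the result is
#' `kronecker(B2[r, ], B1[r, ])`, i.e. the column index of `B1` varies
#' fastest. Applied to marginal longitude/latitude bases it yields the
#' two-dimensional surface basis of dimension `rows x (k1*k2)`. If both
#' inputs have unit row sums so does the product.
#'
#' @param B2 matrix (or `bspline_basis`) whose columns vary slowest.
#' @param B1 matrix (or `bspline_basis`) whose columns vary fastest.
#' @return numeric matrix with `ncol(B1) * ncol(B2)` columns.
#' @export
row_wise_kronecker <- function(B2, B1) {
  if (inherits(B2, "bspline_basis")) B2 <- B2$B
  if (inherits(B1, "bspline_basis")) B1 <- B1$B
  B1 <- as.matrix(B1); B2 <- as.matrix(B2)
  if (nrow(B1) != nrow(B2)) stop("incompatible bases: row counts differ")
  k1 <- ncol(B1); k2 <- ncol(B2)
  # (B2 %x% 1'_{k1}) * (1'_{k2} %x% B1), computed by column indexing
  B2[, rep(seq_len(k2), each = k1), drop = FALSE] *
    B1[, rep(seq_len(k1), times = k2), drop = FALSE]
}
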