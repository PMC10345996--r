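# Descriptive and model-based outputs: standardized incidence ratios,
# risk surfaces, and functional-boxplot outlier detection.

#' Standardized incidence ratios
#'
#' `SIR = sum(O) / sum(E)` over the cells of the requested margin:
#' `"cell"` (every area-time-outcome cell), `"area"` (per outcome-area,
#' aggregating over time) or `"time"` (per outcome-year, aggregating over
#' areas).
#'
#' @param panel a [panel_counts].
#' @param expected result of [expected_counts()] (computed if omitted).
#' @param margin `"cell"`, `"area"` or `"time"`.
#' @return data.frame with the margin keys, `observed`, `expected`, `sir`.
#' @export
sir <- function(panel, expected = NULL, margin = c("time", "area", "cell")) {
  margin <- match.arg(margin)
  expected <- expected %||% expected_counts(panel)
  O <- panel$O; E <- expected$E
  if (margin == "cell") {
    g <- expand.grid(area_id = panel$area_ids, time = panel$times,
                     outcome = panel$outcome_ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$observed <- as.vector(O); g$expected <- as.vector(E)
  } else if (margin == "area") {
    g <- expand.grid(area_id = panel$area_ids, outcome = panel$outcome_ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$observed <- as.vector(apply(O, c(1, 3), sum))
    g$expected <- as.vector(apply(E, c(1, 3), sum))
  } else {
    g <- expand.grid(time = panel$times, outcome = panel$outcome_ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$observed <- as.vector(apply(O, c(2, 3), sum))
    g$expected <- as.vector(apply(E, c(2, 3), sum))
  }
  if (any(g$expected <= 0)) stop("margin with zero expected count")
  g$sir <- g$observed / g$expected
  g
}

#' Pearson correlations between outcome-wise SIR patterns
#'
#' Correlates the per-area (or per-year) SIR vectors of every outcome pair;
#' the exploratory counterpart of the model-based coefficient correlations.
#'
#' @param sir_table output of [sir()] with margin `"area"` or `"time"`.
#' @return symmetric correlation matrix with outcome dimnames.
#' @export
pearson_pattern_correlations <- function(sir_table) {
  key <- if ("area_id" %in% names(sir_table)) "area_id" else "time"
  wide <- stats::reshape(
    sir_table[, c(key, "outcome", "sir")], direction = "wide",
    idvar = key, timevar = "outcome")
  m <- as.matrix(wide[, -1, drop = FALSE])
  colnames(m) <- sub("^sir\\.", "", colnames(m))
  if (nrow(m) < 3) stop("need at least 3 margin points")
  if (any(apply(m, 2, stats::sd) == 0)) stop("zero variance SIR vector")
  stats::cor(m)
}

#' Model-based risk surfaces and trends
#'
#' Convenience wrapper returning posterior summaries (medians, credible
#' intervals, exceedance probabilities) of the district-level spatial risk
#' `exp(f_j(x1, x2))`, the temporal risk `exp(f_j(x3))`, the area-specific
#' interaction trends `exp(delta)` and the full relative risks.
#'
#' @param samples an `mvps_samples` object.
#' @return named list of data.frames: `spatial`, `temporal`, `interaction`,
#'   `risk`.
#' @export
risk_surfaces <- function(samples) {
  list(spatial = summarize_samples(samples, "spatial_risk"),
       temporal = summarize_samples(samples, "temporal_risk"),
       interaction = summarize_samples(samples, "interaction_risk"),
       risk = summarize_samples(samples, "risk"))
}

#' Modified band depth of a set of curves
#'
#' Band depth with bands formed by all pairs of curves and
#' proportion-of-domain membership: the depth of curve `i` is the average,
#' over the `n(n-1)/2` pairs, of the fraction of time points at which the
#' curve lies inside the pair's pointwise envelope.
#'
#' @param curves numeric matrix, one row per curve.
#' @return numeric vector of depths in `[0, 1]`.
#' @export
modified_band_depth <- function(curves) {
  curves <- as.matrix(curves)
  n <- nrow(curves); Tn <- ncol(curves)
  if (n < 3) stop("fewer than 3 curves")
  depth <- numeric(n)
  pairs <- utils::combn(n, 2)
  for (q in seq_len(ncol(pairs))) {
    lo <- pmin(curves[pairs[1, q], ], curves[pairs[2, q], ])
    hi <- pmax(curves[pairs[1, q], ], curves[pairs[2, q], ])
    inside <- sweep(sweep(curves, 2, lo, `>=`) &
                    sweep(curves, 2, hi, `<=`), 1, 1, `*`)
    depth <- depth + rowMeans(inside)
  }
  depth / ncol(pairs)
}

#' Functional boxplot with outlier detection
#'
#' Ranks curves by modified band depth; the central region is the pointwise
#' envelope of the deepest 50% (ties broken by row order for deterministic
#' membership), the fences inflate the central envelope by `fence_factor`
#' times the central range, and any curve leaving the fences at any time
#' point is flagged as an outlier.
#'
#' @param curves numeric matrix (>= 3 rows), one row per curve; rownames
#'   become curve ids.
#' @param fence_factor fence inflation factor (default 1.5).
#' @return object of class `functional_boxplot`: `depth`, `median_curve`
#'   (id of the deepest curve), `central_ids`, `envelope` (lower/upper),
#'   `fences` (lower/upper), `outliers` (ids).
#' @export
functional_boxplot <- function(curves, fence_factor = 1.5) {
  curves <- as.matrix(curves)
  n <- nrow(curves)
  if (n < 3) stop("fewer than 3 curves")
  ids <- rownames(curves) %||% as.character(seq_len(n))
  depth <- modified_band_depth(curves)
  ord <- order(-depth, seq_len(n))      # deepest first, ties by row order
  n_central <- ceiling(n / 2)
  central <- ord[seq_len(n_central)]
  env_lo <- apply(curves[central, , drop = FALSE], 2, min)
  env_hi <- apply(curves[central, , drop = FALSE], 2, max)
  rng <- env_hi - env_lo
  fence_lo <- env_lo - fence_factor * rng
  fence_hi <- env_hi + fence_factor * rng
  out <- which(apply(curves, 1, function(cv) any(cv < fence_lo | cv > fence_hi)))
  structure(list(depth = stats::setNames(depth, ids),
                 median_curve = ids[ord[1]],
                 central_ids = ids[sort(central)],
                 envelope = list(lower = env_lo, upper = env_hi),
                 fences = list(lower = fence_lo, upper = fence_hi),
                 outliers = ids[out]),
            class = "functional_boxplot")
}

#' @export
print.functional_boxplot <- function(x, ...) {
  cat(sprintf("functional_boxplot: %d curves, %d central, outliers: %s\n",
              length(x$depth), length(x$central_ids),
              if (length(x$outliers)) paste(x$outliers, collapse = ", ") else "none"))
  invisible(x)
}

#' Area-level risk-trend curves for outlier screening
#'
#' Extracts, for one outcome, the posterior-median relative-risk trajectory
#' of every area (a curve over time) in the form [functional_boxplot()]
#' expects.
#'
#' @param samples an `mvps_samples` object.
#' @param outcome outcome id (defaults to the first).
#' @return matrix with one row per area, one column per time point.
#' @export
risk_trend_curves <- function(samples, outcome = NULL) {
  model <- samples$model
  outcome <- outcome %||% model$panel$outcome_ids[1]
  j <- match(outcome, model$panel$outcome_ids)
  if (is.na(j)) stop("unknown outcome: ", outcome)
  sm <- summarize_samples(samples, "risk")
  I <- model$dims$I; T <- model$dims$T
  cells <- (j - 1) * I * T + seq_len(I * T)
  matrix(sm$median[cells], nrow = I, ncol = T,
         dimnames = list(model$panel$area_ids, model$panel$times))
}
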