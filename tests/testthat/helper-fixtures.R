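# Shared fixture builders; everything generated in code.

tiny_panel_df <- function() {
  expand.grid(area_id = c("A", "B"), time = c(2001, 2002), outcome = "rape",
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    transform(count = c(3L, 1L, 4L, 1L), population = c(100, 200, 110, 210))
}

tiny_panel_csv <- function() {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tiny_panel_df(), f, row.names = FALSE, quote = FALSE)
  f
}

path_region <- function(n = 3) {
  ids <- LETTERS[seq_len(n)]
  adj <- cbind(ids[-n], ids[-1])
  study_region(ids, cbind(seq_len(n), rep(0, n)), adj)
}

# Small complete panel on an arbitrary region, Poisson counts around E.
small_panel <- function(region, T = 4, J = 2, seed = 42, rate = 2e-4,
                        pop = 5e4) {
  set.seed(seed)
  I <- length(region$area_ids)
  df <- expand.grid(area_id = region$area_ids, time = seq_len(T),
                    outcome = paste0("c", seq_len(J)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$population <- pop
  df$count <- stats::rpois(nrow(df), pop * rate)
  panel_counts(df)
}

small_spec <- function(...) {
  model_spec(spatial_knots = 2, temporal_knots = 2, degree = 1,
             interaction = "II", ...)
}

# independent numeric rank oracle
rank_oracle <- function(M, tol = 1e-8) {
  s <- svd(as.matrix(M))$d
  sum(s > tol * max(s, 1))
}
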