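# Internal helpers shared across modules.

# FNV-1a 32-bit hash of a character scalar; used to fingerprint run configs.
# Double arithmetic (base R has no unsigned 32-bit integers).
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  # format as 8 hex digits (doubles cannot use %x directly)
  hex <- "0123456789abcdef"
  out <- character(8)
  for (k in 8:1) {
    out[k] <- substr(hex, h %% 16 + 1, h %% 16 + 1)
    h <- h %/% 16
  }
  paste(out, collapse = "")
}

# 32-bit xor on doubles holding unsigned ints.
xor32 <- function(a, b) {
  r <- 0
  p <- 1
  for (k in 1:32) {
    abit <- a %% 2
    bbit <- b %% 2
    r <- r + p * as.numeric(xor(abit >= 1, bbit >= 1))
    a <- a %/% 2
    b <- b %/% 2
    p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

config_hash <- function(config) {
  fnv1a32(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
}

# Numeric rank via eigenvalues of a symmetric matrix.
sym_rank <- function(M, tol = 1e-8) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sum(ev > tol * max(abs(ev), 1))
}

# Log generalized determinant (product of eigenvalues above tol) of a
# symmetric PSD matrix; returns list(logdet, rank).
gen_logdet <- function(M, tol = 1e-8) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  keep <- ev > tol * max(abs(ev), 1)
  list(logdet = sum(log(ev[keep])), rank = sum(keep))
}

as_dense <- function(M) as.matrix(M)

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
}
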