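# Internal helpers shared across modules.

# Deterministic child seed from a parent seed and an index; stays inside the
# 32-bit signed range so it is always a legal `set.seed()` argument.
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  m <- 2147483629
  s <- (abs(as.double(seed)) %% m)
  x <- (s * 16807 + as.double(index) * 2654435761 + 1) %% m
  as.integer(x)
}

# Names of predictor columns (x1, x2, ...) in a study tibble, in index order.
predictor_cols <- function(df) {
  nm <- grep("^x[0-9]+$", names(df), value = TRUE)
  nm[order(as.integer(sub("^x", "", nm)))]
}

# Predictor matrix from a study tibble.
predictor_matrix <- function(df) {
  cols <- predictor_cols(df)
  if (length(cols) == 0L) {
    stop("no predictor columns (x1, x2, ...) found", call. = FALSE)
  }
  as.matrix(df[cols])
}

# Trapezoidal quadrature on a uniform or non-uniform grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
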