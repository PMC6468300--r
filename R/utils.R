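# Internal numeric helpers shared across modules.

geom_mean <- function(x) {
  exp(mean(log(x)))
}

# Row-wise sample standard deviation (n - 1 denominator) of a numeric matrix.
row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

# Stable order: ranks by value, breaking ties by original position so that
# results are invariant to permutations up to the documented tie-break.
stable_order <- function(x) {
  order(x, seq_along(x), method = "radix")
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

# Collapse a character vector for error messages, truncating long lists.
id_list <- function(ids, max = 10L) {
  if (length(ids) > max) {
    ids <- c(head(ids, max), sprintf("... (%d more)", length(ids) - max))
  }
  paste(ids, collapse = ", ")
}
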