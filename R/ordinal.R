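# Ordinal-pattern symbolization: each window of D points (spaced by
# `delay`) is encoded as the permutation of indices that sorts it
# ascending, with ties broken by order of occurrence (stable sort).
# Symbolized series feed the discrete machinery, so symbolization is
# invariant under any positive affine transform of the amplitudes.

check_ordinal_spec <- function(n, D, delay) {
  if (!is.numeric(D) || length(D) != 1 || D < 2 || D != round(D))
    abort_it("embedding dimension `D` must be an integer >= 2",
             "it_parameter_error")
  if (!is.numeric(delay) || length(delay) != 1 || delay < 1 || delay != round(delay))
    abort_it("`delay` must be an integer >= 1", "it_parameter_error")
  need <- (D - 1) * delay + 1
  if (n < need)
    abort_it(sprintf("series too short for ordinal patterns: need at least %d points (have %d)",
                     need, n), "it_insufficient_data_error")
  invisible(need)
}

#' Symbolize a series into ordinal patterns
#'
#' Each of the `n - (D-1) * delay` windows
#' `(x[t], x[t + delay], ..., x[t + (D-1) delay])` becomes the
#' permutation of 0-based indices that sorts the window ascending
#' (stable order for ties).  At most `factorial(D)` distinct symbols can
#' occur.
#'
#' @param series Numeric vector.
#' @param D Embedding dimension (window size), integer >= 2.
#' @param delay Spacing between points inside a window, integer >= 1.
#' @return Character vector of patterns such as `"1.2.0"`.
#' @examples
#' symbolize(c(3, 1, 2), D = 3)  # "1.2.0"
#' @export
symbolize <- function(series, D = 3, delay = 1) {
  check_nonempty(series, "series")
  if (!is.numeric(series))
    abort_it("`series` must be numeric for ordinal symbolization", "it_value_error")
  n <- length(series)
  check_ordinal_spec(n, D, delay)
  m <- n - (D - 1) * delay
  offsets <- (0:(D - 1)) * delay
  out <- character(m)
  for (t in seq_len(m)) {
    w <- series[t + offsets]
    out[t] <- paste(order(w, method = "radix") - 1L, collapse = ".")
  }
  out
}

#' Compact integer codec for ordinal patterns
#'
#' `ordinal_index()` maps pattern strings (as produced by [symbolize()])
#' to their Lehmer-code index in `0:(factorial(D) - 1)`;
#' `ordinal_pattern()` is the inverse.
#'
#' @param symbols Character vector of patterns (`"1.2.0"` style).
#' @param index Integer vector of pattern indices.
#' @param D Embedding dimension.
#' @return Integer indices, or pattern strings.
#' @examples
#' ordinal_index("1.2.0", D = 3)
#' ordinal_pattern(3, D = 3)
#' @export
ordinal_index <- function(symbols, D) {
  vapply(strsplit(symbols, ".", fixed = TRUE), function(p) {
    p <- as.integer(p)
    if (length(p) != D) abort_it("pattern arity does not match D", "it_shape_error")
    idx <- 0L
    avail <- 0:(D - 1)
    for (i in seq_len(D - 1)) {
      r <- match(p[i], avail) - 1L
      idx <- idx + r * factorial(D - i)
      avail <- avail[-(r + 1L)]
    }
    as.integer(idx)
  }, integer(1))
}

#' @rdname ordinal_index
#' @export
ordinal_pattern <- function(index, D) {
  vapply(as.integer(index), function(ix) {
    if (ix < 0 || ix >= factorial(D))
      abort_it("pattern index out of range", "it_parameter_error")
    avail <- 0:(D - 1)
    p <- integer(D)
    for (i in seq_len(D - 1)) {
      f <- factorial(D - i)
      r <- ix %/% f
      ix <- ix %% f
      p[i] <- avail[r + 1L]
      avail <- avail[-(r + 1L)]
    }
    p[D] <- avail
    paste(p, collapse = ".")
  }, character(1))
}

#' Ordinal (permutation) entropy
#'
#' Shannon entropy of the ordinal-pattern distribution of a real-valued
#' series; bounded by `log(factorial(D))`.  Because patterns only encode
#' relative order, the value is exactly invariant under positive affine
#' rescaling of the series.
#'
#' @inheritParams symbolize
#' @param base Logarithm base override (see [resolve_base()]).
#' @return An [measure_result()] object.
#' @export
ordinal_entropy <- function(series, D = 3, delay = 1, base = NULL) {
  syms <- symbolize(series, D = D, delay = delay)
  res <- shannon_entropy(syms, base = base)
  res$estimator <- "ordinal"
  res$parameters <- list(D = D, delay = delay)
  res
}
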