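# Shared configuration (logarithm base), result containers and unit
# conversion used by every estimator.

.it_base_table <- list(bits = 2, nats = exp(1), hartleys = 10)

# Classed error helper: every condition also carries class "infodyn_error".
abort_it <- function(message, class) {
  stop(errorCondition(message, class = c(class, "infodyn_error"),
                      call = sys.call(-1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG seed; NULL seed means "use the
# current RNG stream" so callers can wrap whole experiments in one seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

#' Resolve a logarithm base specification
#'
#' Accepts `2`, `exp(1)`, `10` or the unit names `"bits"`, `"nats"`,
#' `"hartleys"` (and the shorthands `"e"`, `"2"`, `"10"`).  `NULL` falls
#' back to the process-wide default set with [it_options()], which starts
#' as bits.
#'
#' @param base Base specification, or `NULL` for the global default.
#' @return The numeric base (2, e or 10).
#' @examples
#' resolve_base("nats")
#' resolve_base(NULL)  # global default: 2
#' @export
resolve_base <- function(base = NULL) {
  if (is.null(base)) base <- getOption("infodyn.base", "bits")
  if (is.character(base) && length(base) == 1) {
    key <- c(bits = "bits", nats = "nats", hartleys = "hartleys",
             e = "nats", "2" = "bits", "10" = "hartleys")[tolower(base)]
    if (!is.na(key)) return(.it_base_table[[key]])
  } else if (is.numeric(base) && length(base) == 1 && is.finite(base)) {
    for (b in .it_base_table) if (abs(base - b) < 1e-12) return(b)
  }
  abort_it(paste0("invalid logarithm base '", paste(format(base), collapse = ","),
                  "': use 2 (bits), exp(1) (nats) or 10 (hartleys)"),
           "it_config_error")
}

# Unit label for a base spec.
unit_label <- function(base = NULL) {
  b <- resolve_base(base)
  if (abs(b - 2) < 1e-12) "bits" else if (abs(b - 10) < 1e-12) "hartleys" else "nats"
}

# Convert a value measured in nats into the requested base.
from_nats <- function(x, base = NULL) x / log(resolve_base(base))

#' Get or set the global logarithm base
#'
#' The package keeps one process-wide default unit for all measures
#' (initially bits).  Every estimator accepts a `base` argument that
#' overrides the global default for that call only, without mutating it.
#'
#' @param base New default base (see [resolve_base()] for accepted
#'   values).  Omit to query the current setting.
#' @return When querying, a list with the current `base`; when setting,
#'   the previous option value, invisibly.
#' @examples
#' it_options()            # query
#' old <- it_options("nats")
#' options(old)            # restore
#' @export
it_options <- function(base) {
  if (missing(base)) {
    return(list(base = getOption("infodyn.base", "bits")))
  }
  resolve_base(base)  # validate before committing
  invisible(options(infodyn.base = base))
}

#' Convert an information value between logarithm bases
#'
#' @param value Numeric value(s) measured in `from` units.
#' @param from,to Base specifications (see [resolve_base()]).
#' @return `value` re-expressed in `to` units; the round trip is the
#'   identity.
#' @examples
#' convert_units(1, "bits", "nats")      # log(2) = 0.6931...
#' convert_units(2, "bits", "hartleys")  # 2 * log10(2) = 0.6021...
#' @export
convert_units <- function(value, from, to) {
  value * log(resolve_base(from)) / log(resolve_base(to))
}

#' Construct a measure result
#'
#' Container returned by every estimator: the global value, optional
#' local (pointwise) values whose mean reproduces the global value, the
#' number of aligned observations actually used, the estimator name, its
#' parameters, and the units.
#'
#' @param value Global measure value.
#' @param n_samples Number of observations used (post-embedding).
#' @param estimator Estimator name.
#' @param units Unit string (`"bits"`, `"nats"`, `"hartleys"`).
#' @param local_values Optional numeric vector of pointwise values.
#' @param parameters Named list of estimator parameters.
#' @return An object of class `it_result`.
#' @export
measure_result <- function(value, n_samples, estimator, units,
                           local_values = NULL, parameters = list()) {
  structure(list(value = value,
                 local_values = local_values,
                 n_samples = as.integer(n_samples),
                 estimator = estimator,
                 parameters = parameters,
                 units = units),
            class = "it_result")
}

#' @export
print.it_result <- function(x, ...) {
  cat(sprintf("<%s> %.6g %s  (n = %d)\n",
              x$estimator, x$value, x$units, x$n_samples))
  if (length(x$parameters)) {
    p <- vapply(x$parameters, function(v) paste(format(v), collapse = ","),
                character(1))
    cat("  parameters:", paste(names(p), p, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$local_values)) {
    cat(sprintf("  local values: n = %d, mean = %.6g\n",
                length(x$local_values), mean(x$local_values)))
  }
  invisible(x)
}

#' @export
as.double.it_result <- function(x, ...) x$value
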