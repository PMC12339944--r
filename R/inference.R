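# Permutation/surrogate hypothesis testing, effective transfer entropy
# and moving-block bootstrap confidence intervals.
#
# Surrogates permute the source variable only: for MI/cMI the source
# observations, for TE/cTE whole sliced source-history rows, so the
# target's self-prediction structure stays untouched while the coupling
# is destroyed and the permuted block's marginal distribution is
# preserved exactly.

# Build aligned blocks for any supported measure.
prepare_measure_blocks <- function(x, y, z, measure, approach,
                                   k_hist, l_hist, tau, u, a) {
  if (measure %in% c("te", "cte")) {
    cond <- if (measure == "cte") z else NULL
    if (measure == "cte" && is.null(cond))
      abort_it("conditional TE requires `z`", "it_parameter_error")
    pb <- prepare_te_blocks(x, y, cond, approach, k_hist, l_hist, tau, u, a)
    return(pb)
  }
  check_approach(approach)
  inner <- approach
  if (approach == "ordinal") {
    D <- a$D %||% 3; delay <- a$delay %||% 1
    x <- symbolize(x, D, delay); y <- symbolize(y, D, delay)
    if (!is.null(z)) z <- symbolize(z, D, delay)
    inner <- "discrete"
  }
  if (measure == "cmi" && is.null(z))
    abort_it("conditional MI requires `z`", "it_parameter_error")
  list(xb = as_cols(x, "x"), yb = as_cols(y, "y"),
       zb = if (measure == "cmi") as_cols(z, "z"), inner = inner, a = a)
}

permute_cols <- function(cols, idx) lapply(cols, function(v) v[idx])

#' Permutation test for mutual information or transfer entropy
#'
#' Builds a null distribution by permuting the source variable (MI/cMI)
#' or whole sliced source-history rows (TE/cTE) `n_perm` times and
#' recomputing the measure, then reports the add-one p-value
#' \eqn{p = (1 + \#\{null \ge observed\})/(1 + n_{perm})} and the
#' t-score \eqn{(observed - \mathrm{mean}(null))/\mathrm{sd}(null)}
#' (sample standard deviation; `NA` with a note when the null is
#' degenerate).
#'
#' @param x,y Source and second variable (target series for TE).
#' @param z Conditioning series for `measure = "cmi"` / `"cte"`.
#' @param measure One of `"mi"`, `"cmi"`, `"te"`, `"cte"`.
#' @param approach Estimator family (see [entropy()]).
#' @param n_perm Number of permutation surrogates (>= 1).
#' @param seed Optional integer seed making the test reproducible.
#' @param base Logarithm base override.
#' @inheritParams transfer_entropy
#' @param ... Family parameters forwarded to the estimator.
#' @return An `it_test` list: `p_value`, `t_score`, `observed`,
#'   `null_values`, `measure`, `n_perm`, `seed`.
#' @export
permutation_test <- function(x, y, z = NULL,
                             measure = c("mi", "te", "cmi", "cte"),
                             approach = "discrete", n_perm = 200, seed = NULL,
                             k_hist = 1, l_hist = 1, tau = 1, u = 1,
                             base = NULL, ...) {
  measure <- match.arg(measure)
  if (!is.numeric(n_perm) || n_perm < 1)
    abort_it("`n_perm` must be >= 1", "it_parameter_error")
  pb <- prepare_measure_blocks(x, y, z, measure, approach,
                               k_hist, l_hist, tau, u, list(...))
  obs <- cmi_blocks(pb$xb, pb$yb, pb$zb, pb$inner, base, pb$a)$value
  nr <- length(pb$xb[[1]])
  null_values <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nr)
    cmi_blocks(permute_cols(pb$xb, idx), pb$yb, pb$zb, pb$inner, base, pb$a)$value
  }, numeric(1)))
  p <- (1 + sum(null_values >= obs)) / (1 + n_perm)
  s <- stats::sd(null_values)
  t <- if (is.finite(s) && s > 0) (obs - mean(null_values)) / s else NA_real_
  structure(list(p_value = p, t_score = t, observed = obs,
                 null_values = null_values, measure = measure,
                 approach = approach, n_perm = as.integer(n_perm),
                 seed = seed,
                 note = if (is.na(t)) "degenerate null: sd = 0, t undefined"),
            class = "it_test")
}

#' @export
print.it_test <- function(x, ...) {
  cat(sprintf("<permutation test: %s/%s> observed = %.6g, p = %.4g, t = %.4g (n_perm = %d)\n",
              x$measure, x$approach, x$observed, x$p_value, x$t_score, x$n_perm))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Effective transfer entropy
#'
#' \eqn{eTE = TE_{X \to Y} - \overline{TE_{\mathrm{shuffled}\,X \to Y}}},
#' the observed transfer entropy minus the mean over source-row shuffles,
#' which removes the finite-sample estimation bias shared by observed and
#' surrogate estimates.
#'
#' @inheritParams transfer_entropy
#' @param n_shuffles Number of source shuffles averaged (>= 1).
#' @param seed Optional seed for the shuffles.
#' @return An [measure_result()] object (no local values).
#' @export
effective_te <- function(source, target, approach = "discrete",
                         k_hist = 1, l_hist = 1, tau = 1, u = 1,
                         n_shuffles = 10, seed = NULL, base = NULL, ...) {
  if (!is.numeric(n_shuffles) || n_shuffles < 1)
    abort_it("`n_shuffles` must be >= 1", "it_parameter_error")
  pb <- prepare_te_blocks(source, target, NULL, approach,
                          k_hist, l_hist, tau, u, list(...))
  obs <- cmi_blocks(pb$xb, pb$yb, pb$zb, pb$inner, base, pb$a)
  nr <- length(pb$xb[[1]])
  surr <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    idx <- sample.int(nr)
    cmi_blocks(permute_cols(pb$xb, idx), pb$yb, pb$zb, pb$inner, base, pb$a)$value
  }, numeric(1)))
  measure_result(obs$value - mean(surr), nr,
                 paste0("effective_", approach, "_te"), obs$units,
                 parameters = c(list(n_shuffles = as.integer(n_shuffles),
                                     k_hist = k_hist, l_hist = l_hist,
                                     tau = tau, u = u), list(...)))
}

#' Moving-block bootstrap confidence interval for MI or TE
#'
#' Resamples the aligned observation rows in contiguous blocks of length
#' `block_len` (preserving serial dependence inside blocks), recomputes
#' the measure `n_boot` times and reports the percentile interval.
#'
#' @inheritParams permutation_test
#' @param level Coverage level in (0, 1).
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param block_len Block length; default `ceiling(n^(1/3))` rows.
#' @return An `it_ci` list: `lower`, `upper`, `level`, `observed`,
#'   `values`.
#' @export
bootstrap_ci <- function(x, y, z = NULL, measure = c("mi", "te", "cmi", "cte"),
                         approach = "discrete", level = 0.95, n_boot = 199,
                         block_len = NULL, seed = NULL,
                         k_hist = 1, l_hist = 1, tau = 1, u = 1,
                         base = NULL, ...) {
  measure <- match.arg(measure)
  if (!is.numeric(level) || level <= 0 || level >= 1)
    abort_it("`level` must lie strictly between 0 and 1", "it_parameter_error")
  if (!is.numeric(n_boot) || n_boot < 2)
    abort_it("`n_boot` must be >= 2", "it_parameter_error")
  pb <- prepare_measure_blocks(x, y, z, measure, approach,
                               k_hist, l_hist, tau, u, list(...))
  nr <- length(pb$xb[[1]])
  b <- if (is.null(block_len)) ceiling(nr^(1 / 3)) else block_len
  if (!is.numeric(b) || b < 1 || b > nr)
    abort_it(sprintf("`block_len` must lie in [1, %d]", nr), "it_parameter_error")
  obs <- cmi_blocks(pb$xb, pb$yb, pb$zb, pb$inner, base, pb$a)$value
  resample_rows <- function() {
    starts <- sample.int(nr - b + 1, ceiling(nr / b), replace = TRUE)
    idx <- as.vector(vapply(starts, function(s) s:(s + b - 1), numeric(b)))
    idx[seq_len(nr)]
  }
  vals <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- resample_rows()
    cmi_blocks(permute_cols(pb$xb, idx), permute_cols(pb$yb, idx),
               if (!is.null(pb$zb)) permute_cols(pb$zb, idx),
               pb$inner, base, pb$a)$value
  }, numeric(1)))
  qs <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(lower = qs[1], upper = qs[2], level = level,
                 observed = obs, values = vals,
                 block_len = as.integer(b), seed = seed),
            class = "it_ci")
}

#' @export
print.it_ci <- function(x, ...) {
  cat(sprintf("<bootstrap CI> %.0f%%: [%.6g, %.6g], observed = %.6g (block = %d)\n",
              100 * x$level, x$lower, x$upper, x$observed, x$block_len))
  invisible(x)
}
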