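# Kernel-density estimation of differential entropy and of the local
# density log-ratios behind kernel MI / cMI / TE.
#
# Conventions: the box kernel counts neighbours in a max-norm radius h/2
# (hypercube of side h) on the raw data, so a lone point in 1-D has
# density 1/h.  The Gaussian kernel is a product kernel with one shared
# bandwidth applied after standardizing every axis to unit variance;
# log-scale terms are added back so densities refer to the original
# units.  Densities are leave-self-in, which keeps box-kernel entropies
# finite at duplicated points at the cost of a small negative bias.

as_num_matrix <- function(x, arg = "samples") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (!is.numeric(x))
    abort_it(paste0("`", arg, "` must be numeric"), "it_value_error")
  if (nrow(x) == 0)
    abort_it(paste0("`", arg, "` is empty"), "it_empty_input_error")
  if (anyNA(x))
    abort_it(paste0("`", arg, "` contains missing values"), "it_value_error")
  storage.mode(x) <- "double"
  x
}

# Silverman's rule for unit-variance data in d dimensions.
silverman_bw <- function(n, d) (4 / ((d + 2) * n))^(1 / (d + 4))

check_bandwidth <- function(bandwidth) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 || bandwidth <= 0 ||
      !is.finite(bandwidth))
    abort_it("`bandwidth` must be a positive real", "it_parameter_error")
  bandwidth
}

#' Kernel density estimates at arbitrary points
#'
#' Leave-self-in KDE with a box or Gaussian kernel, max-norm box of side
#' `bandwidth` or product Gaussian with per-axis scale `bandwidth`.  This
#' low-level routine works in raw data units (no standardization).
#'
#' @param samples Numeric matrix (n x d) or vector of sample points.
#' @param eval_points Numeric matrix (m x d) or vector of evaluation
#'   points; must match the dimensionality of `samples`.
#' @param kernel `"box"` or `"gaussian"`.
#' @param bandwidth Positive bandwidth in data units.
#' @return Numeric vector of m nonnegative densities.
#' @examples
#' kde_at_points(0, 0, kernel = "box", bandwidth = 0.5)       # 1/h = 2
#' kde_at_points(0, 0, kernel = "gaussian", bandwidth = 0.5)  # 1/(h sqrt(2 pi))
#' @export
kde_at_points <- function(samples, eval_points, kernel = c("box", "gaussian"),
                          bandwidth) {
  kernel <- match.arg(kernel)
  X <- as_num_matrix(samples)
  Q <- as_num_matrix(eval_points, "eval_points")
  if (ncol(X) != ncol(Q))
    abort_it(sprintf("dimension mismatch: samples have %d columns, eval_points %d",
                     ncol(X), ncol(Q)), "it_shape_error")
  h <- check_bandwidth(bandwidth)
  n <- nrow(X); d <- ncol(X)
  if (kernel == "box") {
    range_count_cheb(X, Q, h / 2, FALSE) / (n * h^d)
  } else {
    gauss_kde_cpp(X, Q, h)
  }
}

# Standardize columns to zero mean / unit variance; returns Z and log|sd|.
standardize_cols <- function(X) {
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds)))
    abort_it(paste0("degenerate density: axis ",
                    paste(which(sds == 0 | !is.finite(sds)), collapse = ", "),
                    " is constant; standardization is impossible"),
             "it_degenerate_density_error")
  Z <- sweep(sweep(X, 2, colMeans(X), "-"), 2, sds, "/")
  list(Z = Z, log_sds = log(sds))
}

# Default box bandwidth on raw data: Silverman factor times the mean
# per-axis standard deviation.
default_box_bw <- function(X) {
  silverman_bw(nrow(X), ncol(X)) * mean(apply(X, 2, stats::sd))
}

#' Kernel estimate of differential entropy
#'
#' \eqn{\hat H = -\frac1n \sum_i \log \hat p(x_i)} with \eqn{\hat p} the
#' leave-self-in KDE.  Local values are the sample surprisals
#' \eqn{-\log \hat p(x_i)}.
#'
#' For the Gaussian kernel every axis is standardized to unit variance
#' and `bandwidth` is interpreted on that standardized scale (default:
#' Silverman's rule); the entropy is still reported for the original
#' data.  For the box kernel `bandwidth` is in raw data units (default:
#' Silverman's factor times the mean axis standard deviation).
#'
#' @param samples Numeric vector or n x d matrix, n >= 2.
#' @inheritParams kde_at_points
#' @param base Logarithm base override (see [resolve_base()]).
#' @return An [measure_result()] object (differential entropy; may be
#'   negative).
#' @export
kernel_entropy <- function(samples, kernel = c("box", "gaussian"),
                           bandwidth = NULL, base = NULL) {
  kernel <- match.arg(kernel)
  X <- as_num_matrix(samples)
  n <- nrow(X); d <- ncol(X)
  if (n < 2)
    abort_it("kernel entropy needs at least 2 samples", "it_empty_input_error")
  if (kernel == "gaussian") {
    std <- standardize_cols(X)
    h <- if (is.null(bandwidth)) silverman_bw(n, d) else check_bandwidth(bandwidth)
    dens <- gauss_kde_cpp(std$Z, std$Z, h)
    local_nats <- -log(dens) + sum(std$log_sds)
  } else {
    h <- if (is.null(bandwidth)) default_box_bw(X) else check_bandwidth(bandwidth)
    dens <- range_count_cheb(X, X, h / 2, FALSE) / (n * h^d)
    if (any(dens <= 0))
      abort_it(paste0("degenerate density at sample index ",
                      which(dens <= 0)[1]), "it_degenerate_density_error")
    local_nats <- -log(dens)
  }
  local <- from_nats(local_nats, base)
  measure_result(mean(local), n, paste0("kernel_", kernel), unit_label(base),
                 local_values = local,
                 parameters = list(kernel = kernel, bandwidth = h))
}

#' Per-block kernel log-densities for density-ratio measures
#'
#' Evaluates the leave-self-in KDE log-density of each requested variable
#' block (subset of columns) at every sample, with one shared bandwidth,
#' so that callers can assemble local MI / cMI / TE terms as sums and
#' differences of columns.  With the Gaussian kernel all axes are
#' standardized once and per-block scale terms are added back, so the
#' scale corrections cancel exactly in any balanced ratio.
#'
#' @param data Numeric matrix (n x d) holding all variables side by side.
#' @param blocks Named list of integer column-index vectors, e.g.
#'   `list(xy = 1:2, x = 1, y = 2)`.
#' @inheritParams kernel_entropy
#' @return n x length(blocks) matrix of log-densities (natural log),
#'   with `names(blocks)` as column names.
#' @export
kernel_log_densities <- function(data, blocks, kernel = c("box", "gaussian"),
                                 bandwidth = NULL) {
  kernel <- match.arg(kernel)
  X <- as_num_matrix(data, "data")
  n <- nrow(X); d <- ncol(X)
  if (!is.list(blocks) || is.null(names(blocks)) || any(names(blocks) == ""))
    abort_it("`blocks` must be a named list of column indices", "it_parameter_error")
  idx_ok <- vapply(blocks, function(b) all(b %in% seq_len(d)), logical(1))
  if (!all(idx_ok))
    abort_it("`blocks` contains column indices outside the data", "it_shape_error")
  out <- matrix(NA_real_, n, length(blocks),
                dimnames = list(NULL, names(blocks)))
  if (kernel == "gaussian") {
    std <- standardize_cols(X)
    h <- if (is.null(bandwidth)) silverman_bw(n, d) else check_bandwidth(bandwidth)
    for (j in seq_along(blocks)) {
      b <- blocks[[j]]
      Z <- std$Z[, b, drop = FALSE]
      out[, j] <- log(gauss_kde_cpp(Z, Z, h)) - sum(std$log_sds[b])
    }
  } else {
    h <- if (is.null(bandwidth)) default_box_bw(X) else check_bandwidth(bandwidth)
    for (j in seq_along(blocks)) {
      b <- blocks[[j]]
      Xb <- X[, b, drop = FALSE]
      dens <- range_count_cheb(Xb, Xb, h / 2, FALSE) / (n * h^length(b))
      out[, j] <- log(dens)
    }
  }
  attr(out, "bandwidth") <- h
  out
}
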