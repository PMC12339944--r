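# Nearest-neighbour (metric) estimators: Kozachenko-Leonenko differential
# entropy, Kraskov-Stoegbauer-Grassberger mutual information (algorithm 1),
# the Frenzel-Pompe conditional form, and the Leonenko-Pronzato-Savani
# generalisation to Renyi/Tsallis orders.  The Chebyshev (max-norm) metric
# is used everywhere, which makes all volume terms exact: the "ball" of
# radius eps is a cube of side 2 eps, so c_d = 1 in the entropy formula
# and V_d = 2^d in the generalized one.

#' Add uniform jitter to break ties and duplicate points
#'
#' Adds independent uniform noise in `[-amplitude/2, amplitude/2]` to
#' every entry.  `amplitude = 0` returns the input unchanged (bit for
#' bit).  Deterministic for a given `seed`.
#'
#' @param samples Numeric vector or matrix.
#' @param amplitude Nonnegative jitter width.
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @return Object of the same shape as `samples`.
#' @export
add_noise <- function(samples, amplitude, seed = NULL) {
  if (!is.numeric(amplitude) || length(amplitude) != 1 || amplitude < 0)
    abort_it("`amplitude` must be a nonnegative real", "it_parameter_error")
  if (amplitude == 0) return(samples)
  with_seed(seed, samples + (runif(length(samples)) - 0.5) * amplitude)
}

prep_metric <- function(X, k, noise, seed, what) {
  n <- nrow(X)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    abort_it("`k` must be a positive integer", "it_parameter_error")
  if (k >= n)
    abort_it(sprintf("`k` = %d requires more than %d samples", k, n),
             "it_parameter_error")
  if (noise > 0) X <- add_noise(X, noise, seed)
  eps <- knn_cheb_dist(X, as.integer(k))
  if (any(eps <= 0))
    abort_it(paste0("duplicate points give a zero k-th neighbour distance in ",
                    what, "; enable jitter via `noise` (e.g. 1e-10)"),
             "it_degenerate_distance_error")
  list(X = X, eps = eps, n = n)
}

#' Kozachenko-Leonenko differential entropy
#'
#' kNN estimate \eqn{\hat H = \psi(n) - \psi(k) + \frac{d}{n} \sum_i
#' \log(2\epsilon_i)} with \eqn{\epsilon_i} the max-norm distance from
#' sample i to its k-th neighbour (the max-norm unit-cube volume constant
#' is 1).  Local values are the per-sample terms.
#'
#' @param samples Numeric vector or n x d matrix.
#' @param k Neighbour order (default 4).
#' @param base Logarithm base override.
#' @param noise Jitter amplitude forwarded to [add_noise()]; required
#'   (> 0) when the data contain duplicate points.
#' @param seed Seed for the jitter.
#' @return An [measure_result()] object.
#' @export
kl_entropy <- function(samples, k = 4, base = NULL, noise = 0, seed = NULL) {
  X <- as_num_matrix(samples)
  pm <- prep_metric(X, k, noise, seed, "kl_entropy")
  d <- ncol(X)
  local_nats <- digamma(pm$n) - digamma(k) + d * log(2 * pm$eps)
  local <- from_nats(local_nats, base)
  measure_result(mean(local), pm$n, "metric_kl", unit_label(base),
                 local_values = local,
                 parameters = list(k = k, noise = noise))
}

#' Kraskov-Stoegbauer-Grassberger mutual information (algorithm 1)
#'
#' Joint-space k-th neighbour distances are projected into each marginal
#' subspace, where neighbours strictly within that distance are counted:
#' \eqn{\hat I = \psi(k) + \psi(n) - \langle \psi(n_x + 1) +
#' \psi(n_y + 1) \rangle}.  The estimate is returned unclipped (small
#' negative values are possible for independent data).
#'
#' @param x,y Numeric vectors or matrices with one row per observation;
#'   either side may be multivariate.
#' @inheritParams kl_entropy
#' @export
ksg_mi <- function(x, y, k = 4, base = NULL, noise = 0, seed = NULL) {
  X <- as_num_matrix(x, "x")
  Y <- as_num_matrix(y, "y")
  if (nrow(X) != nrow(Y))
    abort_it(sprintf("length mismatch: x has %d rows, y has %d", nrow(X), nrow(Y)),
             "it_shape_error")
  J <- cbind(X, Y)
  pm <- prep_metric(J, k, noise, seed, "ksg_mi")
  dx <- ncol(X)
  Xj <- pm$X[, seq_len(dx), drop = FALSE]
  Yj <- pm$X[, -seq_len(dx), drop = FALSE]
  nx <- count_within_cheb(Xj, pm$eps, TRUE)
  ny <- count_within_cheb(Yj, pm$eps, TRUE)
  local_nats <- digamma(k) + digamma(pm$n) - digamma(nx + 1) - digamma(ny + 1)
  local <- from_nats(local_nats, base)
  measure_result(mean(local), pm$n, "metric_ksg", unit_label(base),
                 local_values = local,
                 parameters = list(k = k, noise = noise))
}

#' KSG-style conditional mutual information (Frenzel-Pompe)
#'
#' \eqn{\hat I(X; Y \mid Z) = \psi(k) + \langle \psi(n_z + 1) -
#' \psi(n_{xz} + 1) - \psi(n_{yz} + 1) \rangle} with all neighbour counts
#' taken strictly within the joint-space k-th neighbour distance.
#'
#' @param x,y,z Numeric vectors or matrices with one row per observation.
#' @inheritParams kl_entropy
#' @export
ksg_cmi <- function(x, y, z, k = 4, base = NULL, noise = 0, seed = NULL) {
  X <- as_num_matrix(x, "x")
  Y <- as_num_matrix(y, "y")
  Z <- as_num_matrix(z, "z")
  if (nrow(X) != nrow(Y) || nrow(X) != nrow(Z))
    abort_it("x, y and z must have equal numbers of rows", "it_shape_error")
  J <- cbind(X, Y, Z)
  pm <- prep_metric(J, k, noise, seed, "ksg_cmi")
  dx <- ncol(X); dy <- ncol(Y)
  Xj <- pm$X[, seq_len(dx), drop = FALSE]
  Yj <- pm$X[, dx + seq_len(dy), drop = FALSE]
  Zj <- pm$X[, -(seq_len(dx + dy)), drop = FALSE]
  nz <- count_within_cheb(Zj, pm$eps, TRUE)
  nxz <- count_within_cheb(cbind(Xj, Zj), pm$eps, TRUE)
  nyz <- count_within_cheb(cbind(Yj, Zj), pm$eps, TRUE)
  local_nats <- digamma(k) + digamma(nz + 1) - digamma(nxz + 1) - digamma(nyz + 1)
  local <- from_nats(local_nats, base)
  measure_result(mean(local), pm$n, "metric_ksg_cmi", unit_label(base),
                 local_values = local,
                 parameters = list(k = k, noise = noise))
}

#' Generalized (Renyi/Tsallis) kNN differential entropy
#'
#' Leonenko-Pronzato-Savani estimator of \eqn{\int f^q}: with
#' \eqn{\zeta_i = (n-1)\, C_k\, (2\epsilon_i)^d} (max-norm volume) and
#' \eqn{C_k = [\Gamma(k)/\Gamma(k+1-q)]^{1/(1-q)}}, the moment estimate
#' is \eqn{\hat I_q = \frac1n \sum_i \zeta_i^{1-q}}; the Renyi entropy is
#' \eqn{\log(\hat I_q)/(1-q)} and the Tsallis entropy
#' \eqn{(1-\hat I_q)/(q-1)} (natural units).  `order = 1` aliases to the
#' Kozachenko-Leonenko Shannon estimate.
#'
#' @inheritParams kl_entropy
#' @param order Entropic order (alpha for Renyi, q for Tsallis);
#'   requires `order < k + 1`.
#' @param type `"renyi"` or `"tsallis"`.
#' @export
lps_entropy <- function(samples, order, k = 4, type = c("renyi", "tsallis"),
                        base = NULL, noise = 0, seed = NULL) {
  type <- match.arg(type)
  if (!is.numeric(order) || length(order) != 1 || order <= 0)
    abort_it("`order` must be a positive real", "it_parameter_error")
  if (abs(order - 1) < 1e-12) {
    res <- kl_entropy(samples, k = k,
                      base = if (type == "tsallis") "nats" else base,
                      noise = noise, seed = seed)
    res$estimator <- paste0("metric_", type)
    res$parameters$order <- order
    return(res)
  }
  if (order >= k + 1)
    abort_it("`order` must be below k + 1 for the kNN generalized entropy",
             "it_parameter_error")
  X <- as_num_matrix(samples)
  pm <- prep_metric(X, k, noise, seed, "lps_entropy")
  d <- ncol(X)
  log_Ck <- (lgamma(k) - lgamma(k + 1 - order)) / (1 - order)
  log_zeta <- log(pm$n - 1) + log_Ck + d * log(2 * pm$eps)
  I_hat <- mean(exp((1 - order) * log_zeta))
  if (type == "renyi") {
    H <- log(I_hat) / (1 - order)
    measure_result(from_nats(H, base), pm$n, "metric_renyi", unit_label(base),
                   parameters = list(order = order, k = k, noise = noise))
  } else {
    H <- (1 - I_hat) / (order - 1)
    measure_result(H, pm$n, "metric_tsallis", "nats",
                   parameters = list(order = order, k = k, noise = noise))
  }
}
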