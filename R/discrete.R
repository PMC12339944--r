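# Plug-in (maximum-likelihood) and bias-corrected estimation of all
# measures on categorical data; the computational kernel that the ordinal
# module reuses.  The convention 0 * log 0 = 0 holds throughout: symbols
# with zero count are simply absent from estimated supports.

check_nonempty <- function(x, arg = "samples") {
  if (length(x) == 0)
    abort_it(paste0("`", arg, "` is empty: at least one observation is required"),
             "it_empty_input_error")
  if (anyNA(x))
    abort_it(paste0("`", arg, "` contains missing values"), "it_value_error")
  invisible(x)
}

# Normalise tuple-style input (vector, matrix rows, data.frame rows, or
# list of parallel vectors) to a list of equal-length atomic columns.
as_cols <- function(data, arg = "samples") {
  cols <- if (is.matrix(data)) {
    lapply(seq_len(ncol(data)), function(j) data[, j])
  } else if (is.data.frame(data)) {
    as.list(data)
  } else if (is.list(data)) {
    data
  } else {
    list(data)
  }
  cols <- lapply(cols, function(v) if (is.factor(v)) as.character(v) else v)
  lens <- lengths(cols)
  if (length(unique(lens)) != 1)
    abort_it(paste0("`", arg, "` is ragged: components have lengths ",
                    paste(lens, collapse = ", ")), "it_shape_error")
  check_nonempty(cols[[1]], arg)
  for (v in cols) check_nonempty(v, arg)
  cols
}

# Dense integer codes (1..K) for joint symbols across columns.  Uses
# double arithmetic for the mixed-radix combination, exact below 2^53.
encode_tuples <- function(cols) {
  code <- as.double(match(cols[[1]], unique(cols[[1]])))
  if (length(cols) > 1) {
    for (j in 2:length(cols)) {
      cj <- as.double(match(cols[[j]], unique(cols[[j]])))
      code <- code * (max(cj) + 1) + cj
    }
    code <- match(code, unique(code))
  }
  as.integer(code)
}

# Plug-in entropy in nats from integer codes; optionally local surprisals.
entropy_nats_codes <- function(codes, local = FALSE) {
  counts <- tabulate(codes)
  n <- length(codes)
  H <- log(n) - sum(counts[counts > 0] * log(counts[counts > 0])) / n
  if (!local) return(list(value = H, n = n))
  list(value = H, n = n, local = -log(counts[codes] / n))
}

#' Estimate a probability mass function from samples
#'
#' Relative-frequency (maximum likelihood) estimate over the observed
#' symbols.  Symbols never observed are absent, so all probabilities are
#' strictly positive and sum to one.
#'
#' @param samples Atomic vector (or factor) of symbols.
#' @return An object of class `it_pmf`: list with `support`, `counts`,
#'   `probs` and the total count `n`.
#' @examples
#' estimate_pmf(c("a", "a", "b", "b"))
#' @export
estimate_pmf <- function(samples) {
  check_nonempty(samples)
  if (is.factor(samples)) samples <- as.character(samples)
  support <- unique(samples)
  counts <- tabulate(match(samples, support), nbins = length(support))
  structure(list(support = support, counts = counts,
                 probs = counts / length(samples), n = length(samples)),
            class = "it_pmf")
}

#' @export
print.it_pmf <- function(x, ...) {
  cat(sprintf("<pmf> %d symbols over n = %d observations\n",
              length(x$support), x$n))
  print(stats::setNames(round(x$probs, 4), format(x$support)))
  invisible(x)
}

#' Joint probability mass function over fixed-arity tuples
#'
#' @param data Tuple sequence: matrix/data.frame with one row per
#'   observation, or a list of equal-length vectors (one per axis).
#' @return An `it_joint_pmf`: support stored per axis plus counts,
#'   probabilities and `arity`.
#' @seealso [marginal_pmf()] for the count-exact marginalisation.
#' @export
joint_pmf <- function(data) {
  cols <- as_cols(data)
  if (length(cols) < 2)
    abort_it("a joint pmf needs tuples of arity >= 2", "it_shape_error")
  key <- do.call(paste, c(cols, sep = "\x1f"))
  first <- !duplicated(key)
  counts <- tabulate(match(key, key[first]), nbins = sum(first))
  structure(list(support = lapply(cols, function(v) v[first]),
                 counts = counts, probs = counts / length(key),
                 n = length(key), arity = length(cols)),
            class = c("it_joint_pmf", "it_pmf"))
}

#' Marginal of a joint pmf along one axis
#'
#' Count-level marginalisation: the marginal counts reproduce exactly the
#' counts [estimate_pmf()] would return for that component.
#'
#' @param jpmf An `it_joint_pmf`.
#' @param axis Axis index (1-based).
#' @return An `it_pmf` for the chosen component.
#' @export
marginal_pmf <- function(jpmf, axis) {
  if (!inherits(jpmf, "it_joint_pmf"))
    abort_it("`jpmf` must be an it_joint_pmf", "it_value_error")
  if (axis < 1 || axis > jpmf$arity)
    abort_it("`axis` out of range", "it_parameter_error")
  sym <- jpmf$support[[axis]]
  support <- unique(sym)
  counts <- vapply(support,
                   function(s) sum(jpmf$counts[sym == s]), numeric(1))
  counts <- as.integer(counts)
  structure(list(support = support, counts = counts,
                 probs = counts / jpmf$n, n = jpmf$n),
            class = "it_pmf")
}

#' Shannon entropy (discrete plug-in)
#'
#' \eqn{H(X) = -\sum_x p(x) \log p(x)} over the empirical distribution.
#' Local values are the surprisals \eqn{-\log p(x_i)}, whose mean equals
#' the global value exactly.
#'
#' @param samples Symbol vector, or tuples (matrix/data.frame/list) whose
#'   rows are treated jointly.
#' @param base Logarithm base override (see [resolve_base()]).
#' @return An [measure_result()] object.
#' @examples
#' shannon_entropy(rep(0:1, each = 50))$value  # 1 bit
#' @export
shannon_entropy <- function(samples, base = NULL) {
  cols <- as_cols(samples)
  e <- entropy_nats_codes(encode_tuples(cols), local = TRUE)
  measure_result(from_nats(e$value, base), e$n, "discrete",
                 unit_label(base), local_values = from_nats(e$local, base))
}

#' Renyi entropy (discrete plug-in)
#'
#' \eqn{H_\alpha = \frac{1}{1-\alpha}\log \sum_x p(x)^\alpha}.  The limit
#' \eqn{\alpha = 1} is treated as an alias for Shannon entropy.
#'
#' @inheritParams shannon_entropy
#' @param alpha Order, positive; `alpha = 1` falls back to Shannon.
#' @export
renyi_entropy <- function(samples, alpha = 2, base = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    abort_it("`alpha` must be a positive real", "it_parameter_error")
  if (abs(alpha - 1) < 1e-12) {
    res <- shannon_entropy(samples, base)
    res$parameters <- list(alpha = alpha)
    res$estimator <- "renyi"
    return(res)
  }
  cols <- as_cols(samples)
  codes <- encode_tuples(cols)
  p <- tabulate(codes) / length(codes)
  p <- p[p > 0]
  H <- log(sum(p^alpha)) / (1 - alpha)
  measure_result(from_nats(H, base), length(codes), "renyi",
                 unit_label(base), parameters = list(alpha = alpha))
}

#' Tsallis entropy (discrete plug-in)
#'
#' \eqn{S_q = (1 - \sum_x p(x)^q)/(q - 1)}, reported in natural units:
#' the q-logarithm has no base freedom, so `base` is not accepted here.
#' The limit `q = 1` aliases to Shannon entropy in nats.  Local values
#' are the q-surprisals \eqn{(1 - p(x_i)^{q-1})/(q-1)}.
#'
#' @inheritParams shannon_entropy
#' @param q Entropic index, positive; `q = 1` falls back to Shannon.
#' @export
tsallis_entropy <- function(samples, q = 2) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0)
    abort_it("`q` must be a positive real", "it_parameter_error")
  if (abs(q - 1) < 1e-12) {
    res <- shannon_entropy(samples, base = "nats")
    res$parameters <- list(q = q)
    res$estimator <- "tsallis"
    return(res)
  }
  cols <- as_cols(samples)
  codes <- encode_tuples(cols)
  counts <- tabulate(codes)
  p <- counts / length(codes)
  local <- (1 - p[codes]^(q - 1)) / (q - 1)
  value <- (1 - sum(p[p > 0]^q)) / (q - 1)
  measure_result(value, length(codes), "tsallis", "nats",
                 local_values = local, parameters = list(q = q))
}

#' Joint Shannon entropy of tuples
#'
#' Shannon entropy of the joint empirical distribution of fixed-arity
#' tuples: \eqn{H(X, Y, \ldots)}.
#'
#' @param data Matrix/data.frame with one row per observation, or a list
#'   of equal-length vectors (ragged lists raise a shape error).
#' @inheritParams shannon_entropy
#' @export
joint_entropy <- function(data, base = NULL) {
  cols <- as_cols(data, arg = "data")
  res <- shannon_entropy(cols, base)
  res$estimator <- "discrete_joint"
  res
}

#' Cross-entropy between two sample sets
#'
#' \eqn{H_Q(P) = -\sum_x p(x) \log q(x)} with \eqn{P} and \eqn{Q}
#' estimated from two independent sample sets.  Defined only when every
#' symbol of \eqn{P}'s support also occurs in \eqn{Q}'s; otherwise the
#' cross-entropy is infinite and a divergence-undefined error is raised.
#'
#' @param samples_p,samples_q Symbol vectors for \eqn{P} and \eqn{Q}.
#' @inheritParams shannon_entropy
#' @export
cross_entropy <- function(samples_p, samples_q, base = NULL) {
  check_nonempty(samples_p, "samples_p")
  check_nonempty(samples_q, "samples_q")
  pm <- estimate_pmf(samples_p)
  qm <- estimate_pmf(samples_q)
  missing <- setdiff(pm$support, qm$support)
  if (length(missing) > 0)
    abort_it(paste0("cross-entropy is infinite: symbols {",
                    paste(format(missing), collapse = ", "),
                    "} of P never occur in Q"),
             "it_divergence_undefined_error")
  if (is.factor(samples_p)) samples_p <- as.character(samples_p)
  qp <- qm$probs[match(samples_p, qm$support)]
  local <- from_nats(-log(qp), base)
  measure_result(mean(local), pm$n, "discrete_cross", unit_label(base),
                 local_values = local)
}

#' Kullback-Leibler divergence between two sample sets
#'
#' \eqn{\mathrm{KLD}(P \| Q) = \sum_x p(x) \log(p(x)/q(x)) \ge 0}; equals
#' `cross_entropy(P, Q) - entropy(P)` exactly.  Requires
#' \eqn{\mathrm{supp}(P) \subseteq \mathrm{supp}(Q)}.
#'
#' A bias-corrected variant is available through `method`: the entropy
#' component \eqn{H(P)} is replaced by its Miller-Madow or Grassberger
#' correction (the remaining corrected families are not defined for
#' divergences and raise an unsupported-combination error).
#'
#' @inheritParams cross_entropy
#' @param method Optional bias correction: `"miller_madow"` or
#'   `"grassberger"`.
#' @export
kl_divergence <- function(samples_p, samples_q, base = NULL, method = NULL) {
  if (!is.null(method)) {
    if (!method %in% c("miller_madow", "grassberger"))
      abort_it(paste0("bias-corrected divergences support only miller_madow ",
                      "and grassberger, not '", method, "'"),
               "it_unsupported_combination_error")
    ce <- cross_entropy(samples_p, samples_q, base = base)
    Hc <- bias_corrected_entropy(samples_p, method = method, base = base)
    return(measure_result(ce$value - Hc$value, ce$n_samples,
                          paste0("discrete_kld_", method), unit_label(base),
                          parameters = list(method = method)))
  }
  check_nonempty(samples_p, "samples_p")
  check_nonempty(samples_q, "samples_q")
  pm <- estimate_pmf(samples_p)
  qm <- estimate_pmf(samples_q)
  missing <- setdiff(pm$support, qm$support)
  if (length(missing) > 0)
    abort_it(paste0("KL divergence is undefined: symbols {",
                    paste(format(missing), collapse = ", "),
                    "} of P never occur in Q"),
             "it_divergence_undefined_error")
  if (is.factor(samples_p)) samples_p <- as.character(samples_p)
  pp <- pm$probs[match(samples_p, pm$support)]
  qp <- qm$probs[match(samples_p, qm$support)]
  local <- from_nats(log(pp / qp), base)
  measure_result(mean(local), pm$n, "discrete_kld", unit_label(base),
                 local_values = local)
}

#' Jensen-Shannon divergence between two sample sets
#'
#' \eqn{\mathrm{JSD} = H(M) - \tfrac12 H(P) - \tfrac12 H(Q)} with
#' \eqn{M = (P + Q)/2} the equal-weight mixture of the two estimated
#' distributions.  Symmetric in its arguments and bounded by 1 bit.
#'
#' A bias-corrected variant (`method = "miller_madow"` or
#' `"grassberger"`) corrects each entropy term, using the pooled counts
#' of both sample sets for the mixture (exactly the equal-weight mixture
#' when the two sets have equal size); other corrections raise an
#' unsupported-combination error.
#'
#' @inheritParams kl_divergence
#' @export
js_divergence <- function(samples_p, samples_q, base = NULL, method = NULL) {
  check_nonempty(samples_p, "samples_p")
  check_nonempty(samples_q, "samples_q")
  if (!is.null(method)) {
    if (!method %in% c("miller_madow", "grassberger"))
      abort_it(paste0("bias-corrected divergences support only miller_madow ",
                      "and grassberger, not '", method, "'"),
               "it_unsupported_combination_error")
    if (is.factor(samples_p)) samples_p <- as.character(samples_p)
    if (is.factor(samples_q)) samples_q <- as.character(samples_q)
    Hm <- bias_corrected_entropy(c(samples_p, samples_q), method = method,
                                 base = base)
    Hp <- bias_corrected_entropy(samples_p, method = method, base = base)
    Hq <- bias_corrected_entropy(samples_q, method = method, base = base)
    return(measure_result(Hm$value - (Hp$value + Hq$value) / 2,
                          length(samples_p) + length(samples_q),
                          paste0("discrete_jsd_", method), unit_label(base),
                          parameters = list(method = method)))
  }
  pm <- estimate_pmf(samples_p)
  qm <- estimate_pmf(samples_q)
  support <- union(pm$support, qm$support)
  p <- rep(0, length(support)); q <- rep(0, length(support))
  p[match(pm$support, support)] <- pm$probs
  q[match(qm$support, support)] <- qm$probs
  m <- (p + q) / 2
  hp <- function(w) { w <- w[w > 0]; -sum(w * log(w)) }
  value <- hp(m) - (hp(p) + hp(q)) / 2
  value <- max(value, 0)  # guard against -1e-17 round-off
  measure_result(from_nats(value, base), pm$n + qm$n, "discrete_jsd",
                 unit_label(base))
}

# ---- bias-corrected entropies ----------------------------------------------

# Grassberger's per-count correction term G(h).
grassberger_G <- function(h) {
  digamma(h) + 0.5 * (-1)^h * (digamma((h + 1) / 2) - digamma(h / 2))
}

# Corrected entropy in nats from integer counts.
corrected_entropy_nats <- function(counts, method) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  K <- length(counts)
  p <- counts / n
  switch(method,
    miller_madow = -sum(p * log(p)) + (K - 1) / (2 * n),
    grassberger = log(n) - sum(counts * grassberger_G(counts)) / n,
    chao_shen = {
      f1 <- sum(counts == 1)
      if (f1 == n) f1 <- n - 1  # all-singleton guard: keep coverage positive
      C <- 1 - f1 / n
      pa <- C * p
      sum(-pa * log(pa) / (1 - (1 - pa)^n))
    },
    shrinkage = {
      t <- 1 / K
      denom <- (n - 1) * sum((t - p)^2)
      lambda <- if (denom <= 0) 1 else min(1, max(0, (1 - sum(p^2)) / denom))
      ps <- lambda * t + (1 - lambda) * p
      -sum(ps * log(ps))
    },
    abort_it(paste0("unknown bias-correction method '", method,
                    "'; valid: miller_madow, grassberger, chao_shen, shrinkage"),
             "it_parameter_error"))
}

#' Bias-corrected Shannon entropy
#'
#' Low-bias small-sample replacements for the plug-in entropy:
#' Miller-Madow (`+ (K-1)/(2n)` nats), Grassberger's digamma-based
#' correction, the Chao-Shen coverage-adjusted Horvitz-Thompson
#' estimator, and James-Stein shrinkage towards the uniform distribution
#' over the observed alphabet.  All converge to the plug-in estimate as
#' n grows.
#'
#' @inheritParams shannon_entropy
#' @param method One of `"miller_madow"`, `"grassberger"`, `"chao_shen"`,
#'   `"shrinkage"`.
#' @export
bias_corrected_entropy <- function(samples,
                                   method = c("miller_madow", "grassberger",
                                              "chao_shen", "shrinkage"),
                                   base = NULL) {
  if (length(method) != 1 || !method %in% c("miller_madow", "grassberger",
                                            "chao_shen", "shrinkage"))
    abort_it(paste0("unknown bias-correction method '",
                    paste(method, collapse = "/"),
                    "'; valid: miller_madow, grassberger, chao_shen, shrinkage"),
             "it_parameter_error")
  cols <- as_cols(samples)
  codes <- encode_tuples(cols)
  H <- corrected_entropy_nats(tabulate(codes), method)
  measure_result(from_nats(H, base), length(codes), method, unit_label(base),
                 parameters = list(method = method))
}
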