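# The unified embedding/slicing layer and the user-facing entropy, MI,
# cMI, TE and cTE front ends for every estimator family.
#
# Slicing convention: the prediction horizon is one step after the target
# history, and the source-to-target lag tau applies to the source block
# only.  Row t aligns y[t+1] with (y[t], ..., y[t-(k-1)u]) and
# (x[t-tau+1], ..., x[t-tau+1-(l-1)u]); the number of aligned rows is the
# maximum the series lengths permit.

.it_approaches <- c("discrete", "kernel", "metric", "ordinal",
                    "miller_madow", "grassberger", "chao_shen", "shrinkage",
                    "renyi", "tsallis")
.bias_methods <- c("miller_madow", "grassberger", "chao_shen", "shrinkage")

check_approach <- function(approach) {
  if (!is.character(approach) || length(approach) != 1 ||
      !approach %in% .it_approaches)
    abort_it(paste0("unknown estimator '", paste(approach, collapse = "/"),
                    "'; valid names: ", paste(.it_approaches, collapse = ", ")),
             "it_unsupported_combination_error")
  approach
}

mat_cols <- function(m) lapply(seq_len(ncol(m)), function(j) m[, j])

cols_to_matrix <- function(cols, arg) {
  ok <- vapply(cols, is.numeric, logical(1))
  if (!all(ok))
    abort_it(paste0("`", arg, "` must be numeric for continuous estimators"),
             "it_value_error")
  do.call(cbind, cols)
}

# ---- the estimator-family workhorse ----------------------------------------
# x/y/z are lists of aligned columns; computes I(X; Y) when `zcols` is
# NULL and I(X; Y | Z) otherwise, under the requested family.
cmi_blocks <- function(xcols, ycols, zcols = NULL, approach = "discrete",
                       base = NULL, a = list()) {
  check_approach(approach)
  n <- length(xcols[[1]])
  if (length(ycols[[1]]) != n || (!is.null(zcols) && length(zcols[[1]]) != n))
    abort_it("variables must have equal numbers of aligned observations",
             "it_shape_error")

  if (approach == "discrete") {
    if (is.null(zcols)) {
      cx <- encode_tuples(xcols); cy <- encode_tuples(ycols)
      cxy <- encode_tuples(c(xcols, ycols))
      tx <- tabulate(cx); ty <- tabulate(cy); txy <- tabulate(cxy)
      local_nats <- log(txy[cxy]) - log(tx[cx]) - log(ty[cy]) + log(n)
    } else {
      cz <- encode_tuples(zcols)
      cxz <- encode_tuples(c(xcols, zcols))
      cyz <- encode_tuples(c(ycols, zcols))
      cxyz <- encode_tuples(c(xcols, ycols, zcols))
      tz <- tabulate(cz); txz <- tabulate(cxz)
      tyz <- tabulate(cyz); txyz <- tabulate(cxyz)
      local_nats <- log(txyz[cxyz]) + log(tz[cz]) - log(txz[cxz]) - log(tyz[cyz])
    }
    local <- from_nats(local_nats, base)
    return(measure_result(mean(local), n, "discrete", unit_label(base),
                          local_values = local))
  }

  if (approach %in% .bias_methods) {
    Hc <- function(cols) corrected_entropy_nats(tabulate(encode_tuples(cols)),
                                                approach)
    v <- if (is.null(zcols)) {
      Hc(xcols) + Hc(ycols) - Hc(c(xcols, ycols))
    } else {
      Hc(c(xcols, zcols)) + Hc(c(ycols, zcols)) - Hc(zcols) -
        Hc(c(xcols, ycols, zcols))
    }
    return(measure_result(from_nats(v, base), n, approach, unit_label(base),
                          parameters = list(method = approach)))
  }

  if (approach == "kernel") {
    X <- cols_to_matrix(xcols, "x"); Y <- cols_to_matrix(ycols, "y")
    Z <- if (!is.null(zcols)) cols_to_matrix(zcols, "z")
    data <- cbind(X, Y, Z)
    ix <- seq_len(ncol(X)); iy <- ncol(X) + seq_len(ncol(Y))
    kern <- a$kernel %||% "box"
    bw <- a$bandwidth
    if (is.null(Z)) {
      ld <- kernel_log_densities(data, list(xy = c(ix, iy), x = ix, y = iy),
                                 kernel = kern, bandwidth = bw)
      local_nats <- ld[, "xy"] - ld[, "x"] - ld[, "y"]
    } else {
      iz <- ncol(X) + ncol(Y) + seq_len(ncol(Z))
      ld <- kernel_log_densities(data, list(xyz = c(ix, iy, iz),
                                            xz = c(ix, iz), yz = c(iy, iz),
                                            z = iz),
                                 kernel = kern, bandwidth = bw)
      local_nats <- ld[, "xyz"] + ld[, "z"] - ld[, "xz"] - ld[, "yz"]
    }
    local <- from_nats(local_nats, base)
    return(measure_result(mean(local), n, paste0("kernel_", kern),
                          unit_label(base), local_values = local,
                          parameters = list(kernel = kern,
                                            bandwidth = attr(ld, "bandwidth"))))
  }

  if (approach == "metric") {
    X <- cols_to_matrix(xcols, "x"); Y <- cols_to_matrix(ycols, "y")
    k <- a$k %||% 4L; noise <- a$noise %||% 0; seed <- a$seed
    if (is.null(zcols))
      return(ksg_mi(X, Y, k = k, base = base, noise = noise, seed = seed))
    return(ksg_cmi(X, Y, cols_to_matrix(zcols, "z"), k = k, base = base,
                   noise = noise, seed = seed))
  }

  # Renyi / Tsallis: entropy-combination definition.  Order 1 aliases to
  # the Shannon route of the matching family (discrete or metric).
  order <- a$alpha %||% a$q %||% a$order %||% 2
  if (!is.numeric(order) || length(order) != 1 || order <= 0)
    abort_it("the Renyi/Tsallis order must be a positive real",
             "it_parameter_error")
  continuous <- all(vapply(c(xcols, ycols, zcols), is.double, logical(1)))
  if (abs(order - 1) < 1e-12) {
    # Tsallis has no base freedom: the Shannon limit is reported in nats.
    res <- cmi_blocks(xcols, ycols, zcols,
                      if (continuous) "metric" else "discrete",
                      if (approach == "tsallis") "nats" else base, a)
    res$estimator <- approach
    res$parameters$order <- order
    return(res)
  }
  Hg <- if (continuous) {
    k <- a$k %||% 4L; noise <- a$noise %||% 0; seed <- a$seed
    function(cols) lps_entropy(do.call(cbind, cols), order = order, k = k,
                               type = approach, base = "nats",
                               noise = noise, seed = seed)$value
  } else if (approach == "renyi") {
    function(cols) renyi_entropy(cols, alpha = order, base = "nats")$value
  } else {
    function(cols) tsallis_entropy(cols, q = order)$value
  }
  v <- if (is.null(zcols)) {
    Hg(xcols) + Hg(ycols) - Hg(c(xcols, ycols))
  } else {
    Hg(c(xcols, zcols)) + Hg(c(ycols, zcols)) - Hg(zcols) -
      Hg(c(xcols, ycols, zcols))
  }
  if (approach == "tsallis") {
    measure_result(v, n, "tsallis", "nats",
                   parameters = list(order = order))
  } else {
    measure_result(from_nats(v, base), n, "renyi", unit_label(base),
                   parameters = list(order = order))
  }
}

# ---- slicing ---------------------------------------------------------------

#' Slice source/target/conditioning series into aligned embedding blocks
#'
#' Builds the aligned blocks used by every transfer-entropy estimator:
#' the target's next value (`future`), `k_hist` columns of target past,
#' `l_hist` columns of source past lagged by `tau`, and (optionally) the
#' conditioning series' past embedded like the source.  Histories are
#' strided by `u` (contiguous when `u = 1`).
#'
#' @param source,target Equal-length vectors (numeric or symbolic).
#' @param cond Optional conditioning series of the same length.
#' @param k_hist Target history length (columns of target past).
#' @param l_hist Source history length.
#' @param tau Source-to-target lag (>= 1).
#' @param u Within-history spacing (>= 1).
#' @return A `sliced_blocks` list: `future` (one-column matrix),
#'   `tgt_past`, `src_past`, optional `cond_past`, and `n_rows`.
#' @examples
#' slice_embed(1:5, 1:5)$n_rows         # 4
#' slice_embed(1:5, 1:5, k_hist = 2)$n_rows  # 3
#' @export
slice_embed <- function(source, target, cond = NULL,
                        k_hist = 1, l_hist = 1, tau = 1, u = 1) {
  for (p in list(k_hist = k_hist, l_hist = l_hist, tau = tau, u = u)) {
    if (!is.numeric(p) || length(p) != 1 || p < 1 || p != round(p))
      abort_it("embedding parameters k_hist, l_hist, tau, u must be integers >= 1",
               "it_parameter_error")
  }
  check_nonempty(source, "source"); check_nonempty(target, "target")
  n <- length(target)
  if (length(source) != n || (!is.null(cond) && length(cond) != n))
    abort_it("source, target (and cond) must have equal lengths", "it_shape_error")
  t_min <- max((k_hist - 1) * u + 1, (l_hist - 1) * u + tau)
  rows <- as.integer(n - t_min)
  if (rows < 1)
    abort_it(sprintf("series too short for this embedding: need at least %d observations (have %d)",
                     t_min + 1, n), "it_insufficient_data_error")
  t <- t_min:(n - 1)
  hist_block <- function(v, len, lag0) {
    do.call(cbind, lapply(0:(len - 1), function(j) v[t - lag0 - j * u]))
  }
  out <- list(future = matrix(target[t + 1], ncol = 1),
              tgt_past = hist_block(target, k_hist, 0),
              src_past = hist_block(source, l_hist, tau - 1),
              cond_past = if (!is.null(cond)) hist_block(cond, l_hist, tau - 1),
              n_rows = rows,
              spec = list(k_hist = k_hist, l_hist = l_hist, tau = tau, u = u))
  class(out) <- "sliced_blocks"
  out
}

# Shared preparation for TE-style measures: ordinal pre-symbolization,
# default jitter for the metric family, then slicing.
prepare_te_blocks <- function(source, target, cond, approach,
                              k_hist, l_hist, tau, u, a) {
  check_approach(approach)
  inner <- approach
  if (approach == "ordinal") {
    D <- a$D %||% 3; delay <- a$delay %||% 1
    source <- symbolize(source, D = D, delay = delay)
    target <- symbolize(target, D = D, delay = delay)
    if (!is.null(cond)) cond <- symbolize(cond, D = D, delay = delay)
    inner <- "discrete"
    a$ordinal <- list(D = D, delay = delay)
  }
  if (approach == "metric" && is.null(a$noise)) a$noise <- 1e-10
  blocks <- slice_embed(source, target, cond, k_hist, l_hist, tau, u)
  zb <- mat_cols(blocks$tgt_past)
  if (!is.null(blocks$cond_past)) zb <- c(zb, mat_cols(blocks$cond_past))
  list(xb = mat_cols(blocks$src_past), yb = mat_cols(blocks$future),
       zb = zb, inner = inner, a = a, blocks = blocks)
}

# ---- user-facing one-liners ------------------------------------------------

#' Entropy of a single variable under any estimator family
#'
#' One-liner front end dispatching on `approach`: `"discrete"` plug-in,
#' the four bias corrections (`"miller_madow"`, `"grassberger"`,
#' `"chao_shen"`, `"shrinkage"`), `"kernel"`, `"metric"`
#' (Kozachenko-Leonenko), `"ordinal"`, and the generalized `"renyi"` /
#' `"tsallis"` orders (discrete plug-in for symbolic input, kNN for
#' continuous input).
#'
#' @param data Sample vector (symbols or reals) or matrix of joint
#'   columns.
#' @param approach Estimator family name.
#' @param base Logarithm base override (see [resolve_base()]).
#' @param ... Family parameters: `kernel`, `bandwidth` (kernel); `k`,
#'   `noise`, `seed` (metric); `D`, `delay` (ordinal); `alpha` / `q`
#'   (generalized orders).
#' @return An [measure_result()] object.
#' @examples
#' entropy(rep(0:1, 50), "discrete")$value               # 1 bit
#' entropy(rnorm(500), "metric", base = "nats")$value    # ~ 1.42
#' @export
entropy <- function(data, approach = "discrete", base = NULL, ...) {
  check_approach(approach)
  a <- list(...)
  switch(approach,
    discrete = shannon_entropy(data, base = base),
    miller_madow = ,
    grassberger = ,
    chao_shen = ,
    shrinkage = bias_corrected_entropy(data, method = approach, base = base),
    kernel = kernel_entropy(data, kernel = a$kernel %||% "box",
                            bandwidth = a$bandwidth, base = base),
    metric = kl_entropy(data, k = a$k %||% 4L, base = base,
                        noise = a$noise %||% 0, seed = a$seed),
    ordinal = ordinal_entropy(data, D = a$D %||% 3L, delay = a$delay %||% 1L,
                              base = base),
    renyi = ,
    tsallis = {
      order <- a$alpha %||% a$q %||% a$order %||% 2
      vals <- if (is.matrix(data) || is.data.frame(data)) unlist(data) else data
      if (is.double(vals)) {
        lps_entropy(data, order = order, k = a$k %||% 4L, type = approach,
                    base = base, noise = a$noise %||% 0, seed = a$seed)
      } else if (approach == "renyi") {
        renyi_entropy(data, alpha = order, base = base)
      } else {
        tsallis_entropy(data, q = order)
      }
    })
}

#' Mutual information between two variables
#'
#' \eqn{I(X; Y)} under the requested estimator family.  Discrete and
#' ordinal estimates are entropy combinations (exact identities on the
#' empirical distribution); the kernel family averages local density
#' log-ratios; the metric family uses the KSG algorithm-1 estimator;
#' `"renyi"`/`"tsallis"` compose the generalized entropies (order 1
#' aliases to the Shannon route).
#'
#' @param x,y Equal-length sample vectors, or matrices of joint columns.
#' @inheritParams entropy
#' @return An [measure_result()] object with local values where the
#'   family defines them.
#' @export
mutual_information <- function(x, y, approach = "discrete", base = NULL, ...) {
  check_approach(approach)
  a <- list(...)
  if (approach == "ordinal") {
    D <- a$D %||% 3; delay <- a$delay %||% 1
    res <- cmi_blocks(list(symbolize(x, D, delay)),
                      list(symbolize(y, D, delay)), NULL, "discrete", base, a)
    res$estimator <- "ordinal"
    res$parameters <- list(D = D, delay = delay)
    return(res)
  }
  cmi_blocks(as_cols(x, "x"), as_cols(y, "y"), NULL, approach, base, a)
}

#' Conditional mutual information
#'
#' \eqn{I(X; Y \mid Z)}: for the discrete family the exact combination
#' \eqn{H(X,Z) + H(Y,Z) - H(Z) - H(X,Y,Z)}; Frenzel-Pompe kNN counting
#' for the metric family; local conditional density ratios for kernels.
#'
#' @param x,y,z Equal-length sample vectors or matrices.
#' @inheritParams entropy
#' @export
conditional_mi <- function(x, y, z, approach = "discrete", base = NULL, ...) {
  check_approach(approach)
  a <- list(...)
  if (approach == "ordinal") {
    D <- a$D %||% 3; delay <- a$delay %||% 1
    res <- cmi_blocks(list(symbolize(x, D, delay)),
                      list(symbolize(y, D, delay)),
                      list(symbolize(z, D, delay)), "discrete", base, a)
    res$estimator <- "ordinal"
    res$parameters <- list(D = D, delay = delay)
    return(res)
  }
  cmi_blocks(as_cols(x, "x"), as_cols(y, "y"), as_cols(z, "z"),
             approach, base, a)
}

#' Transfer entropy from a source to a target series
#'
#' \eqn{T_{X \to Y}}: the conditional mutual information between the
#' target's next value and the source's past, given the target's own
#' past, computed on the aligned blocks of [slice_embed()].  The ordinal
#' family symbolizes both series first (the future is the next symbol);
#' the metric family enables a tiny default jitter (`noise = 1e-10`)
#' because embedded chaotic series frequently contain ties.
#'
#' @param source,target Equal-length series.
#' @inheritParams slice_embed
#' @inheritParams entropy
#' @return An [measure_result()] object; `n_samples` is the number of
#'   aligned rows actually used (post-embedding).
#' @examples
#' x <- sample(0:1, 500, TRUE); y <- c(0L, x[-500])  # y copies x
#' transfer_entropy(x, y)$value                       # ~ 1 bit
#' @export
transfer_entropy <- function(source, target, approach = "discrete",
                             k_hist = 1, l_hist = 1, tau = 1, u = 1,
                             base = NULL, ...) {
  pb <- prepare_te_blocks(source, target, NULL, approach,
                          k_hist, l_hist, tau, u, list(...))
  res <- cmi_blocks(pb$xb, pb$yb, pb$zb, pb$inner, base, pb$a)
  res$estimator <- paste0(approach, "_te")
  res$parameters <- c(res$parameters,
                      list(k_hist = k_hist, l_hist = l_hist, tau = tau, u = u),
                      pb$a$ordinal)
  res
}

#' Conditional transfer entropy
#'
#' \eqn{T_{X \to Y \mid Z}}: transfer entropy with the conditioning
#' series' past (embedded like the source) added to the target history.
#'
#' @param cond Conditioning series, same length as `source`/`target`.
#' @inheritParams transfer_entropy
#' @export
conditional_te <- function(source, target, cond, approach = "discrete",
                           k_hist = 1, l_hist = 1, tau = 1, u = 1,
                           base = NULL, ...) {
  pb <- prepare_te_blocks(source, target, cond, approach,
                          k_hist, l_hist, tau, u, list(...))
  res <- cmi_blocks(pb$xb, pb$yb, pb$zb, pb$inner, base, pb$a)
  res$estimator <- paste0(approach, "_cte")
  res$parameters <- c(res$parameters,
                      list(k_hist = k_hist, l_hist = l_hist, tau = tau, u = u),
                      pb$a$ordinal)
  res
}
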