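# Independent brute-force oracles: direct summation over the empirical
# distribution via table(), never through the package's counting code.

oracle_probs <- function(x) {
  tab <- table(x)
  as.numeric(tab) / sum(tab)
}

oracle_entropy_bits <- function(x) {
  p <- oracle_probs(x)
  -sum(p * log2(p))
}

oracle_joint_entropy_bits <- function(...) {
  oracle_entropy_bits(do.call(paste, list(...)))
}

oracle_mi_bits <- function(x, y) {
  oracle_entropy_bits(x) + oracle_entropy_bits(y) -
    oracle_joint_entropy_bits(x, y)
}

oracle_cross_entropy_bits <- function(xp, xq) {
  tp <- table(xp); tq <- table(xq)
  p <- as.numeric(tp) / sum(tp)
  q <- as.numeric(tq[names(tp)]) / sum(tq)
  -sum(p * log2(q))
}

oracle_kld_bits <- function(xp, xq) {
  oracle_cross_entropy_bits(xp, xq) - oracle_entropy_bits(xp)
}

oracle_jsd_bits <- function(xp, xq) {
  support <- union(unique(xp), unique(xq))
  p <- sapply(support, function(s) mean(xp == s))
  q <- sapply(support, function(s) mean(xq == s))
  m <- (p + q) / 2
  h <- function(w) { w <- w[w > 0]; -sum(w * log2(w)) }
  h(m) - (h(p) + h(q)) / 2
}

# Random categorical sample with alphabet size K.
rand_symbols <- function(n, K, seed) {
  set.seed(seed)
  sample(letters[seq_len(K)], n, replace = TRUE)
}
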