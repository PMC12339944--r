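test_that("pmf estimation reproduces relative frequencies", {
  p <- estimate_pmf(c("a", "a", "b", "b"))
  expect_equal(p$probs[match(c("a", "b"), p$support)], c(0.5, 0.5))
  expect_equal(estimate_pmf("a")$probs, 1)
  p2 <- estimate_pmf(c(1, 1, 1, 2))
  expect_equal(p2$probs[match(c(1, 2), p2$support)], c(0.75, 0.25))
  expect_equal(sum(p2$probs), 1, tolerance = 1e-12)
  expect_equal(p2$counts / p2$n, p2$probs)
  expect_true(all(p2$probs > 0))
  expect_error(estimate_pmf(integer(0)), class = "it_empty_input_error")
})

test_that("joint pmf marginalisation is count-exact", {
  set.seed(8)
  x <- sample(letters[1:3], 60, replace = TRUE)
  y <- sample(0:1, 60, replace = TRUE)
  jp <- joint_pmf(list(x, y))
  for (axis in 1:2) {
    m <- marginal_pmf(jp, axis)
    direct <- estimate_pmf(if (axis == 1) x else y)
    expect_identical(sort(m$counts), sort(direct$counts))
    expect_equal(sum(m$probs), 1, tolerance = 1e-12)
  }
  expect_error(joint_pmf(list(x, y[1:10])), class = "it_shape_error")
})

test_that("Shannon entropy matches hand computations", {
  expect_equal(shannon_entropy(rep(0:1, each = 50))$value, 1)
  expect_equal(shannon_entropy(rep(7, 100))$value, 0)
  # counts (3, 1): -0.75 log2 0.75 - 0.25 log2 0.25
  expect_equal(shannon_entropy(c(1, 1, 1, 2))$value, 0.8112781,
               tolerance = 1e-6)
  expect_error(shannon_entropy(numeric(0)), class = "it_empty_input_error")
})

test_that("Renyi entropy: uniform, alias and hand-derived cases", {
  expect_equal(renyi_entropy(rep(1:4, 10), alpha = 2)$value, 2,
               tolerance = 1e-12)
  x <- c(1, 1, 1, 2)
  expect_equal(renyi_entropy(x, alpha = 1)$value, shannon_entropy(x)$value)
  expect_equal(renyi_entropy(x, alpha = 2)$value, -log2(0.75^2 + 0.25^2),
               tolerance = 1e-12)
  expect_error(renyi_entropy(x, alpha = -1), class = "it_parameter_error")
})

test_that("Tsallis entropy: constant, fair coin and alias cases", {
  expect_equal(tsallis_entropy(rep(3, 20), q = 2)$value, 0)
  expect_equal(tsallis_entropy(rep(0:1, 25), q = 2)$value, 0.5)
  x <- sample(1:3, 50, replace = TRUE)
  expect_equal(tsallis_entropy(x, q = 1)$value,
               shannon_entropy(x, base = "nats")$value)
  expect_identical(tsallis_entropy(x, q = 2)$units, "nats")
  r <- tsallis_entropy(x, q = 1.5)
  expect_equal(mean(r$local_values), r$value, tolerance = 1e-10)
  expect_error(tsallis_entropy(x, q = 0), class = "it_parameter_error")
})

test_that("joint entropy: independence, self-pairing and anticorrelation", {
  combos <- expand.grid(x = 0:1, y = 0:1)
  both <- combos[rep(1:4, 25), ]
  expect_equal(joint_entropy(both)$value, 2)
  x <- sample(0:1, 80, replace = TRUE)
  expect_equal(joint_entropy(list(x, x))$value, shannon_entropy(x)$value)
  xf <- rep(0:1, 30)
  expect_equal(joint_entropy(list(xf, 1 - xf))$value, 1)
  expect_error(joint_entropy(list(1:4, 1:3)), class = "it_shape_error")
})

test_that("cross-entropy: self case, concentrated P, and Gibbs bound", {
  x <- sample(letters[1:3], 60, replace = TRUE)
  expect_equal(cross_entropy(x, x)$value, shannon_entropy(x)$value,
               tolerance = 1e-12)
  expect_equal(cross_entropy(rep("a", 10), rep(c("a", "b"), 10))$value, 1)
  for (s in 1:5) {
    p <- rand_symbols(40, 2, s)
    q <- c(rand_symbols(40, 3, s + 100), letters[1:3])  # cover support
    expect_gte(cross_entropy(p, q)$value,
               shannon_entropy(p)$value - 1e-12)
  }
  expect_error(cross_entropy(c("a", "z"), c("a", "b")),
               class = "it_divergence_undefined_error")
})

test_that("KL divergence matches hand values and identities", {
  x <- sample(1:4, 50, replace = TRUE)
  expect_equal(kl_divergence(x, x)$value, 0, tolerance = 1e-12)
  p <- rep(c("a", "b"), 2)            # (0.5, 0.5)
  q <- c(rep("a", 3), "b")            # (0.75, 0.25)
  expect_equal(kl_divergence(p, q)$value,
               0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25),
               tolerance = 1e-12)
  # cross_entropy = entropy + KLD, exactly
  expect_equal(cross_entropy(p, q)$value,
               shannon_entropy(p)$value + kl_divergence(p, q)$value,
               tolerance = 1e-12)
  expect_error(kl_divergence(rep("a", 5), rep("b", 5)),
               class = "it_divergence_undefined_error")
})

test_that("JS divergence: zero, maximal and symmetric cases", {
  x <- sample(1:3, 40, replace = TRUE)
  expect_equal(js_divergence(x, x)$value, 0, tolerance = 1e-12)
  expect_equal(js_divergence(rep(c("a", "b"), 10), rep(c("c", "d"), 10))$value,
               1, tolerance = 1e-12)
  p <- rand_symbols(30, 3, 1); q <- rand_symbols(30, 3, 2)
  expect_equal(js_divergence(p, q)$value, js_divergence(q, p)$value,
               tolerance = 1e-12)
  expect_gte(js_divergence(p, q)$value, 0)
  expect_lte(js_divergence(p, q)$value, 1)
})

test_that("bias-corrected entropies: exact cases and asymptotic agreement", {
  expect_equal(bias_corrected_entropy(rep(1, 50), "miller_madow")$value, 0)
  # counts (2, 2): 1 bit + (1/8 nats) / ln 2
  expect_equal(bias_corrected_entropy(c(1, 1, 2, 2), "miller_madow")$value,
               1 + (1 / 8) / log(2), tolerance = 1e-10)
  set.seed(99)
  big <- sample(0:1, 1e5, replace = TRUE)
  plug <- shannon_entropy(big)$value
  for (m in c("miller_madow", "grassberger", "chao_shen", "shrinkage"))
    expect_lt(abs(bias_corrected_entropy(big, m)$value - plug), 0.005)
  expect_error(bias_corrected_entropy(1:5, "jackknife"),
               class = "it_parameter_error")
})

test_that("bias corrections reduce the small-sample entropy deficit", {
  # plug-in underestimates on small samples; corrections move upward
  set.seed(4)
  reps <- replicate(200, {
    x <- sample(1:4, 12, replace = TRUE)
    c(plug = shannon_entropy(x, base = "nats")$value,
      mm = bias_corrected_entropy(x, "miller_madow", base = "nats")$value,
      gr = bias_corrected_entropy(x, "grassberger", base = "nats")$value)
  })
  truth <- log(4)
  expect_lt(mean(reps["plug", ]), truth)
  expect_gt(mean(reps["mm", ]), mean(reps["plug", ]))
  expect_lt(abs(mean(reps["mm", ]) - truth), abs(mean(reps["plug", ]) - truth))
  expect_lt(abs(mean(reps["gr", ]) - truth), abs(mean(reps["plug", ]) - truth))
})

test_that("corrected divergences exist for the supported subset only", {
  p <- rand_symbols(40, 3, 5)
  q <- c(rand_symbols(40, 3, 6), letters[1:3])
  for (m in c("miller_madow", "grassberger")) {
    expect_s3_class(kl_divergence(p, q, method = m), "it_result")
    expect_s3_class(js_divergence(p, q, method = m), "it_result")
  }
  expect_error(kl_divergence(p, q, method = "chao_shen"),
               class = "it_unsupported_combination_error")
  expect_error(js_divergence(p, q, method = "shrinkage"),
               class = "it_unsupported_combination_error")
})

test_that("all discrete measures match the brute-force oracle on tiny data", {
  for (s in 1:8) {
    K <- sample(2:4, 1)
    n <- sample(4:12, 1)
    x <- rand_symbols(n, K, s)
    y <- rand_symbols(n, K, s + 50)
    expect_equal(shannon_entropy(x)$value, oracle_entropy_bits(x),
                 tolerance = 1e-12)
    expect_equal(joint_entropy(list(x, y))$value,
                 oracle_joint_entropy_bits(x, y), tolerance = 1e-12)
    expect_equal(mutual_information(x, y)$value, oracle_mi_bits(x, y),
                 tolerance = 1e-12)
    expect_equal(js_divergence(x, y)$value, oracle_jsd_bits(x, y),
                 tolerance = 1e-12)
    if (all(unique(x) %in% unique(y))) {
      expect_equal(kl_divergence(x, y)$value, oracle_kld_bits(x, y),
                   tolerance = 1e-12)
      expect_equal(cross_entropy(x, y)$value, oracle_cross_entropy_bits(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("entropy bounds and generalized-order continuity hold", {
  for (s in 1:6) {
    x <- rand_symbols(200, 5, s)
    y <- rand_symbols(200, 4, s + 10)
    H <- shannon_entropy(x)$value
    expect_gte(H, 0)
    expect_lte(H, log2(length(unique(x))) + 1e-12)
    Hxy <- joint_entropy(list(x, y))$value
    expect_gte(Hxy, max(H, shannon_entropy(y)$value) - 1e-12)
    expect_lte(Hxy, H + shannon_entropy(y)$value + 1e-12)
    Hs_nats <- shannon_entropy(x, base = "nats")$value
    for (eps in c(-1e-6, 1e-6)) {
      expect_lt(abs(renyi_entropy(x, alpha = 1 + eps)$value - H), 1e-4)
      expect_lt(abs(tsallis_entropy(x, q = 1 + eps)$value - Hs_nats), 1e-4)
    }
  }
})
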