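test_that("slicing yields the maximal aligned row count", {
  expect_identical(slice_embed(1:5, 1:5)$n_rows, 4L)
  expect_identical(slice_embed(1:5, 1:5, k_hist = 2)$n_rows, 3L)
  b <- slice_embed(1:20, 21:40, k_hist = 3, l_hist = 2, tau = 2, u = 2)
  # manual alignment: t from max((3-1)*2+1, (2-1)*2+2) = 5 to 19
  expect_identical(b$n_rows, 15L)
  expect_identical(dim(b$tgt_past), c(15L, 3L))
  expect_identical(dim(b$src_past), c(15L, 2L))
  # row alignment spot check at t = 5: future y[6], tgt (y5, y3, y1), src (x4, x2)
  expect_identical(b$future[1, 1], 26L)
  expect_identical(b$tgt_past[1, ], c(25L, 23L, 21L))
  expect_identical(b$src_past[1, ], c(4L, 2L))
  expect_error(slice_embed(1:3, 1:3, k_hist = 5),
               class = "it_insufficient_data_error")
  expect_error(slice_embed(1:5, 1:6), class = "it_shape_error")
})

test_that("self-slicing reproduces the target history in the source block", {
  x <- rnorm(30)
  b <- slice_embed(x, x, k_hist = 2, l_hist = 2, tau = 1)
  expect_identical(b$src_past, b$tgt_past)
})

test_that("discrete MI: self-information, independence and the XOR triple", {
  x <- rep(0:1, 50)
  expect_equal(mutual_information(x, x)$value, 1)
  combos <- expand.grid(a = 0:1, b = 0:1)[rep(1:4, 25), ]
  expect_equal(mutual_information(combos$a, combos$b)$value, 0)
  # XOR: pairwise independent, jointly determined
  z <- (combos$a + combos$b) %% 2
  expect_equal(mutual_information(combos$a, combos$b)$value, 0)
  expect_equal(conditional_mi(combos$a, combos$b, z)$value, 1)
})

test_that("conditioning on constants and on the outcome behave exactly", {
  set.seed(51)
  x <- sample(0:2, 400, replace = TRUE)
  y <- (x + sample(0:1, 400, replace = TRUE)) %% 3
  expect_equal(conditional_mi(x, y, rep(1, 400))$value,
               mutual_information(x, y)$value, tolerance = 1e-12)
  expect_equal(conditional_mi(x, y, y)$value, 0, tolerance = 1e-12)
})

test_that("a balanced one-step copy process transfers exactly one bit", {
  # 32 full cycles of the period-4 pattern; the pad continues the cycle
  # backwards so every (past, next) pair count is exactly balanced
  x <- rep(c(0L, 0L, 1L, 1L), length.out = 129)
  y <- c(1L, x[-129])  # y[t+1] = x[t]
  expect_equal(transfer_entropy(x, y)$value, 1, tolerance = 1e-12)
  r <- transfer_entropy(x, y)
  expect_identical(r$n_samples, 128L)
})

test_that("independent sequences give near-zero TE in every family", {
  set.seed(52)
  n <- 5000
  xd <- sample(0:1, n, TRUE); yd <- sample(0:1, n, TRUE)
  expect_lt(abs(transfer_entropy(xd, yd)$value), 0.02)
  xc <- rnorm(n); yc <- rnorm(n)
  expect_lt(abs(transfer_entropy(xc, yc, "metric", base = "nats")$value), 0.02)
  expect_lt(abs(transfer_entropy(xc, yc, "ordinal", D = 2)$value), 0.02)
})

test_that("discrete TE equals conditional MI on its own sliced blocks", {
  set.seed(53)
  x <- sample(0:2, 800, replace = TRUE)
  y <- c(0L, x[-800] + sample(0:1, 799, TRUE)) %% 3
  for (kh in 1:2) {
    te <- transfer_entropy(x, y, k_hist = kh, l_hist = 2, tau = 2)$value
    b <- slice_embed(x, y, k_hist = kh, l_hist = 2, tau = 2)
    cmi <- conditional_mi(b$src_past, b$future, b$tgt_past)$value
    expect_equal(te, cmi, tolerance = 1e-12)
  }
})

test_that("conditioning away the source or the mediator nulls the transfer", {
  set.seed(54)
  x <- sample(0:1, 600, replace = TRUE)
  z <- c(0L, x[-600])       # z copies x with lag 1
  y <- c(0L, z[-600])       # y copies z with lag 1
  # conditioning on the source itself
  expect_equal(conditional_te(x, y, x)$value, 0, tolerance = 1e-12)
  # chain x -> z -> y: blocked by the mediator, open at lag 2
  expect_equal(conditional_te(x, y, z, tau = 1)$value, 0, tolerance = 1e-12)
  expect_gt(transfer_entropy(x, y, tau = 2)$value, 0.5)
  # independent conditioner changes nothing much
  w <- sample(0:1, 600, replace = TRUE)
  expect_lt(abs(conditional_te(x, y, w, tau = 2)$value -
                  transfer_entropy(x, y, tau = 2)$value), 0.03)
})

test_that("local values average to the global value in every family", {
  set.seed(55)
  n <- 600
  x <- rnorm(n); y <- 0.6 * x + 0.8 * rnorm(n)
  xd <- sample(0:1, n, TRUE); yd <- (xd + sample(0:1, n, TRUE)) %% 2
  cases <- list(
    mutual_information(xd, yd, "discrete"),
    mutual_information(x, y, "kernel", kernel = "gaussian"),
    mutual_information(x, y, "metric"),
    mutual_information(x, y, "ordinal", D = 3),
    transfer_entropy(xd, yd, "discrete"),
    transfer_entropy(x, y, "metric", noise = 1e-10, seed = 1),
    shannon_entropy(xd),
    kernel_entropy(x, "gaussian"),
    kl_entropy(x),
    ordinal_entropy(x, D = 3))
  for (r in cases) {
    expect_false(is.null(r$local_values))
    expect_equal(mean(r$local_values), r$value, tolerance = 1e-10)
    expect_identical(length(r$local_values), as.integer(r$n_samples))
  }
})

test_that("generalized MI reduces to Shannon at order one and deviates off it", {
  set.seed(56)
  xd <- sample(1:3, 500, replace = TRUE)
  yd <- (xd + sample(0:1, 500, TRUE)) %% 3
  shannon_nats <- mutual_information(xd, yd, base = "nats")$value
  expect_equal(mutual_information(xd, yd, "tsallis", q = 1)$value,
               shannon_nats, tolerance = 1e-10)
  expect_equal(mutual_information(xd, yd, "renyi", alpha = 1,
                                  base = "nats")$value,
               shannon_nats, tolerance = 1e-10)
  # near-unit orders stay close (continuity through the limit)
  expect_lt(abs(mutual_information(xd, yd, "renyi", alpha = 1 + 1e-6,
                                   base = "nats")$value - shannon_nats), 1e-4)
  # continuous case: q = 1 aliases to KSG, q = 1.05 produces a distinct value
  g <- gaussian_pair(2000, 0.6, seed = 57)
  ksg <- mutual_information(g$x, g$y, "metric", base = "nats")$value
  expect_equal(mutual_information(g$x, g$y, "tsallis", q = 1)$value, ksg,
               tolerance = 1e-10)
  tq <- mutual_information(g$x, g$y, "tsallis", q = 1.05)$value
  expect_gt(abs(tq - ksg), 1e-4)
})

test_that("unknown estimators fail with the registry of valid names", {
  expect_error(mutual_information(1:5, 1:5, "wavelet"),
               "discrete.*kernel.*metric.*ordinal",
               class = "it_unsupported_combination_error")
  expect_error(entropy(1:5, "nope"),
               class = "it_unsupported_combination_error")
})

test_that("entropy() dispatches consistently across families", {
  set.seed(58)
  xd <- sample(0:3, 400, replace = TRUE)
  expect_identical(entropy(xd, "discrete")$value, shannon_entropy(xd)$value)
  expect_identical(entropy(xd, "miller_madow")$value,
                   bias_corrected_entropy(xd, "miller_madow")$value)
  x <- rnorm(400)
  expect_identical(entropy(x, "metric", k = 3)$value,
                   kl_entropy(x, k = 3)$value)
  expect_identical(entropy(x, "ordinal", D = 3)$value,
                   ordinal_entropy(x, D = 3)$value)
  expect_identical(entropy(xd, "renyi", alpha = 2)$value,
                   renyi_entropy(xd, alpha = 2)$value)
  expect_identical(entropy(x, "renyi", alpha = 2, k = 4)$value,
                   lps_entropy(x, order = 2, k = 4, type = "renyi")$value)
})
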