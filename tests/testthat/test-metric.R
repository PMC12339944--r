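test_that("noise handling: zero amplitude, determinism, bound", {
  x <- matrix(rnorm(60), 20)
  expect_identical(add_noise(x, 0), x)
  n1 <- add_noise(x, 1e-3, seed = 5)
  n2 <- add_noise(x, 1e-3, seed = 5)
  expect_identical(n1, n2)
  expect_lte(max(abs(n1 - x)), 5e-4)
  expect_error(add_noise(x, -1), class = "it_parameter_error")
})

test_that("Kozachenko-Leonenko entropy matches Gaussian and uniform closed forms", {
  set.seed(21)
  x <- rnorm(4000)
  expect_lt(abs(kl_entropy(x, k = 4, base = "nats")$value -
                  0.5 * log(2 * pi * exp(1))), 0.05)
  u <- runif(4000)
  expect_lt(abs(kl_entropy(u, k = 4, base = "nats")$value), 0.05)
  res <- kl_entropy(x, k = 4, base = "nats")
  expect_equal(mean(res$local_values), res$value, tolerance = 1e-10)
})

test_that("kl_entropy is exactly scale-covariant and shift-invariant", {
  set.seed(22)
  x <- rnorm(500)
  h0 <- kl_entropy(x, k = 4, base = "nats")$value
  expect_equal(kl_entropy(5 * x, k = 4, base = "nats")$value - h0, log(5),
               tolerance = 1e-10)
  expect_equal(kl_entropy(x + 100, k = 4, base = "nats")$value, h0,
               tolerance = 1e-8)
})

test_that("duplicate points demand jitter, and jittered runs are reproducible", {
  x <- rep(c(1, 2, 3), each = 10)
  expect_error(kl_entropy(x, k = 2), class = "it_degenerate_distance_error")
  r1 <- kl_entropy(x, k = 2, noise = 1e-8, seed = 3)$value
  r2 <- kl_entropy(x, k = 2, noise = 1e-8, seed = 3)$value
  expect_identical(r1, r2)
  y <- rep(c(4, 5, 6), 10)
  expect_error(ksg_mi(x, y, k = 2), class = "it_degenerate_distance_error")
  m1 <- ksg_mi(x, y, k = 2, noise = 1e-8, seed = 4)$value
  m2 <- ksg_mi(x, y, k = 2, noise = 1e-8, seed = 4)$value
  expect_identical(m1, m2)
})

test_that("KSG mutual information tracks the Gaussian closed form", {
  n <- 4000
  g0 <- gaussian_pair(n, 0, seed = 31)
  expect_lt(abs(ksg_mi(g0$x, g0$y, k = 4, base = "nats")$value), 0.03)
  g9 <- gaussian_pair(n, 0.9, seed = 32)
  expect_lt(abs(ksg_mi(g9$x, g9$y, k = 4, base = "nats")$value -
                  (-0.5 * log(1 - 0.81))), 0.04)
  expect_error(ksg_mi(rnorm(10), rnorm(11)), class = "it_shape_error")
})

test_that("KSG is nearly invariant under strictly monotone marginal transforms", {
  g <- gaussian_pair(3000, 0.7, seed = 33)
  base_mi <- ksg_mi(g$x, g$y, k = 4, base = "nats")$value
  cube_mi <- ksg_mi(g$x, g$y^3, k = 4, base = "nats")$value
  expect_lt(abs(base_mi - cube_mi), 0.05)
})

test_that("conditional KSG separates common-driver from direct coupling", {
  set.seed(34)
  n <- 4000
  z <- rnorm(n)
  x <- z + rnorm(n)
  y <- z + rnorm(n)
  expect_gt(ksg_mi(x, y, k = 4, base = "nats")$value, 0.1)
  expect_lt(abs(ksg_cmi(x, y, z, k = 4, base = "nats")$value), 0.04)
  # irrelevant conditioner leaves MI unchanged
  w <- rnorm(n)
  expect_lt(abs(ksg_cmi(x, y, w, k = 4, base = "nats")$value -
                  ksg_mi(x, y, k = 4, base = "nats")$value), 0.04)
})

test_that("conditional KSG recovers the Gaussian partial-correlation form", {
  set.seed(35)
  n <- 4000
  z <- rnorm(n)
  rho_p <- 0.5
  e1 <- rnorm(n)
  e2 <- rho_p * e1 + sqrt(1 - rho_p^2) * rnorm(n)
  x <- z + e1
  y <- z + e2
  cmi <- ksg_cmi(x, y, z, k = 4, base = "nats")$value
  expect_lt(abs(cmi - (-0.5 * log(1 - rho_p^2))), 0.04)
})

test_that("three routes to Gaussian MI agree within the stated bias bound", {
  g <- gaussian_pair(4000, 0.6, seed = 36)
  closed <- -0.5 * log(1 - 0.36)
  ksg <- ksg_mi(g$x, g$y, k = 4, base = "nats")$value
  decomp <- kl_entropy(g$x, k = 4, base = "nats")$value +
    kl_entropy(g$y, k = 4, base = "nats")$value -
    kl_entropy(cbind(g$x, g$y), k = 4, base = "nats")$value
  expect_lt(abs(ksg - closed), 0.05)
  expect_lt(abs(decomp - closed), 0.05)
  expect_lt(abs(ksg - decomp), 0.05)
})

test_that("generalized kNN entropy: alias at order 1 and Renyi-2 closed form", {
  set.seed(37)
  x <- rnorm(3000)
  expect_equal(lps_entropy(x, order = 1, k = 4, type = "renyi",
                           base = "nats")$value,
               kl_entropy(x, k = 4, base = "nats")$value)
  # Renyi-2 entropy of N(0,1): log(2 sigma sqrt(pi)) = 0.5 log(4 pi)
  r2 <- lps_entropy(x, order = 2, k = 4, type = "renyi", base = "nats")$value
  expect_lt(abs(r2 - 0.5 * log(4 * pi)), 0.05)
  expect_error(lps_entropy(x, order = 6, k = 4), class = "it_parameter_error")
  expect_error(lps_entropy(x, order = -1, k = 4), class = "it_parameter_error")
})
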