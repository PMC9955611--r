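test_that("reservoir_config validates its domain", {
  expect_error(reservoir_config(spectral_radius = 1))
  expect_error(reservoir_config(spectral_radius = 0))
  expect_error(reservoir_config(leak = 1.2))
  expect_error(reservoir_config(connectivity = 0))
  expect_error(reservoir_config(ridge = -1))
  expect_s3_class(reservoir_config(leak = 0), "reservoir_config")
})

test_that("build_reservoir hits the spectral radius and respects the scales", {
  for (s in 1:5) {
    cfg <- reservoir_config(N = 60, spectral_radius = 0.7,
                            connectivity = 0.3, input_scaling = 0.5,
                            seed = s)
    res <- build_reservoir(cfg)
    sr <- max(Mod(eigen(res$A, only.values = TRUE)$values))
    expect_lt(abs(sr - 0.7), 1e-8)
    expect_true(all(abs(res$W_in) <= 0.5))
  }
  # full connectivity: every input weight nonzero
  res1 <- build_reservoir(reservoir_config(N = 40, connectivity = 1,
                                           input_scaling = 0.5, seed = 2))
  expect_true(all(res1$W_in != 0))
  # sparse sampling: nonzero fraction of A near p_s (binomial oracle)
  fr <- vapply(1:10, function(s) {
    A <- build_reservoir(reservoir_config(N = 100, connectivity = 0.1,
                                          seed = s))$A
    mean(A != 0)
  }, numeric(1))
  se <- sqrt(0.1 * 0.9 / 100^2)
  expect_true(all(abs(fr - 0.1) <= 3 * se))
  # degenerate sampling cannot be rescaled
  expect_error(build_reservoir(reservoir_config(N = 1, connectivity = 0.5,
                                                seed = 4)), "zero")
})

test_that("reservoirs are identical under a fixed seed", {
  cfg <- reservoir_config(N = 30, seed = 99)
  expect_identical(build_reservoir(cfg), build_reservoir(cfg))
})

test_that("the leaky state recursion matches hand evaluation", {
  # psi = 0 freezes the state at u0
  res <- build_reservoir(reservoir_config(N = 10, seed = 1))
  res$u0 <- rep(0.3, 10)
  st <- run_states(res, stats::rnorm(20), leak = 0)
  expect_true(all(st == 0.3))
  # N = 1, A = 0, psi = 1: closed form tanh(w x_t)
  r1 <- structure(list(A = matrix(0, 1, 1), W_in = matrix(0.8), u0 = 0,
                       config = reservoir_config(N = 1, connectivity = 1,
                                                 washout = 0)),
                  class = "reservoir")
  x <- stats::runif(30, -2, 2)
  expect_equal(as.numeric(run_states(r1, x, leak = 1)), tanh(0.8 * x),
               tolerance = 1e-12)
  # N = 2, 3 steps, hand-specified weights: step-by-step oracle
  A <- matrix(c(0.2, -0.1, 0.4, 0.3), 2, 2)
  w <- c(0.5, -0.7)
  r2 <- structure(list(A = A, W_in = matrix(w), u0 = c(0, 0),
                       config = reservoir_config(N = 2, washout = 0)),
                  class = "reservoir")
  x3 <- c(1, -0.5, 2)
  psi <- 0.6
  u <- c(0, 0); manual <- matrix(0, 3, 2)
  for (t in 1:3) {
    u_star <- tanh(as.numeric(A %*% u) + w * x3[t])
    u <- (1 - psi) * u + psi * u_star
    manual[t, ] <- u
  }
  expect_equal(unclass(run_states(r2, x3, leak = psi))[, ], manual,
               tolerance = 1e-14, ignore_attr = TRUE)
  # bounded states at full leak; informative error on bad input
  big <- run_states(build_reservoir(reservoir_config(N = 20,
                                                     connectivity = 0.6,
                                                     seed = 3)),
                    stats::rnorm(100, 0, 10), leak = 1)
  expect_true(all(abs(big) < 1))
  expect_error(run_states(r2, c(1, NA, 3)), "index 2")
})

test_that("ridge readout solves the penalized least-squares problem", {
  set.seed(10)
  U <- matrix(stats::rnorm(200 * 12), 200, 12)
  attr(U, "washout") <- 5L
  y <- stats::rnorm(200)
  for (alpha in c(1e-10, 1e-4, 0.1, 100)) {
    w <- as.numeric(fit_readout(U, y, ridge = alpha)$W_out)
    expect_equal(w, ridge_oracle(U[-(1:5), ], y[-(1:5)], alpha),
                 tolerance = 1e-8)
  }
  # zero targets give a zero readout; huge alpha shrinks toward zero
  expect_equal(as.numeric(fit_readout(U, rep(0, 200), ridge = 1)$W_out),
               rep(0, 12))
  w_ols <- as.numeric(fit_readout(U, y, ridge = 0)$W_out)
  w_big <- as.numeric(fit_readout(U, y, ridge = 1e12)$W_out)
  expect_lt(sqrt(sum(w_big^2)), 1e-6 * sqrt(sum(w_ols^2)))
  # rank-deficient states with no penalty: error, or minimum-norm on request
  U2 <- cbind(U[, 1], U[, 1], U[, 2])
  attr(U2, "washout") <- 0L
  expect_error(fit_readout(U2, y, ridge = 0), "singular")
  w_mn <- as.numeric(fit_readout(U2, y, ridge = 0, allow_pinv = TRUE)$W_out)
  expect_equal(as.numeric(U2 %*% w_mn),
               as.numeric(U2 %*% ridge_oracle(U2, y, 1e-12)),
               tolerance = 1e-4)
})

test_that("prediction composes states and readout", {
  res <- build_reservoir(reservoir_config(N = 15, seed = 7, washout = 0))
  x <- stats::rnorm(50)
  st <- run_states(res, x)
  ro <- fit_readout(st, sin(seq_len(50)), ridge = 1e-6)
  expect_equal(predict_readout(ro, st),
               as.numeric(st %*% as.numeric(ro$W_out)), tolerance = 1e-12)
  zero <- structure(list(W_out = matrix(0, 1, 15), ridge = 0),
                    class = "esn_readout")
  expect_equal(predict_readout(zero, st), rep(0, 50))
  expect_error(predict_readout(ro, st[, 1:3]), "match")
})

test_that("NRMSE follows the printed formula and its invariances", {
  expect_equal(nrmse(c(1, 1), c(1, 3)), sqrt(2) / 2)
  expect_equal(nrmse(c(2, 4, 6), c(2, 4, 6)), 0)
  set.seed(2)
  p <- stats::runif(40, 1, 2); o <- stats::runif(40, 1, 2)
  expect_equal(nrmse(3.7 * p, 3.7 * o), nrmse(p, o), tolerance = 1e-12)
  expect_error(nrmse(c(1, 1), c(-1, 1)), "mean zero")
})

test_that("states forget their initial condition (echo state decay)", {
  ok <- vapply(1:30, function(s) {
    res <- build_reservoir(reservoir_config(N = 50, spectral_radius = 0.5,
                                            connectivity = 0.3, seed = s))
    set.seed(s + 50000)
    res$u0 <- stats::rnorm(50)
    st <- run_states(res, rep(0, 500), leak = 1)
    sqrt(sum(st[500, ]^2)) < 1e-6
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("realizable targets are fit to near-perfect skill", {
  r1 <- structure(list(A = matrix(0, 1, 1), W_in = matrix(0.9), u0 = 0,
                       config = reservoir_config(N = 1, washout = 0)),
                  class = "reservoir")
  set.seed(3)
  x <- stats::rnorm(400)
  st <- run_states(r1, x, leak = 1)
  y <- tanh(0.9 * x)
  ro <- fit_readout(st, y, ridge = 1e-10)
  expect_gte(stats::cor(predict_readout(ro, st), y), 1 - 1e-6)
})

test_that("network weights serialize to JSON and reload exactly", {
  res <- build_reservoir(reservoir_config(N = 12, connectivity = 0.6,
                                          seed = 3))
  f <- tempfile(fileext = ".json")
  write_esn_weights(res, f)
  back <- read_esn_weights(f)
  expect_identical(back$A, res$A)
  expect_identical(back$W_in, res$W_in)
  expect_identical(back$u0, res$u0)
  ro <- fit_readout(structure(matrix(stats::rnorm(60), 20, 3),
                              washout = 0L),
                    stats::rnorm(20), ridge = 0.1)
  write_esn_weights(ro, f)
  b2 <- read_esn_weights(f)
  expect_identical(b2$W_out, ro$W_out)
  expect_identical(b2$ridge, ro$ridge)
  expect_error(write_esn_weights(1:3, f), "cannot serialize")
  unlink(f)
})

test_that("the esn() fitting interface is deterministic and consistent", {
  set.seed(4)
  x <- sin(seq(0, 25, length.out = 300)) + stats::rnorm(300, 0, 0.05)
  cfg <- reservoir_config(N = 30, seed = 12, ridge = 1e-6)
  f1 <- esn(x, x, cfg)
  f2 <- esn(x, x, cfg)
  expect_identical(f1$fitted, f2$fitted)
  expect_length(coef(f1), 30)
  expect_equal(predict(f1), fitted(f1))
  expect_equal(residuals(f1), x - fitted(f1))
  expect_equal(predict(f1, newdata = x), fitted(f1), tolerance = 1e-10)
  keep <- seq_along(x) > attr(f1$states, "washout")
  expect_gte(stats::cor(fitted(f1)[keep], x[keep]), 0.99)
})
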