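test_that("qr_dataset validates its invariants", {
  X <- cbind(1, rnorm(10))
  expect_s3_class(qr_dataset(X, rpois(10, 3)), "qr_dataset")
  expect_error(qr_dataset(cbind(2, rnorm(10)), rpois(10, 3)), "intercept")
  expect_error(qr_dataset(X, rep(-1, 10)), "non-negative")
  expect_error(qr_dataset(X, rep(0.5, 10)), "integer")
  expect_error(qr_dataset(X[1:2, ], c(1, 2)), "n > q\\+1")
})

test_that("pinball objective matches term-by-term evaluation", {
  # exact fit has zero loss
  X <- cbind(1, c(0, 1, 2))
  beta <- c(1, 2)
  t <- drop(X %*% beta)
  ev <- pinball_objective(beta, 0.3, t, X)
  expect_equal(ev$loss, 0)
  expect_equal(ev$residuals, rep(0, 3))

  # symmetric median loss: 0.5*1 + 0.5*1
  ev2 <- pinball_objective(0, 0.5, c(1, -1), cbind(c(1, 1)))
  expect_equal(ev2$loss, 1.0)
  expect_equal(ev2$indicators, c(0, 1))

  # asymmetric case against the loop oracle
  X1 <- cbind(rep(1, 5))
  t1 <- 0:4
  expect_equal(pinball_objective(1, 0.25, t1, X1)$loss,
               pinball_loop(1, 0.25, t1, X1))
  expect_equal(pinball_objective(1, 0.25, t1, X1)$loss, 2.25)

  # random instances: vectorised = loop, loss >= 0, summands >= 0
  for (seed in 1:5) {
    inst <- random_instance(30, 2, seed)
    beta <- rnorm(3)
    p <- runif(1, 0.05, 0.95)
    ev <- pinball_objective(beta, p, inst$t, inst$X)
    expect_equal(ev$loss, pinball_loop(beta, p, inst$t, inst$X))
    expect_true(all((p - ev$indicators) * ev$residuals >= 0))
  }
})

test_that("pinball objective rejects malformed input", {
  X <- cbind(1, rnorm(5))
  expect_error(pinball_objective(c(1, 2, 3), 0.5, rnorm(5), X), "length\\(beta\\)")
  expect_error(pinball_objective(c(1, 2), 0.5, rnorm(4), X), "length\\(t\\)")
  expect_error(pinball_objective(c(1, NA), 0.5, rnorm(5), X), "non-finite")
  expect_error(pinball_objective(c(1, 2), 1.2, rnorm(5), X), "strictly inside")
})

test_that("solver achieves the sample-quantile optimum for intercept-only fits", {
  t <- c(1, 2, 9)
  ds <- qr_dataset(cbind(rep(1, 3)), c(0, 0, 0))
  sol <- solve_qr(ds, t, 0.5)
  # any median minimises; compare losses, not coefficients
  expect_equal(sol$achieved_loss, pinball_loop(2, 0.5, t, cbind(rep(1, 3))),
               tolerance = 1e-8)

  set.seed(3)
  t2 <- rnorm(41)
  ds2 <- qr_dataset(cbind(rep(1, 41)), integer(41))
  for (p in c(0.1, 0.33, 0.7, 0.9)) {
    sol2 <- solve_qr(ds2, t2, p)
    loss_at_quantile <- pinball_loop(quantile(t2, p, type = 1), p, t2,
                                     cbind(rep(1, 41)))
    expect_equal(sol2$achieved_loss, loss_at_quantile, tolerance = 1e-7)
  }
})

test_that("solver loss equals the vertex-enumeration optimum on random instances", {
  cases <- expand.grid(q = 1:3, p = c(0.1, 0.5, 0.9))
  for (i in seq_len(nrow(cases))) {
    q <- cases$q[i]
    inst <- random_instance(c(35, 25, 18)[q], q, seed = 100 + i)
    p <- cases$p[i]
    ds <- qr_dataset(inst$X, integer(nrow(inst$X)))
    sol <- solve_qr(ds, inst$t, p)
    oracle <- brute_force_qr(inst$X, inst$t, p)
    expect_equal(sol$achieved_loss, oracle$loss,
                 tolerance = 1e-6 * max(1, oracle$loss))
  }
})

test_that("intercept-only solutions are non-decreasing in the quantile order", {
  set.seed(9)
  t <- rnorm(120, sd = 3)
  ds <- qr_dataset(cbind(rep(1, 120)), integer(120))
  b <- vapply(percentile_grid(), function(p) solve_qr(ds, t, p)$beta, 0)
  expect_true(all(diff(b) > -1e-6))
})

test_that("rank-deficient designs warn and still return a minimiser", {
  set.seed(4)
  x <- rnorm(20)
  X <- cbind(1, x, 2 * x)
  ds <- qr_dataset(X, integer(20))
  t <- x + rnorm(20)
  expect_warning(sol <- solve_qr(ds, t, 0.5), "rank-deficient")
  # the attained loss cannot beat the full-rank two-column optimum
  ref <- brute_force_qr(cbind(1, x), t, 0.5)
  expect_lte(sol$achieved_loss, ref$loss + 1e-6)
})

test_that("percentile grid is the standard 99-point grid", {
  g <- percentile_grid()
  expect_length(g, 99)
  expect_equal(g[1], 0.01)
  expect_equal(g[50], 0.50)
  expect_true(all(diff(g) > 0))
})
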