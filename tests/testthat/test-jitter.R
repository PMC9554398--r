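test_that("jitter noise lives on [y, y+1) and averages to one half", {
  set.seed(1)
  y <- c(0, 3, 21)
  z <- jitter_sample(y)
  expect_true(all(z >= y & z < y + 1))
  expect_error(jitter_sample(c(-1, 2)), "non-negative")
  expect_error(jitter_sample(c(0.5, 2)), "integer")

  set.seed(7)
  z1 <- jitter_sample(rep(2, 5))
  set.seed(7)
  z2 <- jitter_sample(rep(2, 5))
  expect_identical(z1, z2)

  set.seed(2)
  big <- jitter_sample(integer(1e5))
  expect_equal(mean(big), 0.5, tolerance = 0.01)
})

test_that("working transforms follow the linear and log definitions", {
  lin <- jitter_config(transform = "linear")
  lg <- jitter_config(transform = "log", zeta = 1e-5)
  expect_equal(transform_working(3.7, 0.5, lin), 3.2)
  expect_equal(transform_working(2.0, 0.5, lg), log(1.5))
  expect_equal(transform_working(0.3, 0.5, lg), log(1e-5))
  # vectorised with both branches at once
  expect_equal(transform_working(c(0.3, 2), 0.5, lg), c(log(1e-5), log(1.5)))
})

test_that("count recovery inverts the transform with the ceiling rule", {
  lin <- jitter_config(transform = "linear")
  lg <- jitter_config(transform = "log")
  expect_identical(invert_to_count(2.7, 0.5, lin), 3L)
  # T^{-1}(v) - 1 landing exactly on an integer stays there
  expect_identical(invert_to_count(3.5, 0.5, lin), 3L)
  expect_identical(invert_to_count(log(1.5), 0.5, lg), 1L)
  # negative recovered counts are reported unclamped: ceil(-2.2) = -2
  expect_identical(invert_to_count(-1.7, 0.5, lin), -2L)
})

test_that("average-jittering estimates are the mean of the stored replications", {
  set.seed(5)
  ds <- qr_dataset(cbind(1, rnorm(60)), rpois(60, 5))
  pg <- c(0.25, 0.5, 0.75)

  one <- average_jittering_fit(ds, pg, jitter_config(m = 1, seed = 11))
  expect_equal(one$beta_avg, one$beta_reps[1, , ], ignore_attr = TRUE)

  several <- average_jittering_fit(ds, pg, jitter_config(m = 7, seed = 11))
  expect_equal(several$beta_avg, apply(several$beta_reps, c(2, 3), mean),
               ignore_attr = TRUE)

  # determinism under a fixed seed
  again <- average_jittering_fit(ds, pg, jitter_config(m = 7, seed = 11))
  expect_identical(several$beta_avg, again$beta_avg)
})

test_that("averaging over more jitter replications reduces jitter noise", {
  # same dataset throughout: the only randomness is the jitter draw
  set.seed(21)
  ds <- qr_dataset(cbind(rep(1, 80)), rpois(80, 6))
  est <- function(m, seed) {
    average_jittering_fit(ds, 0.5, jitter_config(m = m, seed = seed))$beta_avg[1, 1]
  }
  e1 <- vapply(1:20, function(s) est(1, 1000 + s), 0)
  e25 <- vapply(1:20, function(s) est(25, 2000 + s), 0)
  expect_lt(var(e25), var(e1))
})

test_that("adding a constant to the counts shifts only the intercept", {
  set.seed(13)
  x <- rnorm(70)
  y <- rpois(70, 4)
  pg <- c(0.3, 0.6)
  cfg <- jitter_config(m = 5, seed = 99)
  f0 <- average_jittering_fit(qr_dataset(cbind(1, x), y), pg, cfg)
  f3 <- average_jittering_fit(qr_dataset(cbind(1, x), y + 3), pg, cfg)
  expect_equal(f3$beta_avg[, 1], f0$beta_avg[, 1] + 3, tolerance = 1e-6)
  expect_equal(f3$beta_avg[, 2], f0$beta_avg[, 2], tolerance = 1e-6)
})

test_that("bootstrap standard errors are reproducible and collapse for constant data", {
  set.seed(31)
  ds <- qr_dataset(cbind(1, rnorm(50)), rpois(50, 5))
  cfg <- jitter_config(m = 3)
  se1 <- bootstrap_se(ds, 0.5, cfg, B = 10, seed = 4)
  se2 <- bootstrap_se(ds, 0.5, cfg, B = 10, seed = 4)
  expect_identical(se1, se2)

  dsc <- qr_dataset(cbind(1, rnorm(40)), rep(5L, 40))
  expect_warning(sec <- bootstrap_se(dsc, 0.5, cfg, B = 8, seed = 4),
                 "degenerate")
  # only jitter noise remains: slope SE near zero on the count scale
  expect_lt(max(sec), 0.2)
})

test_that("bootstrap SE of the median matches the sparsity-function form", {
  # Y ~ Poisson(10); the jittered working variable Z = Y + U has density
  # f_Z(z) = P(Y = floor(z)), so the asymptotic SE of the sample median of Z
  # is 1 / (2 f_Z(q) sqrt(n)).
  set.seed(41)
  n <- 500
  y <- rpois(n, 10)
  ds <- qr_dataset(cbind(rep(1, n)), y)
  se <- unname(bootstrap_se(ds, 0.5, jitter_config(m = 10), B = 150,
                            m_boot = 10, seed = 8)[1, 1])
  Fy <- cumsum(dpois(0:40, 10))
  y_star <- min(which(Fy >= 0.5)) - 1
  q_med <- y_star + (0.5 - c(0, Fy)[y_star + 1]) / dpois(y_star, 10)
  se_asym <- 1 / (2 * dpois(floor(q_med), 10) * sqrt(n))
  expect_equal(se, se_asym, tolerance = 0.3)
})
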