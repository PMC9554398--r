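test_that("compiled loss/gradient kernel matches the plain-R reference", {
  sc <- toy_qrcm_scenario()
  d <- sc$gen(300, seed = 2)
  rule <- countqr:::quad_rule(99)
  B <- countqr:::basis_matrix(sc$spec, rule$p)
  yw <- d$dataset$response + 0.5
  for (seed in 1:4) {
    set.seed(seed)
    par <- rnorm(4, sd = 2)
    a <- countqr:::qrcm_loss_parts(par, sc$spec, d$dataset$design, yw, B,
                                   rule$p, rule$w)
    b <- countqr:::qrcm_loss_parts_r(par, sc$spec, d$dataset$design, yw, B,
                                     rule$p, rule$w)
    expect_equal(a$loss, b$loss, tolerance = 1e-12)
    expect_equal(a$grad, b$grad, tolerance = 1e-10)
    expect_equal(a$eta, b$eta, tolerance = 1e-12)
  }
})

test_that("integrated loss is positively homogeneous in (working response, theta)", {
  sc <- toy_qrcm_scenario()
  d <- sc$gen(200, seed = 5)
  rule <- countqr:::quad_rule(99)
  B <- countqr:::basis_matrix(sc$spec, rule$p)
  yw <- d$dataset$response + 0.5
  par <- c(7, 1.2, 0.9, 0.3)
  base <- countqr:::qrcm_loss_parts(par, sc$spec, d$dataset$design, yw, B,
                                    rule$p, rule$w, want_grad = FALSE)$loss
  for (a in c(0.5, 2, 7.3)) {
    scaled <- countqr:::qrcm_loss_parts(a * par, sc$spec, d$dataset$design,
                                        a * yw, B, rule$p, rule$w,
                                        want_grad = FALSE)$loss
    expect_equal(scaled, a * base, tolerance = 1e-12)
  }
})

test_that("quadrature value matches pointwise pinball evaluation and is node-stable", {
  sc <- toy_qrcm_scenario()
  d <- sc$gen(250, seed = 7)
  theta <- theta_matrix(sc$theta_true, sc$spec)
  loss <- integrated_loss(theta, d$dataset, sc$spec, n_nodes = 199)

  rule <- countqr:::quad_rule(199)
  yw <- d$dataset$response + 0.5
  pointwise <- sum(vapply(seq_along(rule$p), function(k) {
    b <- beta_curve(theta, sc$spec, rule$p[k])
    rule$w[k] * pinball_objective(b, rule$p[k], yw, d$dataset$design)$loss
  }, 0))
  expect_equal(loss, pointwise, tolerance = 1e-12)

  fine <- integrated_loss(theta, d$dataset, sc$spec, n_nodes = 999)
  expect_equal(loss, fine, tolerance = 1e-4)
})

test_that("the fitted theta is a local minimiser that recovers the truth", {
  sc <- toy_qrcm_scenario()
  d <- sc$gen(2000, seed = 3)
  fit <- fit_qrcm(d$dataset, sc$spec)
  expect_true(fit$converged)

  # no coordinate perturbation of 1e-4 improves the integrated loss
  for (idx in which(sc$spec$mask)) {
    for (s in c(-1e-4, 1e-4)) {
      th <- fit$theta$values
      th[idx] <- th[idx] + s
      expect_gte(integrated_loss(th, d$dataset, sc$spec) - fit$loss,
                 -1e-7 * (1 + fit$loss))
    }
  }

  err <- abs(fit$theta$values - sc$theta_true)[sc$spec$mask]
  se <- fit$se[sc$spec$mask]
  expect_true(all(err <= 4.5 * se))

  # deterministic refit from the same start
  fit2 <- fit_qrcm(d$dataset, sc$spec)
  expect_identical(fit$theta$values, fit2$theta$values)
})

test_that("sandwich covariance is PSD and shrinks like root-n", {
  sc <- toy_qrcm_scenario()
  d1 <- sc$gen(1000, seed = 9)
  d2 <- sc$gen(4000, seed = 10)
  f1 <- fit_qrcm(d1$dataset, sc$spec)
  f2 <- fit_qrcm(d2$dataset, sc$spec)
  expect_true(all(diag(f1$covariance) >= 0))
  expect_equal(f1$covariance, t(f1$covariance))
  ev <- eigen(f1$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10 * max(ev)))
  # quadrupling n should halve the SEs, approximately
  ratio <- median(f1$se[sc$spec$mask] / f2$se[sc$spec$mask])
  expect_gt(ratio, 1.45)
  expect_lt(ratio, 2.9)
})

test_that("global Wald test has the right degrees of freedom and holds its size", {
  sc <- toy_qrcm_scenario()
  d <- sc$gen(800, seed = 12)
  fit <- fit_qrcm(d$dataset, sc$spec)
  w <- wald_test_global(fit, 2)
  expect_equal(w$df, 2)   # x1 loads on two basis functions
  expect_gt(w$statistic, 0)

  # size under a true null: add a covariate absent from the generator
  spec3 <- model_spec(
    list(list(basis_legendre(0), basis_legendre(1)),
         list(basis_legendre(0), basis_legendre(1)),
         list(basis_legendre(0), basis_legendre(1))),
    coef_names = c("(Intercept)", "x1", "x_null"))
  n_rep <- 60
  n <- 250
  rej <- vapply(seq_len(n_rep), function(r) {
    d <- sc$gen(n, seed = 400 + r)
    set.seed(9000 + r)
    Xa <- cbind(d$dataset$design, rnorm(n))
    dsa <- qr_dataset(Xa, d$dataset$response,
                      names = c("(Intercept)", "x1", "x_null"))
    f <- suppressWarnings(fit_qrcm(dsa, spec3))
    wald_test_global(f, 3)$p_value < 0.05
  }, TRUE)
  # binomial(60, .05) band, generous: [0, 8] rejections
  expect_lte(sum(rej), 8)
})

test_that("count-quantile prediction applies the ceiling rule unclamped", {
  sc <- toy_qrcm_scenario()
  d <- sc$gen(300, seed = 15)
  fit <- fit_qrcm(d$dataset, sc$spec)
  # replace theta with a handmade one so the prediction is analytic:
  # beta0(p) = 2 + 2p  ->  x'beta at p = .6 is 3.2
  th <- theta_matrix(matrix(c(3, 1, 0, 0), 2, 2, byrow = TRUE), sc$spec)
  fit$theta <- th
  expect_identical(predict_quantile_count(fit, c(1, 0), 0.6), 3L)
  # x'beta = 0.4 -> ceil(-0.6) = 0; x'beta = -0.3 -> ceil(-1.3) = -1
  th2 <- theta_matrix(matrix(c(0.4, 0, 0, 0), 2, 2, byrow = TRUE), sc$spec)
  fit$theta <- th2
  expect_identical(predict_quantile_count(fit, c(1, 0), 0.3), 0L)
  th3 <- theta_matrix(matrix(c(-0.3, 0, 0, 0), 2, 2, byrow = TRUE), sc$spec)
  fit$theta <- th3
  expect_identical(predict_quantile_count(fit, c(1, 0), 0.3), -1L)
})

test_that("PIT inverts the fitted quantile function and clamps at the edges", {
  # handmade fit with beta0(p) = p (intercept-only identity quantile curve)
  spec <- model_spec(list(list(basis_legendre(0), basis_legendre(1))))
  rule <- countqr:::quad_rule(199)
  fit <- structure(list(
    theta = theta_matrix(matrix(c(0.5, 0.5), 1, 2), spec), spec = spec,
    design = cbind(1), working = 0.5, rule = rule,
    basis_nodes = countqr:::basis_matrix(spec, rule$p),
    n_nodes = 199L, converged = TRUE), class = "qrcm_fit")
  # y = -0.2 gives working 0.3, and the identity curve crosses at 0.3
  expect_equal(pit(fit, x = c(1), y = -0.2), 0.3, tolerance = 1e-6)
  # working response below the whole curve clamps at eps
  expect_equal(pit(fit, x = c(1), y = -2), 1e-4)
  expect_equal(pit(fit, x = c(1), y = 5), 1 - 1e-4)

  # PIT of the continuous latent under the true model is uniform
  sc <- toy_qrcm_scenario()
  d <- sc$gen(10000, seed = 20)
  tfit <- fit_qrcm(d$dataset, sc$spec, working = d$latent)
  u <- pit(tfit, x = d$dataset$design, y = d$latent - 0.5)
  expect_lt(uniformity_statistic(u, "KS"), 0.02)
})

test_that("uniformity statistics match their closed forms", {
  n <- 40
  grid <- (seq_len(n) - 0.5) / n
  expect_equal(uniformity_statistic(grid, "KS"), 0.5 / n)
  # CvM against a direct-formula loop on a random sorted sample
  set.seed(3)
  u <- sort(runif(25))
  direct <- 1 / (12 * 25) +
    sum(vapply(1:25, function(i) (u[i] - (2 * i - 1) / 50)^2, 0))
  expect_equal(uniformity_statistic(u, "CvM"), direct)
})

test_that("goodness-of-fit test returns the observed statistic and a valid p-value", {
  sc <- toy_qrcm_scenario()
  d <- sc$gen(200, seed = 30)
  fit <- fit_qrcm(d$dataset, sc$spec, n_nodes = 60)
  g <- gof_test(fit, d$dataset, "KS", n_mc = 60, seed = 5)
  expect_equal(g$value, uniformity_statistic(pit(fit), "KS"))
  expect_gte(g$p_value, 0)
  expect_lte(g$p_value, 1)
  expect_lte(g$n_mc_used, 60)
  expect_error(gof_test(fit, d$dataset, "KS", n_mc = 10), "at least 50")
})

test_that("a rich one-covariate QRCM tracks pointwise jittering estimates", {
  # saturated-limit check: Legendre 0..8 plus -log(1-p) on both coefficients
  sc <- toy_qrcm_scenario()
  d <- sc$gen(4000, seed = 33)
  rich <- model_spec(list(
    c(lapply(0:8, basis_legendre), list(basis_minus_log1mp())),
    c(lapply(0:8, basis_legendre), list(basis_minus_log1mp()))),
    coef_names = c("(Intercept)", "x1"))
  qfit <- suppressWarnings(fit_qrcm(d$dataset, rich))
  pg <- seq(0.2, 0.8, 0.1)
  jfit <- average_jittering_fit(d$dataset, pg, jitter_config(m = 10, seed = 2))
  curves <- beta_curve(qfit$theta, rich, pg)
  # the two estimators target quantile functions that agree only up to the
  # sub-unit discretisation wobble of the count support, which loads on the
  # intercept; slopes are comparable much more tightly
  # (one count cell is the hard bound on the intercept discrepancy)
  expect_lt(max(abs(curves[1, ] - jfit$beta_avg[, 1])), 1.0)
  expect_lt(max(abs(curves[2, ] - jfit$beta_avg[, 2])), 0.3)
})
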