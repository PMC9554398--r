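test_that("covariate marginals match the configured shares and moments", {
  cfg <- covariate_config(1e5, seed = 101)
  tab <- sample_covariates(cfg)
  expect_equal(mean(tab$gender == "female"), 0.795, tolerance = 0.005)
  expect_equal(mean(tab$cohort == 2019), 0.5, tolerance = 0.01)
  expect_equal(mean(tab$grade), 81.17, tolerance = 0.25)
  expect_equal(sd(tab$grade), 11.0, tolerance = 0.25)
  expect_equal(mean(tab$credits_sem1), 21.6, tolerance = 0.3)
  expect_true(all(tab$credits_sem1 %% 3 == 0 & tab$credits_sem1 > 0))
  expect_true(all(tab$grade >= 60 & tab$grade <= 100))
  st <- prop.table(table(tab$school_type))
  expect_equal(unname(st["Scientific"]), 0.3513, tolerance = 0.01)

  # standardised columns
  expect_equal(mean(tab$grade_std), 0, tolerance = 1e-10)
  expect_equal(sd(tab$credits_sem1_std), 1, tolerance = 1e-10)

  # determinism
  tab2 <- sample_covariates(cfg)
  expect_identical(tab, tab2)
})

test_that("the reference model implies a monotone quantile function and a median near 10", {
  model <- default_true_model()
  cfg <- covariate_config(1000, seed = 5)
  X <- countqr:::design_from_covariates(sample_covariates(cfg))
  expect_true(validate_monotone(model, X))

  # reference profile: all covariates at baseline / mean
  x0 <- c(1, rep(0, 10))
  b <- beta_curve(model$theta, model$spec, 0.5)
  med_count <- ceiling(sum(x0 * b) - 1)
  expect_true(med_count %in% 9:12)

  # the cohort coefficient curve is exactly the configured combination
  pg <- c(0.1, 0.5, 0.9)
  B <- countqr:::basis_matrix(model$spec, pg)
  expect_equal(unname(beta_curve(model$theta, model$spec, pg)[3, ]),
               drop(B %*% model$theta$values[3, ]))
})

test_that("responses are inverse-transform draws from the true quantile function", {
  model <- default_true_model()
  cfg <- covariate_config(10000, seed = 31)
  X <- countqr:::design_from_covariates(sample_covariates(cfg))
  resp <- sample_response(X, model, seed = 32)
  expect_true(all(resp$y >= 0 & resp$y <= model$support_cap))
  expect_lt(mean(resp$y %in% c(0, model$support_cap)), 0.01)
  expect_lt(uniformity_statistic(resp$latent_p, "KS"), 0.02)

  # fixed profile: empirical count quantiles equal the ceiling rule applied
  # to the true conditional quantile function (brute force over the draws)
  x0 <- c(1, 0.5, 1, 0, -0.3, 0, 1, 0, 0, 0, 0)
  X0 <- matrix(rep(x0, 4e4), ncol = 11, byrow = TRUE)
  r0 <- sample_response(X0, model, seed = 33)
  for (p in seq(0.1, 0.9, 0.2)) {
    q_true <- ceiling(sum(x0 * beta_curve(model$theta, model$spec, p)) - 1)
    expect_equal(unname(quantile(r0$y, p, type = 1)), q_true)
  }
})

test_that("generated records round-trip through the pipeline schema", {
  gen <- generate_credits_data(n = 200, seed = 9)
  expect_equal(nrow(gen$records), 200)
  expect_true(all(gen$records$credits_sem2 %% 3 == 0))
  expect_equal(gen$records$credits_sem2 / 3, as.numeric(gen$dataset$response))
  expect_true(all(gen$records$cohort %in% c(2018, 2019)))

  gen2 <- generate_credits_data(n = 200, seed = 9)
  expect_identical(gen$records, gen2$records)
  expect_identical(gen$dataset$design, gen2$dataset$design)
})
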