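test_that("explanatory r2 approaches 1 on a noiseless fixture", {
  set.seed(4)
  X <- scale(matrix(rnorm(60 * 2), 60), scale = FALSE)
  colnames(X) <- c("t1", "t2")
  Z <- scale(matrix(rnorm(60 * 2), 60), scale = FALSE)
  colnames(Z) <- c("v1", "v2")
  y <- 1 + 0.2 * X[, 1] - 0.1 * X[, 2] + 0.05 * Z[, 1] + rnorm(60, 0, 1e-6)
  ds <- selection_dataset(X, Z, y, allow_negative_fitness = TRUE)
  fit <- fit_multiple_regression(ds, quick_config(seed = 2))
  expect_gte(explanatory_r2(fit, ds), 0.999)
})

test_that("shuffled fitness yields near-zero explanatory power", {
  for (seed in 1:3) {
    sim <- simulate_dataset(simulation_spec(n = 200, n_volatiles = 6,
                                            n_standard = 2,
                                            true_axis_gradient = 0,
                                            true_standard_gradients = 0,
                                            seed = 100 + seed))
    fit <- fit_rrr(sim$dataset, quick_config(seed = seed))
    expect_lt(explanatory_r2(fit, sim$dataset), 0.15)
  }
})

test_that("method agreement is the Pearson correlation of mean-scaled gradients", {
  tmpl <- back_project(manual_fit(w = c(0.6, 0.8, 0)))
  a <- tmpl; b <- tmpl
  a$beta_mu <- c(0.1, -0.2, 0.4)
  expect_equal(method_agreement(a, a), 1.0)
  b$beta_mu <- -a$beta_mu
  expect_equal(method_agreement(a, b), -1.0)

  x <- c(0.12, -0.05, 0.33, 0.01, -0.2)
  y <- c(0.10, 0.02, 0.28, -0.04, -0.15)
  t5 <- data.frame(compound = paste0("c", 1:5), beta_mu = x,
                   beta_mu_se = 0.01)
  class(t5) <- c("compound_gradient_table", "data.frame")
  t5b <- t5; t5b$beta_mu <- y
  manual_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(method_agreement(t5, t5b), manual_r, tolerance = 1e-12)

  t4 <- t5[1:4, ]
  class(t4) <- c("compound_gradient_table", "data.frame")
  expect_error(method_agreement(t5, t4), "shape error")
})

test_that("cross-validation is deterministic and row-order invariant", {
  ds <- quick_sim(n = 60, seed = 20)$dataset
  cfg <- quick_config(seed = 21)
  a <- cv_predictive_r2(ds, cfg, 5, cv_seed = 7)
  b <- cv_predictive_r2(ds, cfg, 5, cv_seed = 7)
  expect_identical(a$folds, b$folds)
  expect_identical(a$r2, b$r2)

  perm <- sample(ds$n)
  ds_perm <- ds
  ds_perm$standard_traits <- ds$standard_traits[perm, , drop = FALSE]
  ds_perm$volatiles <- ds$volatiles[perm, , drop = FALSE]
  ds_perm$absolute_fitness <- ds$absolute_fitness[perm]
  ds_perm$relative_fitness <- ds$relative_fitness[perm]
  ds_perm$ids <- ds$ids[perm]
  c_ <- cv_predictive_r2(ds_perm, cfg, 5, cv_seed = 7)
  expect_equal(c_$r2, a$r2, tolerance = 1e-12)
  expect_identical(c_$folds, a$folds[perm])
})

test_that("cross-validation rejects invalid fold requests", {
  ds <- quick_sim(n = 40, seed = 22)$dataset
  expect_error(cv_predictive_r2(ds, quick_config(), 1, cv_seed = 1),
               "config error")
  expect_error(cv_predictive_r2(ds, quick_config(), 41, cv_seed = 1),
               "config error")
  expect_error(cv_predictive_r2(ds, quick_config(), 25, cv_seed = 1),
               "config error")
  expect_error(cv_predictive_r2(ds, quick_config(), 5), "cv_seed")
})

test_that("predictive r2 separates signal from noise", {
  sim <- simulate_dataset(simulation_spec(n = 300, n_volatiles = 6,
                                          n_standard = 2,
                                          true_axis_gradient = 0.5,
                                          seed = 23))
  cv <- cv_predictive_r2(sim$dataset, quick_config(seed = 23), 5,
                         cv_seed = 23)
  expect_gt(cv$r2, 0.05)
  expect_gt(cor(cv$predictions, sim$dataset$relative_fitness), 0)

  null_r2 <- sapply(1:3, function(s) {
    simn <- simulate_dataset(simulation_spec(n = 200, n_volatiles = 6,
                                             n_standard = 2,
                                             true_axis_gradient = 0,
                                             true_standard_gradients = 0,
                                             seed = 300 + s))
    cv_predictive_r2(simn$dataset, quick_config(seed = s), 5,
                     cv_seed = s)$r2
  })
  expect_lt(mean(null_r2), 0.10)
})

test_that("the multiple-regression model explains at least as much in-sample", {
  for (seed in c(25, 26)) {
    sim <- quick_sim(n = 120, n_volatiles = 6, seed = seed,
                     true_axis_gradient = 0.3)
    cfg <- rrr_config(n_warmup = 400, n_samples = 400, seed = seed)
    r_rrr <- explanatory_r2(fit_rrr(sim$dataset, cfg), sim$dataset)
    r_mr <- explanatory_r2(fit_multiple_regression(sim$dataset, cfg),
                           sim$dataset)
    expect_gte(r_mr, r_rrr - 0.02)
  }
})

test_that("the study summary row carries the reporting columns", {
  sim <- quick_sim(n = 60, seed = 27)
  s <- selection_summary(sim$dataset, quick_config(seed = 27), cv_seed = 1)
  expect_named(s, c("dataset_id", "n", "n_vol", "beta_scent", "lower95",
                    "upper95", "support", "r2", "r2_mr", "r2_cv",
                    "r2_cv_mr", "r_beta"))
  expect_equal(s$n, 60)
  expect_true(s$support >= 0.5 && s$support <= 1)
  expect_true(all(is.finite(unlist(s[, -1]))))
})
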