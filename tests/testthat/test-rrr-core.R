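make_noiseless <- function(n = 60, seed = 4, noise_sd = 1e-6) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * 2), n), scale = FALSE)
  colnames(X) <- c("t1", "t2")
  Z <- scale(matrix(rnorm(n * 2), n), scale = FALSE)
  colnames(Z) <- c("v1", "v2")
  truth <- c(t1 = 0.2, t2 = -0.1, v1 = 0.05, v2 = 0)
  y <- 1 + X %*% truth[1:2] + Z %*% truth[3:4] + rnorm(n, 0, noise_sd)
  list(dataset = selection_dataset(X, Z, as.numeric(y),
                                   allow_negative_fitness = TRUE),
       truth = truth)
}

test_that("noiseless multiple regression recovers the coefficients", {
  nl <- make_noiseless()
  fit <- fit_multiple_regression(nl$dataset, quick_config(seed = 2))
  est <- colMeans(fit$beta_standard)
  expect_equal(unname(est), unname(nl$truth), tolerance = 1e-3)
  expect_equal(fit$rank, 0L)
  expect_equal(ncol(fit$beta_axis), 0L)
})

test_that("posterior draws satisfy the identification invariants", {
  fit <- fit_rrr(quick_sim(seed = 6)$dataset, quick_config(seed = 6))
  norms <- sqrt(rowSums(fit$weights[, 1, ]^2))
  expect_true(all(abs(norms - 1) < 1e-10))
  expect_true(all(fit$sigma2 > 0))
  med <- apply(fit$weights[, 1, ], 2, median)
  expect_true(all(fit$weights[, 1, ] %*% med >= 0))
})

test_that("predictions match hand arithmetic for a known single draw", {
  fit <- manual_fit(intercept = 1, beta_std_orig = 0.5, x_center = 10,
                    x_scale = 2, beta_axis = 0.4, w = c(0.6, 0.8, 0),
                    z_center = c(1, 2, 4), z_scale = c(0.5, 1, 2))
  X <- matrix(c(12, 8), 2, dimnames = list(NULL, "trait_a"))
  Z <- matrix(c(1.5, 0.5, 3, 1, 4, 6), 2,
              dimnames = list(NULL, c("vol_1", "vol_2", "vol_3")))
  # by hand: standardized trait (x-10)/2; z std per column; axis score w.z
  zs1 <- c((1.5 - 1) / 0.5, (3 - 2) / 1, (4 - 4) / 2)
  zs2 <- c((0.5 - 1) / 0.5, (1 - 2) / 1, (6 - 4) / 2)
  expected <- c(1 + 0.5 * 1 + 0.4 * sum(c(0.6, 0.8, 0) * zs1),
                1 + 0.5 * (-1) + 0.4 * sum(c(0.6, 0.8, 0) * zs2))
  expect_equal(predict(fit, X, Z), expected, tolerance = 1e-12)
})

test_that("predictions are invariant to axis sign and scale conventions", {
  fit <- fit_rrr(quick_sim(n = 50, seed = 8)$dataset, quick_config(seed = 8))
  ds <- quick_sim(n = 50, seed = 8)$dataset
  p0 <- predict(fit, ds$standard_traits, ds$volatiles)

  flipped <- fit
  flipped$weights <- -fit$weights
  flipped$beta_axis <- -fit$beta_axis
  expect_equal(predict(flipped, ds$standard_traits, ds$volatiles), p0,
               tolerance = 1e-12)

  rescaled <- fit
  rescaled$weights <- fit$weights * 2.5
  rescaled$beta_axis <- fit$beta_axis / 2.5
  expect_equal(predict(rescaled, ds$standard_traits, ds$volatiles), p0,
               tolerance = 1e-12)
})

test_that("training-row predictions reproduce a noiseless response", {
  nl <- make_noiseless(noise_sd = 1e-7)
  fit <- fit_multiple_regression(nl$dataset, quick_config(seed = 3))
  pred <- predict(fit, nl$dataset$standard_traits, nl$dataset$volatiles)
  expect_equal(pred, nl$dataset$relative_fitness, tolerance = 1e-3)
  # a row at the covariate means predicts the mean response, about 1
  Xm <- matrix(colMeans(nl$dataset$standard_traits), 1,
               dimnames = list(NULL, c("t1", "t2")))
  Zm <- matrix(colMeans(nl$dataset$volatiles), 1,
               dimnames = list(NULL, c("v1", "v2")))
  expect_equal(as.numeric(predict(fit, Xm, Zm)), 1, tolerance = 1e-3)
})

test_that("invalid configurations and shape mismatches are rejected", {
  ds <- quick_sim(n = 40, n_volatiles = 4, seed = 5)$dataset
  expect_error(fit_rrr(ds, quick_config(rank = 5)), "config error")
  expect_error(rrr_config(rank = 0), "config error")
  expect_error(rrr_config(prior_sd_beta = -1), "config error")
  fit <- fit_rrr(ds, quick_config(seed = 5))
  bad <- ds$volatiles
  colnames(bad) <- paste0("x", seq_len(ncol(bad)))
  expect_error(predict(fit, ds$standard_traits, bad), "shape error")
})

test_that("identical seeds give bit-identical draws", {
  ds <- quick_sim(seed = 10)$dataset
  f1 <- fit_rrr(ds, quick_config(seed = 11))
  f2 <- fit_rrr(ds, quick_config(seed = 11))
  expect_identical(f1$beta_axis, f2$beta_axis)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$sigma2, f2$sigma2)
})

test_that("different seeds agree within Monte-Carlo error", {
  ds <- quick_sim(n = 100, seed = 12)$dataset
  cfg <- function(s) rrr_config(n_warmup = 500, n_samples = 500, seed = s)
  f1 <- fit_multiple_regression(ds, cfg(1))
  f2 <- fit_multiple_regression(ds, cfg(99))
  d1 <- f1$diagnostics; d2 <- f2$diagnostics
  for (p in grep("^beta\\[", d1$parameter, value = TRUE)) {
    i1 <- match(p, d1$parameter); i2 <- match(p, d2$parameter)
    mcse <- sqrt(d1$sd[i1]^2 / d1$ess[i1] + d2$sd[i2]^2 / d2$ess[i2])
    expect_lt(abs(d1$mean[i1] - d2$mean[i2]), 3 * mcse)
  }
})

test_that("a wide ill-conditioned fit stays finite under the slope prior", {
  sim <- quick_sim(n = 20, n_volatiles = 22, n_standard = 3, seed = 13)
  expect_warning(fit <- fit_multiple_regression(sim$dataset,
                                                quick_config(seed = 13)),
                 "small")
  expect_true(all(is.finite(fit$beta_standard)))
  expect_true(all(is.finite(fit$diagnostics$rhat) |
                    is.na(fit$diagnostics$rhat)))
})

test_that("diagnostics behave sensibly on independent draws", {
  set.seed(1)
  d <- mcmc_diagnostics(rnorm(2000), rep(1:2, each = 1000))
  expect_lt(abs(d$rhat - 1), 0.02)
  expect_gt(d$ess, 1000)
})
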