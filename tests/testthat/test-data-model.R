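test_that("relative fitness divides by the population mean", {
  expect_equal(relative_fitness(c(5, 5, 5, 5)), c(1, 1, 1, 1))
  expect_equal(relative_fitness(c(2, 4, 6)), c(0.5, 1.0, 1.5))
  expect_error(relative_fitness(c(0, 0, 0)), "degenerate")
  expect_error(relative_fitness(numeric(0)), "empty")
  expect_error(relative_fitness(c(1, -2, 3)), "negative")
})

test_that("relative fitness is invariant to the fitness scale", {
  for (seed in 1:10) {
    set.seed(seed)
    w <- rpois(20, 5)
    if (mean(w) == 0) next
    c_pos <- runif(1, 0.1, 50)
    expect_equal(relative_fitness(c_pos * w), relative_fitness(w))
    expect_equal(mean(relative_fitness(w)), 1)
  }
})

test_that("zero-variance volatile columns are dropped and logged", {
  df <- data.frame(absolute_fitness = c(3, 1, 0, 4, 2),
                   trait_a = c(1.2, 3.1, 2.2, 0.8, 1.9),
                   vol_a = c(0.5, 1.5, 0.7, 2.2, 1.1),
                   vol_flat = rep(0, 5))
  path <- write_fixture_csv(df)
  schema <- list(fitness = "absolute_fitness", standard = "trait_a",
                 volatile_prefix = "vol_")
  expect_warning(ds <- load_dataset(path, schema), "zero-variance")
  expect_equal(colnames(ds$volatiles), "vol_a")
  expect_equal(ds$cleaning_log$dropped_columns, "vol_flat")
  expect_equal(ds$n, 5)
})

test_that("rows with missing values are listwise-deleted and counted", {
  df <- data.frame(absolute_fitness = c(3, 1, 0, 4, 2, 5, 1),
                   trait_a = c(1.2, 3.1, 2.2, 0.8, 1.9, 2.5, 1.1),
                   vol_a = c(0.5, NA, 0.7, 2.2, 1.1, 0.9, 1.4),
                   vol_b = c(1.1, 0.4, 0.8, NA, 0.3, 1.7, 0.6))
  path <- write_fixture_csv(df)
  ds <- load_dataset(path, list(fitness = "absolute_fitness",
                                standard = "trait_a",
                                volatiles = c("vol_a", "vol_b")))
  expect_equal(ds$n, 5)
  expect_equal(ds$cleaning_log$n_rows_dropped, 2)
  expect_equal(mean(ds$relative_fitness), 1)
})

test_that("the packaged synthetic fixture loads with its documented shape", {
  path <- system.file("extdata", "synthetic_selection_30.csv",
                      package = "rrsel")
  ds <- load_dataset(path, dataset_schema(
    standard = c("flower_number", "plant_height", "inflorescence_length"),
    volatiles = c("linalool", "beta_ocimene", "alpha_pinene", "limonene",
                  "eugenol", "benzyl_acetate", "methyl_benzoate",
                  "phenylacetaldehyde"),
    allow_negative_fitness = TRUE))
  expect_equal(ds$n, 30)
  expect_equal(ncol(ds$standard_traits), 3)
  expect_equal(ncol(ds$volatiles), 8)
  expect_true(all(ds$volatiles > 0))
})

test_that("schema and data errors are rejected", {
  df <- data.frame(fruits = c(3, 1, 2, 4, 5, 2), t1 = rnorm(6),
                   v1 = runif(6), v2 = runif(6))
  path <- write_fixture_csv(df)
  expect_error(load_dataset(path, list(fitness = "nope", standard = "t1",
                                       volatiles = c("v1", "v2"))),
               "schema error")
  expect_error(load_dataset(path, list(fitness = "fruits", standard = "t1",
                                       volatiles = character(0))),
               "schema error")

  df$fruits[2] <- -1
  path2 <- write_fixture_csv(df)
  expect_error(load_dataset(path2, list(fitness = "fruits", standard = "t1",
                                        volatiles = c("v1", "v2"))),
               "negative fitness")

  df3 <- data.frame(fruits = c(3, 1, 2), t1 = rnorm(3), t2 = rnorm(3),
                    t3 = rnorm(3), v1 = runif(3))
  path3 <- write_fixture_csv(df3)
  expect_error(load_dataset(path3, list(fitness = "fruits",
                                        standard = c("t1", "t2", "t3"),
                                        volatiles = "v1")),
               "insufficient")
})

test_that("write -> load round trip is idempotent on a clean dataset", {
  ds <- quick_sim(n = 40, seed = 9)$dataset
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  ds2 <- load_dataset(path, dataset_schema(
    standard = colnames(ds$standard_traits),
    volatiles = colnames(ds$volatiles),
    allow_negative_fitness = TRUE))
  expect_equal(unname(ds2$volatiles), unname(ds$volatiles), tolerance = 1e-12)
  expect_equal(ds2$relative_fitness, ds$relative_fitness, tolerance = 1e-12)
  expect_equal(ds2$cleaning_log$n_rows_dropped, 0)
  path2 <- tempfile(fileext = ".csv")
  write_dataset(ds2, path2)
  expect_identical(readLines(path), readLines(path2))
})
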