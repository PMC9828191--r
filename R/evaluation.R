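#' Explanatory r-squared
#'
#' Squared Pearson correlation between posterior-mean in-sample
#' predictions and observed relative fitness. This matches the definition
#' used for the cross-validated version, applied to the training data.
#'
#' @param fit An `rrr_fit`.
#' @param dataset The [selection_dataset()] the fit was made on.
#' @return A proportion in \[0, 1\]. Returns 0 with a warning if the
#'   predictions have zero variance.
#' @export
explanatory_r2 <- function(fit, dataset) {
  check_fit_dataset(fit, dataset)
  pred <- stats::predict(fit, dataset$standard_traits, dataset$volatiles)
  squared_correlation(pred, dataset$relative_fitness)
}

squared_correlation <- function(pred, obs) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    warning("zero variance in predictions or observations; r2 = 0",
            call. = FALSE)
    return(0)
  }
  stats::cor(pred, obs)^2
}

#' Cross-validated predictive r-squared
#'
#' Fivefold (by default) cross-validation: rows are partitioned uniformly
#' at random into near-equal folds, the full model -- including weight
#' estimation and the standardization constants -- is refitted on each
#' training set, held-out predictions are pooled over all folds, and the
#' squared Pearson correlation between pooled predictions and observed
#' relative fitness is returned.
#'
#' Fold assignment is drawn after sorting rows by individual id, so the
#' result is invariant to row order; `cv_seed` makes it reproducible.
#'
#' @param dataset A [selection_dataset()].
#' @param config An [rrr_config()]; the same settings are reused for
#'   every training-fold fit.
#' @param n_folds Number of folds (2 to n).
#' @param cv_seed Seed for the fold assignment (required; there is no
#'   silent default).
#' @param method `"rrr"` for the reduced-rank model or `"mr"` for the
#'   multiple-regression baseline.
#' @return A list: `r2` (the pooled predictive r-squared), `folds`
#'   (integer fold id per row, in dataset row order), `predictions`
#'   (pooled held-out predictions, in dataset row order).
#' @export
cv_predictive_r2 <- function(dataset, config = rrr_config(), n_folds = 5,
                             cv_seed, method = c("rrr", "mr")) {
  validate_selection_dataset(dataset)
  method <- match.arg(method)
  if (missing(cv_seed)) stop("cv_seed is required", call. = FALSE)
  if (n_folds < 2 || n_folds > dataset$n)
    stop("config error: n_folds must be between 2 and n", call. = FALSE)
  if (dataset$n < 2 * n_folds)
    stop("config error: need n >= 2 * n_folds", call. = FALSE)

  ord <- order(dataset$ids)
  set.seed(cv_seed)
  fold_sorted <- sample(rep_len(seq_len(n_folds), dataset$n))
  folds <- integer(dataset$n)
  folds[ord] <- fold_sorted

  fitter <- if (method == "rrr") fit_rrr else fit_multiple_regression
  pred <- numeric(dataset$n)
  for (f in seq_len(n_folds)) {
    test <- which(folds == f)
    train <- subset_rows(dataset, which(folds != f))
    fit <- fitter(train, config, .validate = FALSE)
    pred[test] <- stats::predict(fit,
                                 dataset$standard_traits[test, , drop = FALSE],
                                 dataset$volatiles[test, , drop = FALSE])
  }
  list(r2 = squared_correlation(pred, dataset$relative_fitness),
       folds = folds, predictions = pred)
}

#' Agreement between reduced-rank and multiple-regression gradients
#'
#' Pearson correlation between the per-compound posterior-mean
#' mean-scaled gradients inferred by back-projection from the reduced-rank
#' fit and those from the multiple-regression baseline -- the summary used
#' to ask whether the single learned axis reproduces compound-level
#' inference.
#'
#' @param rrr_compounds A `compound_gradient_table` from [back_project()].
#' @param mr_table A `gradient_table` from [scale_gradients()] on a
#'   multiple-regression fit (its volatile rows are used), or a second
#'   `compound_gradient_table`.
#' @return Pearson correlation in \[-1, 1\].
#' @export
method_agreement <- function(rrr_compounds, mr_table) {
  stopifnot(inherits(rrr_compounds, "compound_gradient_table"))
  if (inherits(mr_table, "compound_gradient_table")) {
    mr <- data.frame(term = mr_table$compound, beta_mu = mr_table$beta_mu)
  } else {
    mr <- as.data.frame(mr_table)
    mr <- mr[mr$role == "volatile", c("term", "beta_mu")]
  }
  if (nrow(mr) != nrow(rrr_compounds) ||
      !setequal(mr$term, rrr_compounds$compound))
    stop("shape error: the two tables must cover the same volatiles",
         call. = FALSE)
  m <- mr$beta_mu[match(rrr_compounds$compound, mr$term)]
  stats::cor(rrr_compounds$beta_mu, m)
}

#' One-row study summary
#'
#' Collects the headline quantities for one population-year into a single
#' row: sample size, number of volatiles, the variance-scaled axis
#' gradient with credible interval and posterior support, explanatory
#' r-squared for both models, cross-validated predictive r-squared for
#' both models, and the between-method gradient correlation.
#'
#' @param dataset A [selection_dataset()].
#' @param config An [rrr_config()].
#' @param cv_seed Seed for the cross-validation folds; `NULL` skips the
#'   (comparatively slow) CV columns.
#' @param n_folds Folds for the CV columns.
#' @return A one-row data frame with columns `dataset_id`, `n`, `n_vol`,
#'   `beta_scent`, `lower95`, `upper95`, `support`, `r2`, `r2_mr`,
#'   `r2_cv`, `r2_cv_mr`, `r_beta`.
#' @export
selection_summary <- function(dataset, config = rrr_config(),
                              cv_seed = NULL, n_folds = 5) {
  fit <- fit_rrr(dataset, config)
  fit_mr <- fit_multiple_regression(dataset, config)
  grad <- scale_gradients(fit, dataset)
  axis <- grad[grad$role == "axis", ][1, ]
  r_beta <- method_agreement(back_project(fit, dataset),
                             scale_gradients(fit_mr, dataset))
  out <- data.frame(dataset_id = dataset$dataset_id, n = dataset$n,
                    n_vol = ncol(dataset$volatiles),
                    beta_scent = axis$beta_sigma,
                    lower95 = axis$lower95, upper95 = axis$upper95,
                    support = axis$support,
                    r2 = explanatory_r2(fit, dataset),
                    r2_mr = explanatory_r2(fit_mr, dataset),
                    r2_cv = NA_real_, r2_cv_mr = NA_real_,
                    r_beta = r_beta, stringsAsFactors = FALSE)
  if (!is.null(cv_seed)) {
    out$r2_cv <- cv_predictive_r2(dataset, config, n_folds, cv_seed,
                                  method = "rrr")$r2
    out$r2_cv_mr <- cv_predictive_r2(dataset, config, n_folds, cv_seed,
                                     method = "mr")$r2
  }
  out
}
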