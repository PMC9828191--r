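# Realistic column names for simulated blends; beyond the pool, columns
# fall back to volatile_<k>.
volatile_name_pool <- c(
  "linalool", "beta_ocimene", "alpha_pinene", "limonene", "eugenol",
  "benzyl_acetate", "methyl_benzoate", "phenylacetaldehyde",
  "benzaldehyde", "beta_caryophyllene", "germacrene_d", "nerolidol",
  "geraniol", "citronellol", "methyl_salicylate", "indole",
  "phenylethyl_alcohol", "cinnamyl_alcohol", "alpha_farnesene",
  "myrcene", "sabinene", "caryophyllene_oxide", "benzyl_alcohol",
  "p_cresol", "anisaldehyde", "veratrole", "eucalyptol",
  "trans_beta_farnesene", "methyl_eugenol", "alpha_terpineol",
  "nonanal", "decanal")

standard_name_pool <- c("flower_number", "plant_height",
                        "inflorescence_length", "flowering_time",
                        "corolla_width", "spur_length")

#' Specify a synthetic selection study
#'
#' Defines the generative model for one simulated population-year dataset.
#' Volatile emission rates are right-skewed and correlated: on the log
#' scale each compound is a linear combination of a few shared latent
#' factors (biosynthetic pathways) plus independent noise, then
#' exponentiated. Standard traits are multivariate normal with
#' exchangeable correlation 0.3. Relative fitness is generated from a true
#' rank-1 selection axis over the standardized volatiles plus
#' variance-scaled gradients on the standard traits and Gaussian noise:
#' \deqn{w_i = 1 + \beta_{axis} s_i + \sum_k \beta_k x_{ik}^{(std)} + \epsilon_i}
#' with the axis score \eqn{s_i} standardized to unit variance, so
#' `true_axis_gradient` and `true_standard_gradients` are variance-scaled
#' gradients by construction.
#'
#' Defaults mirror a typical single-population floral-scent selection
#' study: 80 individuals, 3 morphological traits, 22 volatiles, axis
#' gradient 0.15 (about the across-study average strength of selection on
#' scent), residual SD 0.3.
#'
#' @param n Number of individuals (>= 10).
#' @param n_standard Number of standard traits.
#' @param n_volatiles Number of volatile compounds.
#' @param n_factors Latent factors generating volatile correlation.
#' @param volatile_log_mean,volatile_log_sd Location and scale of the
#'   log-emission model.
#' @param factor_loading_sd SD of the latent-factor loadings.
#' @param true_weights Unit vector of length `n_volatiles` defining the
#'   true selection axis, or `"random"` for a seeded random unit vector.
#' @param true_axis_gradient Variance-scaled selection gradient on the
#'   axis score.
#' @param true_standard_gradients Variance-scaled gradients on the
#'   standard traits (recycled to length `n_standard`).
#' @param residual_sd SD of the Gaussian fitness noise (> 0).
#' @param fitness_model `"gaussian"` (relative fitness observed directly,
#'   the analysis model's own error structure) or `"poisson"` (fruit
#'   counts drawn around `mean_fruits` times the positive part of the
#'   linear predictor; a robustness mode).
#' @param mean_fruits Mean fruit count for the Poisson mode.
#' @param seed Integer seed; every draw is governed by it.
#' @param dataset_id Label for the generated dataset.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n = 80, n_standard = 3, n_volatiles = 22,
                            n_factors = 3, volatile_log_mean = 0,
                            volatile_log_sd = 1, factor_loading_sd = 0.6,
                            true_weights = "random",
                            true_axis_gradient = 0.15,
                            true_standard_gradients = 0.1,
                            residual_sd = 0.3,
                            fitness_model = c("gaussian", "poisson"),
                            mean_fruits = 10, seed = 1,
                            dataset_id = "simulated") {
  fitness_model <- match.arg(fitness_model)
  spec <- list(n = as.integer(n), n_standard = as.integer(n_standard),
               n_volatiles = as.integer(n_volatiles),
               n_factors = as.integer(n_factors),
               volatile_log_mean = volatile_log_mean,
               volatile_log_sd = volatile_log_sd,
               factor_loading_sd = factor_loading_sd,
               true_weights = true_weights,
               true_axis_gradient = true_axis_gradient,
               true_standard_gradients =
                 rep_len(true_standard_gradients, n_standard),
               residual_sd = residual_sd,
               fitness_model = fitness_model,
               mean_fruits = mean_fruits,
               seed = as.integer(seed),
               dataset_id = dataset_id)
  class(spec) <- "simulation_spec"
  validate_simulation_spec(spec)
  spec
}

validate_simulation_spec <- function(spec) {
  if (spec$n < 10) stop("config error: need at least 10 individuals",
                        call. = FALSE)
  if (spec$residual_sd <= 0) stop("config error: residual_sd must be > 0",
                                  call. = FALSE)
  if (spec$n_volatiles < 1 || spec$n_standard < 1 || spec$n_factors < 1)
    stop("config error: trait/factor counts must be positive", call. = FALSE)
  if (is.numeric(spec$true_weights)) {
    if (length(spec$true_weights) != spec$n_volatiles)
      stop("config error: true_weights length must equal n_volatiles",
           call. = FALSE)
    if (abs(sqrt(sum(spec$true_weights^2)) - 1) > 1e-8)
      stop("config error: true_weights must be a unit vector", call. = FALSE)
  } else if (!identical(spec$true_weights, "random")) {
    stop("config error: true_weights must be a unit vector or \"random\"",
         call. = FALSE)
  }
  if (spec$fitness_model == "poisson" && spec$mean_fruits <= 0)
    stop("config error: mean_fruits must be > 0 for poisson fitness",
         call. = FALSE)
  invisible(spec)
}

#' Simulate one selection dataset
#'
#' Draws a dataset from the generative model described in
#' [simulation_spec()] and returns it together with a truth record holding
#' every generating parameter, for parameter-recovery tests.
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `dataset` (a [selection_dataset()]) and
#'   `truth` (list: `weights` -- the true unit axis, `axis_gradient`,
#'   `standard_gradients`, `axis_scores` -- the standardized true composite
#'   scores, `spec`).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n; q <- spec$n_volatiles; p <- spec$n_standard

  # volatiles: exp(mu + scale * (Lambda f + e)), e ~ N(0, 0.5^2)
  Lambda <- matrix(stats::rnorm(q * spec$n_factors, 0,
                                spec$factor_loading_sd), q)
  f <- matrix(stats::rnorm(n * spec$n_factors), n)
  e <- matrix(stats::rnorm(n * q, 0, 0.5), n)
  Z <- exp(spec$volatile_log_mean +
             spec$volatile_log_sd * (f %*% t(Lambda) + e))
  colnames(Z) <- make_pool_names(volatile_name_pool, q, "volatile")

  # standard traits: exchangeable correlation 0.3, mean 10, sd 2
  R <- matrix(0.3, p, p); diag(R) <- 1
  X <- matrix(stats::rnorm(n * p), n) %*% chol(R)
  X <- 10 + 2 * X
  colnames(X) <- make_pool_names(standard_name_pool, p, "trait")

  w_true <- if (identical(spec$true_weights, "random")) {
    v <- stats::rnorm(q); v / sqrt(sum(v^2))
  } else spec$true_weights
  names(w_true) <- colnames(Z)

  score <- as.numeric(scale(scale(Z) %*% w_true))
  Xstd <- scale(X)

  lp <- 1 + spec$true_axis_gradient * score +
    as.numeric(Xstd %*% spec$true_standard_gradients)
  if (spec$fitness_model == "gaussian") {
    w_abs <- lp + stats::rnorm(n, 0, spec$residual_sd)
    ds <- selection_dataset(X, Z, w_abs, dataset_id = spec$dataset_id,
                            allow_negative_fitness = TRUE)
  } else {
    w_abs <- stats::rpois(n, spec$mean_fruits * pmax(0, lp))
    ds <- selection_dataset(X, Z, w_abs, dataset_id = spec$dataset_id)
  }

  list(dataset = ds,
       truth = list(weights = w_true,
                    axis_gradient = spec$true_axis_gradient,
                    standard_gradients = spec$true_standard_gradients,
                    axis_scores = score, spec = spec))
}

#' Simulate a collection of studies with varying selection
#'
#' Generates `n_datasets` datasets that share the true axis weights but
#' whose true axis gradients are drawn from
#' Normal(`base_spec$true_axis_gradient`, `gradient_dispersion`^2) -- the
#' generative counterpart of the among-dataset variance estimator
#' [sigma_beta_c()].
#'
#' @param base_spec A [simulation_spec()]; its `true_weights` (resolved
#'   once if `"random"`) and all other fields are shared across datasets.
#' @param n_datasets Number of datasets (>= 2).
#' @param gradient_dispersion SD of true axis gradients across datasets
#'   (>= 0).
#' @param seed Governs the gradient draws and per-dataset seeds.
#' @return A list with elements `datasets` (list of [selection_dataset()]),
#'   `truths` (list of truth records), and `true_gradients`.
#' @export
simulate_study_collection <- function(base_spec, n_datasets,
                                      gradient_dispersion, seed = 1) {
  stopifnot(inherits(base_spec, "simulation_spec"))
  if (n_datasets < 2)
    stop("config error: need at least 2 datasets", call. = FALSE)
  if (gradient_dispersion < 0)
    stop("config error: gradient_dispersion must be >= 0", call. = FALSE)

  set.seed(seed)
  gradients <- stats::rnorm(n_datasets, base_spec$true_axis_gradient,
                            gradient_dispersion)
  child_seeds <- sample.int(.Machine$integer.max, n_datasets)
  if (identical(base_spec$true_weights, "random")) {
    v <- stats::rnorm(base_spec$n_volatiles)
    base_spec$true_weights <- v / sqrt(sum(v^2))
  }

  sims <- lapply(seq_len(n_datasets), function(d) {
    sp <- base_spec
    sp$true_axis_gradient <- gradients[d]
    sp$seed <- child_seeds[d]
    sp$dataset_id <- paste0(base_spec$dataset_id, "_", d)
    validate_simulation_spec(sp)
    simulate_dataset(sp)
  })

  list(datasets = lapply(sims, `[[`, "dataset"),
       truths = lapply(sims, `[[`, "truth"),
       true_gradients = gradients)
}

make_pool_names <- function(pool, k, stem) {
  if (k <= length(pool)) pool[seq_len(k)]
  else c(pool, paste0(stem, "_", seq.int(length(pool) + 1, k)))
}
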