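#' Configure the Bayesian reduced-rank selection model
#'
#' Model: relative fitness \eqn{w_i = \alpha + \sum_k x_{ik}\beta_k +
#' \sum_{k\le r}(\sum_l w_{kl} z_{il})\beta_{axis,k} + \epsilon_i},
#' \eqn{\epsilon_i \sim N(0,\sigma^2)}, where the \eqn{z_{il}} are
#' internally standardized volatiles and each axis's weight vector is
#' reported with unit norm. Priors are conditionally conjugate:
#' independent Normal(0, `prior_sd_beta`^2) on the intercept and all
#' slopes (standardized-covariate scale), Normal(0, `prior_sd_weights`^2)
#' on the raw weights (normalized post hoc), and inverse-gamma on
#' \eqn{\sigma^2}. These are weak at typical selection-study sample sizes
#' and make every full conditional normal or inverse-gamma, enabling a
#' Gibbs sampler.
#'
#' @param rank Number of composite axes (default 1, the single "scent
#'   selection axis"). Ranks above 1 are supported for prediction and
#'   back-projection but individual axes then lack rotational
#'   identifiability.
#' @param prior_sd_beta Prior SD of intercept and slopes.
#' @param prior_sd_weights Prior SD of raw axis weights.
#' @param residual_prior_shape,residual_prior_scale Inverse-gamma
#'   hyperparameters for the residual variance.
#' @param n_chains,n_warmup,n_samples,thin MCMC settings. Defaults: 2
#'   chains of 1000 warmup + 1000 retained draws.
#' @param seed Integer seed; the sampler is bit-reproducible given it.
#' @return An `rrr_config` list.
#' @export
rrr_config <- function(rank = 1, prior_sd_beta = 1, prior_sd_weights = 1,
                       residual_prior_shape = 0.01,
                       residual_prior_scale = 0.01,
                       n_chains = 2, n_warmup = 1000, n_samples = 1000,
                       thin = 1, seed = 1) {
  cfg <- list(rank = as.integer(rank), prior_sd_beta = prior_sd_beta,
              prior_sd_weights = prior_sd_weights,
              residual_prior_shape = residual_prior_shape,
              residual_prior_scale = residual_prior_scale,
              n_chains = as.integer(n_chains),
              n_warmup = as.integer(n_warmup),
              n_samples = as.integer(n_samples),
              thin = as.integer(thin), seed = as.integer(seed))
  with(cfg, {
    if (rank < 1) stop("config error: rank must be >= 1", call. = FALSE)
    if (any(c(prior_sd_beta, prior_sd_weights, residual_prior_shape,
              residual_prior_scale) <= 0))
      stop("config error: prior parameters must be positive", call. = FALSE)
    if (n_chains < 1 || n_samples < 2 || n_warmup < 0 || thin < 1)
      stop("config error: invalid MCMC settings", call. = FALSE)
  })
  class(cfg) <- "rrr_config"
  cfg
}

#' Fit the reduced-rank selection model
#'
#' Regresses relative fitness on the standard traits plus `config$rank`
#' composite covariates that are learned linear combinations of the
#' (internally standardized) volatiles. Sampling alternates conditionally
#' conjugate blocks: slopes and intercept jointly normal given the
#' weights; each axis's weight vector normal given the slopes; residual
#' variance inverse-gamma. After sampling, each draw's weight vector is
#' rescaled to unit norm with the axis slope absorbing the magnitude, and
#' draws are sign-aligned to the element-wise median weight vector (the
#' bilinear term is identified only up to sign and scale; neither
#' operation changes the likelihood or predictions).
#'
#' Standard-trait slopes are mapped back to the original measurement
#' scale for reporting. Split-R-hat and effective sample size are
#' computed per parameter; a warning is issued if any R-hat exceeds 1.1.
#'
#' @param dataset A [selection_dataset()].
#' @param config An [rrr_config()].
#' @param .validate Run dataset invariant checks before fitting. Internal
#'   callers (cross-validation training folds, whose relative fitness no
#'   longer averages exactly 1) disable this.
#' @return An object of class `rrr_fit` holding posterior draws
#'   (`intercept`, `beta_standard` on the original trait scale,
#'   `beta_standard_std`, `beta_axis`, `weights` as an S x rank x q array,
#'   `sigma2`, `axis_scores`, `chain`), training standardization
#'   constants, the config, and a `diagnostics` data frame.
#' @examples
#' sim <- simulate_dataset(simulation_spec(n = 60, n_volatiles = 5, seed = 3))
#' fit <- fit_rrr(sim$dataset, rrr_config(n_warmup = 100, n_samples = 100))
#' @export
fit_rrr <- function(dataset, config = rrr_config(), .validate = TRUE) {
  if (.validate) validate_selection_dataset(dataset)
  stopifnot(inherits(config, "rrr_config"))
  q <- ncol(dataset$volatiles)
  if (config$rank > q)
    stop("config error: rank (", config$rank,
         ") exceeds the number of volatiles (", q, ")", call. = FALSE)
  fit_engine(dataset, config, rank = config$rank)
}

#' Fit the multiple-regression baseline
#'
#' The classical Lande-Arnold comparison model: every volatile enters as
#' a standard covariate alongside the morphological traits, with no
#' weight block. Uses the same sampler and priors, so the normal prior on
#' standardized slopes acts as mild ridge regularization, keeping
#' ill-conditioned fits (many collinear volatiles, modest n) finite.
#'
#' @inheritParams fit_rrr
#' @return An `rrr_fit` with empty axis components.
#' @export
fit_multiple_regression <- function(dataset, config = rrr_config(),
                                    .validate = TRUE) {
  if (.validate) validate_selection_dataset(dataset)
  stopifnot(inherits(config, "rrr_config"))
  p <- ncol(dataset$standard_traits); q <- ncol(dataset$volatiles)
  if (dataset$n <= p + q + 1)
    warning(sprintf("n = %d is small for %d covariates; the slope prior does the regularizing",
                    dataset$n, p + q), call. = FALSE)
  fit_engine(dataset, config, rank = 0L)
}

fit_engine <- function(dataset, config, rank) {
  y <- dataset$relative_fitness
  if (rank > 0) {
    Xraw <- dataset$standard_traits
    Zraw <- dataset$volatiles
  } else {
    Xraw <- cbind(dataset$standard_traits, dataset$volatiles)
    Zraw <- matrix(numeric(0), dataset$n, 0)
  }
  x_center <- colMeans(Xraw); x_scale <- apply(Xraw, 2, stats::sd)
  if (any(x_scale <= 0))
    stop("zero-variance covariate: ",
         paste(colnames(Xraw)[x_scale <= 0], collapse = ", "), call. = FALSE)
  Xs <- sweep(sweep(Xraw, 2, x_center), 2, x_scale, "/")
  if (rank > 0) {
    z_center <- colMeans(Zraw); z_scale <- apply(Zraw, 2, stats::sd)
    Zs <- sweep(sweep(Zraw, 2, z_center), 2, z_scale, "/")
  } else {
    z_center <- numeric(0); z_scale <- numeric(0)
    Zs <- Zraw
  }

  set.seed(config$seed)
  chains <- lapply(seq_len(config$n_chains), function(ch)
    rrr_gibbs_chain(y, Xs, Zs, rank, config$prior_sd_beta,
                    config$prior_sd_weights, config$residual_prior_shape,
                    config$residual_prior_scale, config$n_warmup,
                    config$n_samples, config$thin))

  S <- config$n_samples * config$n_chains
  px <- ncol(Xs); q <- ncol(Zs)
  beta <- do.call(rbind, lapply(chains, `[[`, "beta"))
  sigma2 <- unlist(lapply(chains, `[[`, "sigma2"))
  chain_id <- rep(seq_len(config$n_chains), each = config$n_samples)

  intercept <- beta[, 1]
  beta_std <- beta[, seq_len(px) + 1, drop = FALSE]
  colnames(beta_std) <- colnames(Xraw)
  beta_axis <- beta[, px + 1 + seq_len(rank), drop = FALSE]

  weights <- array(NA_real_, c(S, rank, q),
                   dimnames = list(NULL, NULL, colnames(dataset$volatiles)[seq_len(q)]))
  beta_axis_unaligned <- beta_axis
  if (rank > 0) {
    wm <- do.call(rbind, lapply(chains, `[[`, "weights"))
    for (k in seq_len(rank))
      weights[, k, ] <- wm[, (k - 1) * q + seq_len(q), drop = FALSE]
    # magnitude absorption changes no signs, so the unaligned slope keeps
    # the sampler's within-chain sign-switching, which carries the
    # evidence against a consistent direction of selection
    for (k in seq_len(rank))
      beta_axis_unaligned[, k] <- beta_axis[, k] *
        sqrt(rowSums(weights[, k, , drop = FALSE]^2, dims = 1))
    raw_weights <- weights
    ident <- identify_axes(beta_axis, weights)
    beta_axis <- ident$beta_axis; weights <- ident$weights
    # the two sign modes of the bilinear term are symmetric, so which one
    # a chain settles in is an initialization artifact; orient whole
    # chains (never individual draws) to the median aligned direction
    for (k in seq_len(rank)) {
      ref <- apply(weights[, k, , drop = FALSE], 3, stats::median)
      dots <- as.numeric(matrix(raw_weights[, k, ], ncol = length(ref)) %*% ref)
      for (ch in seq_len(config$n_chains)) {
        s_ch <- sign(sum(dots[chain_id == ch]))
        if (s_ch < 0)
          beta_axis_unaligned[chain_id == ch, k] <-
            -beta_axis_unaligned[chain_id == ch, k]
      }
    }
  }

  axis_scores <- array(NA_real_, c(S, rank, dataset$n))
  if (rank > 0)
    for (k in seq_len(rank))
      axis_scores[, k, ] <- weights[, k, ] %*% t(Zs)

  fit <- structure(list(
    intercept = intercept,
    beta_standard = sweep(beta_std, 2, x_scale, "/"),
    beta_standard_std = beta_std,
    beta_axis = beta_axis,
    beta_axis_unaligned = beta_axis_unaligned,
    weights = weights,
    sigma2 = sigma2,
    axis_scores = axis_scores,
    chain = chain_id,
    rank = rank,
    method = if (rank > 0) "rrr" else "mr",
    training = list(
      x_center = x_center, x_scale = x_scale,
      x_names = colnames(Xraw), x_roles = if (rank > 0)
        rep("standard", px) else c(rep("standard", ncol(dataset$standard_traits)),
                                   rep("volatile", ncol(dataset$volatiles))),
      z_center = z_center, z_scale = z_scale,
      z_names = colnames(dataset$volatiles)[seq_len(q)],
      standard_names = colnames(dataset$standard_traits),
      volatile_names = colnames(dataset$volatiles),
      n = dataset$n, dataset_id = dataset$dataset_id),
    config = config), class = "rrr_fit")

  fit$diagnostics <- fit_diagnostics(fit)
  bad <- fit$diagnostics$rhat[is.finite(fit$diagnostics$rhat)]
  if (length(bad) > 0 && max(bad) > 1.1)
    warning(sprintf("convergence warning for '%s': max split R-hat = %.3f",
                    dataset$dataset_id, max(bad)), call. = FALSE)
  fit
}

# Per-draw unit-norm rescaling (axis slope absorbs the magnitude) and
# iterative sign alignment to the element-wise median weight vector.
identify_axes <- function(beta_axis, weights) {
  S <- dim(weights)[1]; rank <- dim(weights)[2]
  for (k in seq_len(rank)) {
    nrm <- sqrt(rowSums(weights[, k, , drop = FALSE]^2, dims = 1))
    nrm <- pmax(nrm, .Machine$double.eps)
    weights[, k, ] <- weights[, k, ] / nrm
    beta_axis[, k] <- beta_axis[, k] * nrm
    for (pass in 1:25) {
      med <- apply(weights[, k, , drop = FALSE], 3, stats::median)
      flip <- as.numeric(matrix(weights[, k, ], ncol = length(med)) %*% med) < 0
      if (!any(flip)) break
      weights[flip, k, ] <- -weights[flip, k, , drop = FALSE]
      beta_axis[flip, k] <- -beta_axis[flip, k]
    }
  }
  list(beta_axis = beta_axis, weights = weights)
}

#' @export
print.rrr_fit <- function(x, ...) {
  cat(sprintf("rrr_fit (%s) on '%s': n = %d, %d standard covariate(s), rank %d\n",
              x$method, x$training$dataset_id, x$training$n,
              length(x$training$x_names), x$rank))
  cat(sprintf("  %d chains x %d draws; max split R-hat %.3f, min ESS %.0f\n",
              x$config$n_chains, x$config$n_samples,
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  if (x$rank > 0)
    cat(sprintf("  posterior mean axis slope(s): %s\n",
                paste(sprintf("%.3f", colMeans(x$beta_axis)), collapse = ", ")))
  invisible(x)
}

#' Posterior-mean predictions of relative fitness
#'
#' Applies the posterior-mean linear predictor to new individuals. New
#' volatiles are standardized with the means and SDs stored at fit time,
#' so predictions are valid for data not seen during fitting. Because the
#' predictor is linear in the parameters and back-projection is exact,
#' the result is invariant to the post-hoc sign/scale identification of
#' the axes.
#'
#' @param object An `rrr_fit`.
#' @param standard_traits Matrix with the training standard-trait columns.
#' @param volatiles Matrix with the training volatile columns.
#' @param ... Unused.
#' @return Numeric vector of posterior-mean predicted relative fitness.
#' @export
predict.rrr_fit <- function(object, standard_traits, volatiles, ...) {
  tr <- object$training
  X <- check_columns(standard_traits, tr$standard_names, "standard_traits")
  Z <- check_columns(volatiles, tr$volatile_names, "volatiles")
  if (nrow(X) != nrow(Z))
    stop("shape error: standard_traits and volatiles row counts differ",
         call. = FALSE)
  D <- if (object$method == "mr") cbind(X, Z) else X
  Ds <- sweep(sweep(D[, tr$x_names, drop = FALSE], 2, tr$x_center), 2,
              tr$x_scale, "/")
  pred <- mean(object$intercept) +
    as.numeric(Ds %*% colMeans(object$beta_standard_std))
  if (object$rank > 0) {
    Zs <- sweep(sweep(Z, 2, tr$z_center), 2, tr$z_scale, "/")
    # E[sum_k beta_k w_k] per volatile: exact posterior-mean projection
    bp <- back_project_draws(object)
    pred <- pred + as.numeric(Zs %*% colMeans(bp))
  }
  pred
}

check_columns <- function(m, expected, what) {
  m <- as.matrix(as.data.frame(m, check.names = FALSE))
  storage.mode(m) <- "double"
  if (is.null(colnames(m)) || !all(expected %in% colnames(m)))
    stop("shape error: ", what, " must contain columns ",
         paste(expected, collapse = ", "), call. = FALSE)
  m[, expected, drop = FALSE]
}

# --- convergence diagnostics ------------------------------------------

fit_diagnostics <- function(fit) {
  params <- list(sigma2 = fit$sigma2, `(Intercept)` = fit$intercept)
  for (j in seq_along(fit$training$x_names))
    params[[paste0("beta[", fit$training$x_names[j], "]")]] <-
      fit$beta_standard_std[, j]
  if (fit$rank > 0) {
    for (k in seq_len(fit$rank)) {
      params[[paste0("beta_axis[", k, "]")]] <- fit$beta_axis[, k]
      for (l in seq_len(dim(fit$weights)[3]))
        params[[paste0("w[", k, ",", dimnames(fit$weights)[[3]][l], "]")]] <-
          fit$weights[, k, l]
    }
  }
  res <- t(vapply(params, function(x)
    unlist(mcmc_diagnostics(x, fit$chain)), numeric(4)))
  data.frame(parameter = names(params), mean = res[, "mean"],
             sd = res[, "sd"], rhat = res[, "rhat"], ess = res[, "ess"],
             row.names = NULL)
}

#' Split-R-hat and effective sample size for one parameter
#'
#' Standard rank-free split-half potential scale reduction and an
#' autocorrelation-based effective sample size (paired-sum truncation of
#' the combined-chain autocorrelation series).
#'
#' @param x Numeric vector of posterior draws, chains stacked.
#' @param chain Integer chain id per draw.
#' @return A list with `mean`, `sd`, `rhat`, `ess`.
#' @export
mcmc_diagnostics <- function(x, chain = rep(1L, length(x))) {
  m <- split(x, chain)
  half <- floor(min(lengths(m)) / 2)
  mat <- do.call(cbind, lapply(m, function(v)
    cbind(v[seq_len(half)], v[half + seq_len(half)])))
  out <- list(mean = mean(x), sd = stats::sd(x))
  W <- mean(apply(mat, 2, stats::var))
  if (!is.finite(W) || W == 0) {
    out$rhat <- NA_real_; out$ess <- length(x)
    return(out)
  }
  nr <- nrow(mat)
  B <- nr * stats::var(colMeans(mat))
  var_plus <- (nr - 1) / nr * W + B / nr
  out$rhat <- sqrt(var_plus / W)

  lag_max <- min(nr - 1, 500)
  acov <- apply(mat, 2, function(v)
    stats::acf(v, lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1])
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # Geyer initial positive sequence on paired sums
  tau <- 1
  t <- 1
  while (t + 1 <= length(rho) - 1) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  out$ess <- max(1, length(x) / tau)
  out
}
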