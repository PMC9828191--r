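#' Posterior support for a selection gradient
#'
#' The probability that a parameter's sign matches its dominant posterior
#' sign: `max(P(draws > 0), P(draws < 0))`, with exact zeros split
#' equally between the two sides. Equals 0.5 when the posterior is
#' perfectly balanced around zero (no evidence of directional selection)
#' and 1 when the sign is certain.
#'
#' @param draws Numeric vector of posterior draws (length >= 2).
#' @return A probability in \[0.5, 1\].
#' @examples
#' posterior_support(c(-1, 1, 1, 1)) # 0.75
#' @export
posterior_support <- function(draws) {
  if (length(draws) < 2) stop("need at least 2 draws", call. = FALSE)
  p_pos <- mean(draws > 0) + 0.5 * mean(draws == 0)
  max(p_pos, 1 - p_pos)
}

#' Scaled selection gradients for standard traits and the composite axis
#'
#' Converts posterior draws into the reporting currency of selection
#' analysis. For each standard trait, per draw: the raw gradient
#' \eqn{\beta} (original measurement scale), the mean-scaled gradient
#' \eqn{\beta_\mu = \beta \times \bar{x}} (dimensionless, for ratio-scale
#' traits) and the variance-scaled gradient
#' \eqn{\beta_\sigma = \beta \times SD(x)} (change in relative fitness
#' per SD of trait). For the composite axis, \eqn{\beta_\sigma} is the
#' axis slope times the realized SD of that draw's axis scores;
#' mean-scaling is omitted because the axis is not on a ratio scale.
#' Draws are then summarized: posterior mean, posterior SD (the standard
#' error), equal-tailed 95% credible interval of \eqn{\beta_\sigma}, and
#' posterior support. SDs use the n-1 denominator throughout.
#'
#' @param fit An `rrr_fit`.
#' @param dataset The [selection_dataset()] the fit was made on. Used
#'   only for a consistency check; scaling constants come from the
#'   training statistics stored in the fit.
#' @return A `gradient_table` data frame with one row per covariate plus
#'   one per axis: columns `term`, `role`, `beta`, `se`, `beta_mu`,
#'   `beta_mu_se`, `beta_sigma`, `beta_sigma_se`, `lower95`, `upper95`
#'   (bounds for `beta_sigma`), `support`.
#' @export
scale_gradients <- function(fit, dataset = NULL) {
  stopifnot(inherits(fit, "rrr_fit"))
  check_fit_dataset(fit, dataset)
  tr <- fit$training
  rows <- lapply(seq_along(tr$x_names), function(j) {
    b_orig <- fit$beta_standard[, j]
    summarize_gradient(tr$x_names[j], tr$x_roles[j],
                       beta = b_orig,
                       beta_mu = b_orig * tr$x_center[j],
                       beta_sigma = fit$beta_standard_std[, j])
  })
  if (fit$rank > 0) {
    for (k in seq_len(fit$rank)) {
      sd_scores <- apply(fit$axis_scores[, k, , drop = FALSE], 1, stats::sd)
      b <- fit$beta_axis[, k]
      row <- summarize_gradient(axis_label(k, fit$rank), "axis",
                                beta = b, beta_mu = NULL,
                                beta_sigma = b * sd_scores)
      # the axis slope's sign is identified only jointly with the weights;
      # support uses the unaligned draws, whose sign-switching across the
      # bilinear model's two modes expresses directional uncertainty
      row$support <- posterior_support(fit$beta_axis_unaligned[, k])
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gradient_table", "data.frame")
  out
}

axis_label <- function(k, rank) if (rank == 1) "scent_axis" else
  paste0("scent_axis", k)

summarize_gradient <- function(term, role, beta, beta_mu, beta_sigma) {
  ci <- stats::quantile(beta_sigma, c(0.025, 0.975), names = FALSE)
  data.frame(term = term, role = role,
             beta = mean(beta), se = stats::sd(beta),
             beta_mu = if (is.null(beta_mu)) NA_real_ else mean(beta_mu),
             beta_mu_se = if (is.null(beta_mu)) NA_real_ else stats::sd(beta_mu),
             beta_sigma = mean(beta_sigma),
             beta_sigma_se = stats::sd(beta_sigma),
             lower95 = ci[1], upper95 = ci[2],
             support = posterior_support(beta),
             stringsAsFactors = FALSE)
}

#' Back-project axis selection onto the original volatiles
#'
#' Maps the selection gradient on each composite axis to implied
#' gradients on the original compounds through the axis weights,
#' \eqn{\beta^*_l = \sum_k w_{kl}\,\beta_{axis,k}}, computed per draw on
#' the standardized-volatile scale, then rescaled: dividing by each
#' volatile's training SD gives the raw gradient on the original
#' emission scale, and multiplying that by the volatile's training mean
#' gives the mean-scaled gradient (ratio-scale emission rates).
#'
#' @param fit An `rrr_fit` with at least one axis.
#' @param dataset Optional; consistency check only.
#' @return A `compound_gradient_table` data frame, one row per volatile:
#'   `compound`, `beta` (original scale), `se`, `beta_mu`, `beta_mu_se`,
#'   `beta_sigma` (standardized scale), `beta_sigma_se`, `support`.
#' @export
back_project <- function(fit, dataset = NULL) {
  stopifnot(inherits(fit, "rrr_fit"))
  if (fit$rank == 0)
    stop("not applicable: multiple-regression fits have no axis to back-project; use scale_gradients()",
         call. = FALSE)
  check_fit_dataset(fit, dataset)
  bp <- back_project_draws(fit)                    # S x q, standardized scale
  tr <- fit$training
  raw <- sweep(bp, 2, tr$z_scale, "/")             # original emission scale
  mu <- sweep(raw, 2, tr$z_center, "*")            # mean-scaled
  out <- data.frame(compound = tr$z_names,
                    beta = colMeans(raw), se = apply(raw, 2, stats::sd),
                    beta_mu = colMeans(mu), beta_mu_se = apply(mu, 2, stats::sd),
                    beta_sigma = colMeans(bp),
                    beta_sigma_se = apply(bp, 2, stats::sd),
                    support = apply(bp, 2, posterior_support),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dataset_id") <- tr$dataset_id
  class(out) <- c("compound_gradient_table", "data.frame")
  out
}

#' Per-draw back-projected gradients (standardized-volatile scale)
#'
#' The draw-level version of [back_project()]:
#' \eqn{\beta^*_l = \sum_k w_{kl}\beta_{axis,k}} for every retained draw.
#' Useful for Monte-Carlo-error computations on derived quantities.
#'
#' @param fit An `rrr_fit` with at least one axis.
#' @return An S x q matrix, columns named by volatile.
#' @export
back_project_draws <- function(fit) {
  stopifnot(inherits(fit, "rrr_fit"))
  if (fit$rank == 0)
    stop("not applicable: no axis in a multiple-regression fit", call. = FALSE)
  q <- dim(fit$weights)[3]
  bp <- matrix(0, nrow(fit$beta_axis), q,
               dimnames = list(NULL, dimnames(fit$weights)[[3]]))
  for (k in seq_len(fit$rank))
    bp <- bp + fit$weights[, k, , drop = TRUE] * fit$beta_axis[, k]
  bp
}

#' Export a gradient table to delimited text
#'
#' @param table A `gradient_table` or `compound_gradient_table`.
#' @param path Output path (`.tsv` for tab-separated, else comma).
#' @return `path`, invisibly.
#' @export
write_gradient_table <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_fit_dataset <- function(fit, dataset) {
  if (is.null(dataset)) return(invisible())
  stopifnot(inherits(dataset, "selection_dataset"))
  tr <- fit$training
  if (dataset$n != tr$n ||
      !identical(colnames(dataset$volatiles), tr$volatile_names) ||
      !identical(colnames(dataset$standard_traits), tr$standard_names))
    stop("shape error: dataset does not match the one the model was fitted on",
         call. = FALSE)
  invisible()
}
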