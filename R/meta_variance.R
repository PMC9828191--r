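#' Sampling-error-corrected among-dataset variance of selection gradients
#'
#' The moment estimator \eqn{\sigma^2_{\beta,c} = \sigma^2_\beta -
#' \overline{SE^2_\beta}}: the n-1 sample variance of gradient estimates
#' across datasets minus the mean of their sampling variances. In a
#' Bayesian fit the posterior variance of the gradient serves as the
#' squared standard error. The corrected variance may be negative (the
#' estimates vary less than their sampling error predicts); it is
#' reported as-is, and the companion SD is truncated at zero before the
#' square root.
#'
#' @param estimates Numeric vector of D >= 2 gradient estimates
#'   (posterior means), one per dataset.
#' @param sampling_variances Nonnegative numeric vector of the same
#'   length (posterior variances).
#' @return A list: `sigma_beta_c` (the corrected variance),
#'   `corrected_sd` (`sqrt(max(0, sigma_beta_c))`), `sigma2_among` (raw
#'   among-dataset variance), `mean_se2`, and `n_datasets`.
#' @examples
#' sigma_beta_c(c(0.1, 0.3), c(0.005, 0.015)) # corrected variance 0.01
#' @export
sigma_beta_c <- function(estimates, sampling_variances) {
  estimates <- as.numeric(estimates)
  sampling_variances <- as.numeric(sampling_variances)
  if (length(estimates) < 2)
    stop("insufficient datasets: need at least 2 gradient estimates",
         call. = FALSE)
  if (length(sampling_variances) != length(estimates))
    stop("estimates and sampling_variances must have equal length",
         call. = FALSE)
  if (any(sampling_variances < 0) || any(!is.finite(sampling_variances)) ||
      any(!is.finite(estimates)))
    stop("sampling variances must be finite and nonnegative", call. = FALSE)
  s2 <- stats::var(estimates)
  se2 <- mean(sampling_variances)
  corrected <- s2 - se2
  list(sigma_beta_c = corrected,
       corrected_sd = sqrt(max(0, corrected)),
       sigma2_among = s2, mean_se2 = se2,
       n_datasets = length(estimates))
}

#' Among-dataset variance of compound-specific selection gradients
#'
#' Applies [sigma_beta_c()] per compound across a collection of fitted
#' datasets, using the mean-scaled back-projected gradients (the scale on
#' which among-study dispersion reads as units of the strength of
#' selection on fitness itself). Compounds are matched by name; a
#' compound present in fewer than two tables is skipped with a message.
#' Also reports each compound's across-dataset mean gradient.
#'
#' @param tables A list of `compound_gradient_table` objects from
#'   [back_project()] (length >= 2). Names, or their `dataset_id`
#'   attributes, label the datasets.
#' @return A `meta_variance_table` data frame, one row per shared
#'   compound: `compound`, `n_datasets`, `mean_gradient`, `sigma2_among`,
#'   `mean_se2`, `sigma_beta_c`, `corrected_sd`.
#' @export
compound_variance_table <- function(tables) {
  if (length(tables) < 2)
    stop("insufficient datasets: need at least 2 fitted tables",
         call. = FALSE)
  stopifnot(all(vapply(tables, inherits, logical(1),
                       "compound_gradient_table")))
  all_names <- lapply(tables, function(t) t$compound)
  counts <- table(unlist(all_names))
  shared <- names(counts)[counts >= 2]
  skipped <- names(counts)[counts < 2]
  if (length(shared) == 0)
    stop("no compound is shared by at least two datasets", call. = FALSE)
  if (length(skipped) > 0)
    message("[rrsel] skipping compound(s) present in <2 datasets: ",
            paste(skipped, collapse = ", "))

  rows <- lapply(shared, function(cmp) {
    est <- numeric(0); se2 <- numeric(0)
    for (t in tables) {
      i <- match(cmp, t$compound)
      if (!is.na(i)) {
        est <- c(est, t$beta_mu[i])
        se2 <- c(se2, t$beta_mu_se[i]^2)
      }
    }
    v <- sigma_beta_c(est, se2)
    data.frame(compound = cmp, n_datasets = v$n_datasets,
               mean_gradient = mean(est), sigma2_among = v$sigma2_among,
               mean_se2 = v$mean_se2, sigma_beta_c = v$sigma_beta_c,
               corrected_sd = v$corrected_sd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$compound), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("meta_variance_table", "data.frame")
  out
}

#' Two-panel plot of among-dataset variation in compound gradients
#'
#' Upper panel: per-dataset mean-scaled gradients per compound with a
#' "+" at each compound's across-dataset mean. Lower panel: the
#' sampling-error-corrected SD per compound.
#'
#' @param tables The list of `compound_gradient_table` objects passed to
#'   [compound_variance_table()].
#' @param meta Optional precomputed `meta_variance_table`.
#' @return `meta`, invisibly.
#' @export
plot_meta_variance <- function(tables, meta = NULL) {
  if (is.null(meta)) meta <- compound_variance_table(tables)
  old <- graphics::par(mfrow = c(2, 1), mar = c(7, 4, 1, 1))
  on.exit(graphics::par(old))
  k <- nrow(meta)
  est <- lapply(meta$compound, function(cmp)
    unlist(lapply(tables, function(t) t$beta_mu[match(cmp, t$compound)])))
  ylim <- range(unlist(est), na.rm = TRUE)
  graphics::plot(NA, xlim = c(0.5, k + 0.5), ylim = ylim, xaxt = "n",
                 xlab = "", ylab = "mean-scaled gradient")
  for (i in seq_len(k))
    graphics::points(rep(i, length(est[[i]])), est[[i]], pch = 16,
                     col = grDevices::grey(0.5, 0.6))
  graphics::points(seq_len(k), meta$mean_gradient, pch = 3, cex = 1.4)
  graphics::abline(h = 0, lty = 3)
  graphics::axis(1, at = seq_len(k), labels = meta$compound, las = 2,
                 cex.axis = 0.7)
  graphics::barplot(meta$corrected_sd, names.arg = meta$compound, las = 2,
                    ylab = "corrected SD", cex.names = 0.7)
  invisible(meta)
}
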