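# Short-chain MCMC settings for unit tests; acceptance checks use
# criterion-scale settings defined where they run.
quick_config <- function(seed = 1, ...) {
  rrr_config(n_warmup = 200, n_samples = 200, seed = seed, ...)
}

quick_sim <- function(n = 80, n_volatiles = 6, n_standard = 2, seed = 1, ...) {
  simulate_dataset(simulation_spec(n = n, n_volatiles = n_volatiles,
                                   n_standard = n_standard, seed = seed, ...))
}

# A deterministic two-draw fit object with known parameters, for
# hand-arithmetic checks of scaling, back-projection and prediction.
# Both draws are identical so posterior means equal the given values.
manual_fit <- function(intercept = 1, beta_std_orig = 0.5, x_center = 10,
                       x_scale = 2, beta_axis = 0.4,
                       w = c(1, 0, 0), z_center = c(1, 2, 4),
                       z_scale = c(0.5, 1, 2), n = 4,
                       axis_score_sd = 1) {
  q <- length(w)
  S <- 2
  scores <- matrix(rep(seq_len(n) - mean(seq_len(n)), each = S), S)
  scores <- scores / stats::sd(scores[1, ]) * axis_score_sd
  structure(list(
    intercept = rep(intercept, S),
    beta_standard = matrix(rep(beta_std_orig / x_scale, S), S,
                           dimnames = list(NULL, "trait_a")),
    beta_standard_std = matrix(rep(beta_std_orig, S), S,
                               dimnames = list(NULL, "trait_a")),
    beta_axis = matrix(rep(beta_axis, S), S),
    beta_axis_unaligned = matrix(rep(beta_axis, S), S),
    weights = array(rep(w, each = S), c(S, 1, q),
                    dimnames = list(NULL, NULL, paste0("vol_", seq_len(q)))),
    sigma2 = rep(0.01, S),
    axis_scores = array(scores, c(S, 1, n)),
    chain = c(1L, 2L),
    rank = 1L, method = "rrr",
    training = list(x_center = c(trait_a = x_center),
                    x_scale = c(trait_a = x_scale),
                    x_names = "trait_a", x_roles = "standard",
                    z_center = stats::setNames(z_center, paste0("vol_", seq_len(q))),
                    z_scale = stats::setNames(z_scale, paste0("vol_", seq_len(q))),
                    z_names = paste0("vol_", seq_len(q)),
                    standard_names = "trait_a",
                    volatile_names = paste0("vol_", seq_len(q)),
                    n = n, dataset_id = "manual"),
    config = rrr_config(seed = 1),
    diagnostics = data.frame()), class = "rrr_fit")
}

write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  path
}
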