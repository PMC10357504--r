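## Small fixtures built in code.

## deterministic toy summary dataset with known matrices
toy_summary <- function(n = 3, p = 2, q = 2, seed = 99) {
  set.seed(seed)
  summary_data(beta_x = matrix(round(rnorm(n * p), 3), n, p),
               se_x = matrix(round(runif(n * p, 0.1, 0.4), 3), n, p),
               beta_y = matrix(round(rnorm(n * q), 3), n, q),
               se_y = matrix(round(runif(n * q, 0.1, 0.4), 3), n, q))
}

## a standardized_data object built directly from matrices (unit weights)
as_std <- function(X, Y) {
  structure(list(beta_x_std = X, beta_y_std = Y,
                 weights = rep(1, nrow(X)),
                 standardization_mode = "none",
                 variant_ids = paste0("v", seq_len(nrow(X))),
                 exposure_names = paste0("X", seq_len(ncol(X))),
                 outcome_names = paste0("Y", seq_len(ncol(Y))),
                 n = nrow(X), p = ncol(X), q = ncol(Y)),
            class = "standardized_data")
}

## mean of the off-diagonal entries of a square matrix
offdiag_mean <- function(m) mean(m[upper.tri(m)])

## small scenario config for fast MCMC tests; caps the pathway genetic
## ratio when the sample is too small for the full-study default
fast_cfg <- function(scenario, seed, N = 20000, ...) {
  dots <- list(...)
  nv <- if (is.null(dots$n_variants)) 100 else dots$n_variants
  if (is.null(dots$a_genetic_ratio))
    dots$a_genetic_ratio <- min(25, 0.4 * N / (2 * nv))
  do.call(scenario_config,
          c(list(scenario = scenario, n_individuals = N, seed = seed), dots))
}
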