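#' Posterior summaries of a multi-response MR fit
#'
#' Computes the marginal posterior probability of inclusion (mPPI) for every
#' exposure-outcome pair, the edge posterior probability of inclusion (ePPI)
#' for every outcome pair, posterior means and credible intervals of the
#' direct causal effects (both unconditional, with zeros when excluded, and
#' conditional on inclusion), and the residual partial correlations derived
#' from each draw of the correlation matrix.
#'
#' @param object an `mr2_fit`.
#' @param level credible level (default 0.95).
#' @param ... unused.
#' @return An object of class `mr2_summary` with elements `mppi` (q x p),
#'   `eppi` (q x q), `theta_mean`, `theta_ci_low`, `theta_ci_high`,
#'   `theta_cond_mean`, `partial_corr_mean`, `partial_corr_ci_low`,
#'   `partial_corr_ci_high`, `delta2_mean`, `credible_level`.
#' @export
summary.mr2_fit <- function(object, level = 0.95, ...) {
  if (object$n_draws < 1) stop("no stored draws")
  if (object$n_draws < 100)
    warning("fewer than 100 stored draws; summaries will be noisy")
  d <- object$draws
  q <- object$q; p <- object$p
  alpha <- (1 - level) / 2

  mppi <- apply(d$gamma, c(2, 3), mean)
  eppi <- apply(d$graph, c(2, 3), mean); diag(eppi) <- 1

  theta_mean <- apply(d$theta, c(2, 3), mean)
  theta_lo <- apply(d$theta, c(2, 3), stats::quantile, probs = alpha)
  theta_hi <- apply(d$theta, c(2, 3), stats::quantile, probs = 1 - alpha)
  cond_mean <- matrix(NA_real_, q, p)
  for (k in seq_len(q)) for (j in seq_len(p)) {
    inc <- d$gamma[, k, j] == 1
    if (any(inc)) cond_mean[k, j] <- mean(d$theta[inc, k, j])
  }

  ## partial correlations: -P_kl / sqrt(P_kk P_ll) from each draw's R
  pc <- array(0, c(object$n_draws, q, q))
  for (i in seq_len(object$n_draws)) {
    P <- chol2inv(chol(d$R[i, , ]))
    s <- sqrt(diag(P))
    pc[i, , ] <- -P / outer(s, s)
  }
  pc_mean <- apply(pc, c(2, 3), mean); diag(pc_mean) <- 1
  pc_lo <- apply(pc, c(2, 3), stats::quantile, probs = alpha)
  pc_hi <- apply(pc, c(2, 3), stats::quantile, probs = 1 - alpha)
  diag(pc_lo) <- diag(pc_hi) <- 1

  dn <- list(object$outcome_names, object$exposure_names)
  dimnames(mppi) <- dimnames(theta_mean) <- dimnames(theta_lo) <-
    dimnames(theta_hi) <- dimnames(cond_mean) <- dn
  dno <- list(object$outcome_names, object$outcome_names)
  dimnames(eppi) <- dimnames(pc_mean) <- dimnames(pc_lo) <-
    dimnames(pc_hi) <- dno

  structure(list(mppi = mppi, eppi = eppi,
                 theta_mean = theta_mean,
                 theta_ci_low = theta_lo, theta_ci_high = theta_hi,
                 theta_cond_mean = cond_mean,
                 partial_corr_mean = pc_mean,
                 partial_corr_ci_low = pc_lo,
                 partial_corr_ci_high = pc_hi,
                 R_mean = apply(d$R, c(2, 3), mean),
                 delta2_mean = colMeans(d$delta2),
                 credible_level = level,
                 n_draws = object$n_draws),
            class = "mr2_summary")
}

#' @export
print.mr2_summary <- function(x, digits = 3, ...) {
  cat("Marginal posterior probabilities of inclusion (mPPI):\n")
  print(round(x$mppi, digits))
  cat("\nEdge posterior probabilities of inclusion (ePPI):\n")
  print(round(x$eppi, digits))
  cat("\nPosterior mean direct effects (unconditional):\n")
  print(round(x$theta_mean, digits))
  invisible(x)
}

#' Joint posterior probability of inclusion of an exposure for several outcomes
#'
#' Fraction of MCMC draws in which the exposure is selected simultaneously
#' for every outcome in the set — the evidence that the exposure is a shared
#' cause of that group of outcomes.
#'
#' @param fit an `mr2_fit`.
#' @param exposure exposure index or name.
#' @param outcomes vector of two or more outcome indices or names.
#' @return A probability in \[0, 1\], never exceeding the smallest mPPI of
#'   the pairs involved.
#' @export
jppi <- function(fit, exposure, outcomes) {
  stopifnot(inherits(fit, "mr2_fit"))
  if (is.character(exposure)) exposure <- match(exposure, fit$exposure_names)
  if (is.character(outcomes)) outcomes <- match(outcomes, fit$outcome_names)
  if (anyNA(exposure) || anyNA(outcomes)) stop("unknown exposure or outcome")
  if (length(outcomes) < 2)
    stop("jppi needs two or more outcomes; use the mPPI for a single outcome")
  inc <- fit$draws$gamma[, outcomes, exposure, drop = FALSE]
  mean(apply(inc == 1, 1, all))
}

## two-component Beta mixture log likelihood on clamped PPIs
.beta_mix_ll <- function(x, par) {
  f0 <- stats::dbeta(x, par$a0, par$b0)
  f1 <- stats::dbeta(x, par$a1, par$b1)
  sum(log(par$pi0 * f0 + (1 - par$pi0) * f1))
}

.beta_mle <- function(x, w) {
  ## weighted Beta maximum likelihood on the log-parameter scale
  nll <- function(lp) {
    a <- exp(lp[1]); b <- exp(lp[2])
    -sum(w * stats::dbeta(x, a, b, log = TRUE))
  }
  m <- sum(w * x) / sum(w)
  v <- max(sum(w * (x - m)^2) / sum(w), 1e-6)
  c0 <- max(m * (1 - m) / v - 1, 0.1)
  st <- log(pmax(c(m * c0, (1 - m) * c0), 1e-3))
  fit <- tryCatch(stats::optim(st, nll, method = "Nelder-Mead"),
                  error = function(e) NULL)
  if (is.null(fit)) exp(st) else exp(fit$par)
}

#' Bayesian FDR selection from posterior inclusion probabilities
#'
#' Clusters the PPIs (mPPIs or ePPIs) into a low and a high component with a
#' two-component Beta mixture fitted by EM (with random restarts), computes
#' each PPI's posterior probability of belonging to the low ("null")
#' component, and selects the largest set of PPIs whose average null
#' probability does not exceed `fdr_level`. When the mixture degenerates to
#' a single cluster, selection falls back to the median-probability-model
#' rule (threshold 0.5) with a warning.
#'
#' @param ppis numeric vector of probabilities in \[0, 1\] (at least 8).
#' @param fdr_level target Bayesian FDR (default 0.05).
#' @param n_restarts EM restarts (default 10).
#' @param seed RNG seed for the restarts.
#' @return An object of class `mr2_selection`: `selected_mask` (logical,
#'   same length/shape as `ppis`), `ppi_threshold`, `fdr_level`,
#'   `mixture_params`, and `null_prob` (per-PPI posterior null weight).
#' @export
fdr_select <- function(ppis, fdr_level = 0.05, n_restarts = 10, seed = 1) {
  shape <- dim(ppis)
  x_raw <- as.vector(ppis)
  if (any(x_raw < 0 | x_raw > 1, na.rm = TRUE)) stop("ppis must lie in [0, 1]")
  if (length(x_raw) < 8) stop("need at least 8 PPIs to fit the mixture")
  x <- pmin(pmax(x_raw, 1e-4), 1 - 1e-4)

  fallback <- function(msg) {
    warning(msg, "; falling back to the 0.5 median-probability rule")
    mask <- x_raw >= 0.5
    structure(list(selected_mask = .reshape(mask, shape),
                   ppi_threshold = 0.5, fdr_level = fdr_level,
                   mixture_params = NULL,
                   null_prob = as.numeric(!mask)),
              class = "mr2_selection")
  }
  if (stats::sd(x) < 1e-8) return(fallback("all PPIs identical"))

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  best <- NULL; best_ll <- -Inf
  for (r in seq_len(n_restarts)) {
    thr <- stats::runif(1, stats::quantile(x, 0.2), stats::quantile(x, 0.8))
    z <- as.numeric(x >= thr)
    if (sum(z) == 0 || sum(z) == length(z)) next
    par <- list(pi0 = mean(z == 0))
    ab0 <- .beta_mle(x, 1 - z); ab1 <- .beta_mle(x, z)
    par$a0 <- ab0[1]; par$b0 <- ab0[2]; par$a1 <- ab1[1]; par$b1 <- ab1[2]
    ll_old <- -Inf
    for (em in 1:100) {
      f0 <- par$pi0 * stats::dbeta(x, par$a0, par$b0)
      f1 <- (1 - par$pi0) * stats::dbeta(x, par$a1, par$b1)
      w0 <- f0 / (f0 + f1)
      if (anyNA(w0)) break
      par$pi0 <- mean(w0)
      ab0 <- .beta_mle(x, w0); ab1 <- .beta_mle(x, 1 - w0)
      par$a0 <- ab0[1]; par$b0 <- ab0[2]; par$a1 <- ab1[1]; par$b1 <- ab1[2]
      ll <- .beta_mix_ll(x, par)
      if (!is.finite(ll) || abs(ll - ll_old) < 1e-6) break
      ll_old <- ll
    }
    ll <- tryCatch(.beta_mix_ll(x, par), error = function(e) -Inf)
    if (is.finite(ll) && ll > best_ll) { best_ll <- ll; best <- par }
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  if (is.null(best)) return(fallback("mixture fit failed"))

  ## label the component with the smaller mean as null
  m0 <- best$a0 / (best$a0 + best$b0); m1 <- best$a1 / (best$a1 + best$b1)
  if (m0 > m1) best <- list(pi0 = 1 - best$pi0, a0 = best$a1, b0 = best$b1,
                            a1 = best$a0, b1 = best$b0)
  if (abs(m0 - m1) < 0.05) return(fallback("mixture components not separated"))

  f0 <- best$pi0 * stats::dbeta(x, best$a0, best$b0)
  f1 <- (1 - best$pi0) * stats::dbeta(x, best$a1, best$b1)
  null_prob <- f0 / (f0 + f1)

  ## largest set, in decreasing PPI order, with mean null prob <= fdr_level
  ord <- order(x, decreasing = TRUE)
  cum_fdr <- cumsum(null_prob[ord]) / seq_along(ord)
  n_sel <- max(c(0, which(cum_fdr <= fdr_level)))
  mask <- rep(FALSE, length(x))
  if (n_sel > 0) mask[ord[seq_len(n_sel)]] <- TRUE
  thr <- if (n_sel > 0) min(x_raw[mask]) else Inf

  structure(list(selected_mask = .reshape(mask, shape),
                 ppi_threshold = thr, fdr_level = fdr_level,
                 mixture_params = best, null_prob = null_prob),
            class = "mr2_selection")
}

.reshape <- function(v, shape) {
  if (is.null(shape)) v else array(v, shape)
}

#' Conditional predictive ordinate outlier diagnostics
#'
#' The conditional predictive ordinate of variant i is the harmonic mean
#' over the stored draws of its per-variant observation density, an
#' importance-sampling estimate of the leave-one-out predictive density
#' f(beta_Yi | data without i). Small values flag outlying or
#' high-leverage instruments ("local" pleiotropy); the scaled CPO divides
#' by the maximum across variants and variants below `threshold` are
#' flagged. The intended workflow is flag, remove, refit.
#'
#' @param fit an `mr2_fit`.
#' @param data the `standardized_data` the model was fitted to.
#' @param threshold scaled-CPO flagging threshold (default 0.01).
#' @return An object of class `mr2_cpo`: `cpo`, `scaled_cpo`,
#'   `outlier_mask`, `threshold`.
#' @export
compute_cpo <- function(fit, data, threshold = 0.01) {
  stopifnot(inherits(fit, "mr2_fit"), inherits(data, "standardized_data"))
  Y <- data$beta_y_std; X <- data$beta_x_std
  n <- nrow(Y); q <- ncol(Y)
  if (fit$n != n || fit$p != ncol(X) || fit$q != q)
    stop("fit and data dimensions disagree")
  M <- fit$n_draws
  neg_ll <- matrix(0, n, M)     # -log f(y_i | state_m)
  for (m in seq_len(M)) {
    d2 <- fit$draws$delta2[m, ]
    Sigma <- sqrt(d2) * t(sqrt(d2) * t(fit$draws$R[m, , ]))
    ch <- chol(Sigma)
    Em <- Y - X %*% t(fit$draws$theta[m, , ]) -
      matrix(fit$draws$mu[m, ], n, q, byrow = TRUE)
    Zm <- t(backsolve(ch, t(Em), transpose = TRUE))
    ll_i <- -0.5 * q * log(2 * pi) - sum(log(diag(ch))) - 0.5 * rowSums(Zm^2)
    neg_ll[, m] <- -ll_i
  }
  ## log CPO_i = log M - logsumexp_m(-ll_im)
  mx <- apply(neg_ll, 1, max)
  lse <- mx + log(rowSums(exp(neg_ll - mx)))
  if (any(!is.finite(lse)))
    warning("numerically degenerate densities in CPO; results may be unstable")
  log_cpo <- log(M) - lse
  cpo <- exp(log_cpo)
  scaled <- exp(log_cpo - max(log_cpo))
  structure(list(cpo = cpo, scaled_cpo = scaled,
                 outlier_mask = scaled < threshold, threshold = threshold,
                 variant_ids = data$variant_ids),
            class = "mr2_cpo")
}
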