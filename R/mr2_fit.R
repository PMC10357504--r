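#' Prior configuration for the multi-response MR sampler
#'
#' @param slab_variance variance of the Gaussian slab on a nonzero direct
#'   effect (standardized scale; default 1).
#' @param inclusion_a,inclusion_b Beta hyperparameters of the common
#'   exposure-inclusion probability, marginalized analytically
#'   (beta-binomial prior on the selection matrix; default Beta(1, 1)).
#' @param hiw_df hyper-inverse Wishart degrees of freedom d > 2 (default 3).
#' @param hiw_scale scalar tau: HIW scale matrix is tau * I (default 1).
#' @param edge_prior Bernoulli prior probability of each residual-graph edge
#'   (default 0.5).
#' @param intercept_variance prior variance of the response intercepts when
#'   enabled (default 100).
#' @return An object of class `mr2_prior`.
#' @export
mr2_prior <- function(slab_variance = 1, inclusion_a = 1, inclusion_b = 1,
                      hiw_df = 3, hiw_scale = 1, edge_prior = 0.5,
                      intercept_variance = 100) {
  stopifnot(slab_variance > 0, inclusion_a > 0, inclusion_b > 0,
            hiw_df > 2, hiw_scale > 0,
            edge_prior >= 0, edge_prior <= 1, intercept_variance > 0)
  structure(list(slab_variance = slab_variance, inclusion_a = inclusion_a,
                 inclusion_b = inclusion_b, hiw_df = hiw_df,
                 hiw_scale = hiw_scale, edge_prior = edge_prior,
                 intercept_variance = intercept_variance),
            class = "mr2_prior")
}

#' Multivariate Gaussian log likelihood of a multi-response MR state
#'
#' Sum over variants of the q-variate Gaussian log density of the outcome
#' associations with mean `mu + Theta beta_X` and covariance
#' `D^{1/2} R D^{1/2}`, `D = diag(delta2)`.
#'
#' @param theta q x p effect matrix.
#' @param R q x q residual correlation matrix.
#' @param delta2 length-q overdispersion vector.
#' @param data a `standardized_data` object (see [ivw_standardize()]).
#' @param mu optional length-q intercept vector (default zero).
#' @return The log likelihood (a scalar).
#' @export
mr2_log_likelihood <- function(theta, R, delta2, data, mu = NULL) {
  stopifnot(inherits(data, "standardized_data"))
  Y <- data$beta_y_std; X <- data$beta_x_std
  n <- nrow(Y); q <- ncol(Y)
  if (is.null(mu)) mu <- rep(0, q)
  Sigma <- sqrt(delta2) * t(sqrt(delta2) * t(R))
  ch <- tryCatch(chol(Sigma), error = function(e)
    stop("residual covariance is not positive definite; state: delta2 = ",
         paste(signif(delta2, 4), collapse = ", ")))
  E <- Y - X %*% t(theta)
  E <- sweep(E, 2, mu)
  Z <- E %*% chol2inv(ch) # Sigma^-1 E'
  -0.5 * n * q * log(2 * pi) - n * sum(log(diag(ch))) -
    0.5 * sum(E * Z)
}

## conditionally marginalized log "model score" of an active set A for
## response k: -|A|/2 log tau - 1/2 log|P_A| + 1/2 b_A' P_A^-1 b_A
## with P_A = Omega_kk (X'X)_A + I/tau. Returns also the Cholesky factor
## and mean needed to draw theta_A from its full conditional.
.sel_score <- function(A, XtX, b, okk, tau) {
  if (length(A) == 0)
    return(list(score = 0, chol = NULL, mean = numeric(0)))
  P <- okk * XtX[A, A, drop = FALSE]
  diag(P) <- diag(P) + 1 / tau + 1e-8
  ch <- chol(P)
  u <- backsolve(ch, b[A], transpose = TRUE)
  list(score = -0.5 * length(A) * log(tau) - sum(log(diag(ch))) +
         0.5 * sum(u^2),
       chol = ch, mean = backsolve(ch, u))
}

.draw_block <- function(sc) {
  if (is.null(sc$chol)) return(numeric(0))
  sc$mean + backsolve(sc$chol, stats::rnorm(length(sc$mean)))
}

#' Fit the multi-response Mendelian randomization model by MCMC
#'
#' Sparse seemingly-unrelated-regression sampler: each outcome's vector of
#' direct causal effects carries a spike-and-slab prior (point mass at zero
#' vs Gaussian slab) with a beta-binomial prior on the inclusion
#' indicators, and the residual covariance across outcomes carries a
#' hyper-inverse Wishart prior restricted to decomposable graphs, giving
#' exact zeros in the residual precision off the estimated graph.
#'
#' One sweep cycles: (i) a Metropolis-Hastings add/delete/swap move on the
#' inclusion indicators of each response, with the affected effects proposed
#' from their exact Gaussian full conditional so they are implicitly
#' marginalized out of the acceptance ratio; (ii) a Gibbs refresh of all
#' active effects; (iii) an optional Gibbs update of response intercepts;
#' (iv) a single-edge Metropolis-Hastings move on the residual graph using
#' the closed-form hyper-inverse Wishart marginal likelihood of the current
#' residuals (non-decomposable proposals are rejected outright); and (v) a
#' draw of the residual covariance from its clique-factorized full
#' conditional, renormalized into a correlation matrix `R` and
#' overdispersions `delta2`.
#'
#' @param data a `standardized_data` object from [ivw_standardize()].
#' @param prior an [mr2_prior()].
#' @param n_iter total MCMC sweeps (default 15000).
#' @param n_burnin burn-in sweeps discarded (default 5000).
#' @param thin keep every `thin`-th post-burn-in draw (default 1).
#' @param seed integer seed; runs with equal seeds are identical.
#' @param intercepts include response-specific intercepts mu (default
#'   `FALSE`, the standard MR convention).
#' @param fix_gamma optional q x p 0/1 matrix freezing the selection
#'   indicators (no selection moves; effects still sampled).
#' @param fix_graph optional adjacency matrix freezing the residual graph.
#' @param verbose print progress every 1000 sweeps.
#' @return An object of class `mr2_fit` holding post-burn-in draws
#'   (`gamma`, `theta`, `R`, `graph`, `delta2`, `mu`, `loglik` as arrays
#'   with the draw index first), acceptance-rate logs per move type, and
#'   the call configuration.
#' @export
fit_mr2 <- function(data, prior = mr2_prior(), n_iter = 15000,
                    n_burnin = 5000, thin = 1, seed = 1,
                    intercepts = FALSE, fix_gamma = NULL, fix_graph = NULL,
                    verbose = FALSE) {
  stopifnot(inherits(data, "standardized_data"), inherits(prior, "mr2_prior"))
  Y <- data$beta_y_std; X <- data$beta_x_std
  n <- nrow(Y); q <- ncol(Y); p <- ncol(X)
  if (n < 3) stop("need at least 3 variants")
  if (anyNA(Y) || anyNA(X)) stop("missing values in standardized data")
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter")
  if (n <= q * (p + 1) + q * (q - 1) / 2)
    warning("few instruments: n <= q(p+1) + q(q-1)/2; estimates of the ",
            "residual correlation may be weakly identified")
  set.seed(seed)

  tau <- prior$slab_variance
  a_in <- prior$inclusion_a; b_in <- prior$inclusion_b
  Dpr <- diag(prior$hiw_scale, q)
  npair <- q * (q - 1) / 2

  ## state
  gamma <- if (is.null(fix_gamma)) matrix(0L, q, p) else
    (as.matrix(fix_gamma) != 0) * 1L
  theta <- matrix(0, q, p)
  mu <- rep(0, q)
  adj <- if (is.null(fix_graph)) matrix(0L, q, q) else
    (as.matrix(fix_graph) != 0) * 1L
  diag(adj) <- 0L
  if (!is_decomposable(adj)) stop("fix_graph must be decomposable")
  Sigma <- diag(apply(Y, 2, stats::var), q)
  Omega <- diag(1 / diag(Sigma), q)
  XtX <- crossprod(X)
  E <- Y - X %*% t(theta)

  log_bb_prior <- function(s) lbeta(a_in + s, b_in + p * q - s)
  log_edge_prior <- function(ne) {
    if (prior$edge_prior == 0) return(if (ne == 0) 0 else -Inf)
    if (prior$edge_prior == 1) return(if (ne == npair) 0 else -Inf)
    ne * log(prior$edge_prior) + (npair - ne) * log(1 - prior$edge_prior)
  }

  edge_pairs <- .edge_pairs(q)
  n_keep <- floor((n_iter - n_burnin) / thin)
  draws <- list(gamma = array(0L, c(n_keep, q, p)),
                theta = array(0, c(n_keep, q, p)),
                R = array(0, c(n_keep, q, q)),
                graph = array(0L, c(n_keep, q, q)),
                delta2 = matrix(0, n_keep, q),
                mu = matrix(0, n_keep, q),
                loglik = numeric(n_keep))
  acc <- c(add = 0, delete = 0, swap = 0, graph = 0)
  att <- c(add = 0, delete = 0, swap = 0, graph = 0)

  sel_b <- function(k) {
    ## b_j = sum_i x_ij (Omega_kk (y - mu)_ik + sum_{l != k} Omega_kl e_il)
    r <- Omega[k, k] * (Y[, k] - mu[k])
    if (q > 1) {
      Em <- E[, -k, drop = FALSE]
      if (intercepts) Em <- sweep(Em, 2, mu[-k])
      r <- r + Em %*% Omega[-k, k, drop = FALSE]
    }
    crossprod(X, r)
  }

  for (it in seq_len(n_iter)) {
    ## (i) selection moves
    if (is.null(fix_gamma)) {
      for (k in sample.int(q)) {
        A <- which(gamma[k, ] == 1L)
        nA <- length(A)
        types <- c(if (nA < p) "add", if (nA > 0) "delete",
                   if (nA > 0 && nA < p) "swap")
        type <- if (length(types) == 1) types else sample(types, 1)
        zero <- which(gamma[k, ] == 0L)
        if (type == "add") {
          j_in <- if (length(zero) == 1) zero else sample(zero, 1)
          A2 <- sort(c(A, j_in))
          ## forward: choose add (1/|types|) then j (1/n0);
          ## reverse: delete from |A|+1 actives under the new type set
          nA2 <- nA + 1
          types2 <- length(c(if (nA2 < p) "add", "delete",
                             if (nA2 < p) "swap"))
          lq <- (-log(types2) - log(nA2)) - (-log(length(types)) - log(length(zero)))
          lpr <- log_bb_prior(sum(gamma) + 1) - log_bb_prior(sum(gamma))
        } else if (type == "delete") {
          j_out <- if (nA == 1) A else sample(A, 1)
          A2 <- setdiff(A, j_out)
          nA2 <- nA - 1
          types2 <- length(c("add", if (nA2 > 0) "delete",
                             if (nA2 > 0 && nA2 < p) "swap"))
          lq <- (-log(types2) - log(length(zero) + 1)) -
            (-log(length(types)) - log(nA))
          lpr <- log_bb_prior(sum(gamma) - 1) - log_bb_prior(sum(gamma))
        } else {
          j_out <- if (nA == 1) A else sample(A, 1)
          j_in <- if (length(zero) == 1) zero else sample(zero, 1)
          A2 <- sort(c(setdiff(A, j_out), j_in))
          lq <- 0   # same counts both ways
          lpr <- 0
        }
        b <- sel_b(k)
        sc1 <- .sel_score(A, XtX, b, Omega[k, k], tau)
        sc2 <- .sel_score(A2, XtX, b, Omega[k, k], tau)
        att[type] <- att[type] + 1
        if (log(stats::runif(1)) < sc2$score - sc1$score + lpr + lq) {
          acc[type] <- acc[type] + 1
          gamma[k, ] <- 0L; gamma[k, A2] <- 1L
          theta[k, ] <- 0
          theta[k, A2] <- .draw_block(sc2)
          E[, k] <- Y[, k] - X %*% theta[k, ]
        }
      }
    }

    ## (ii) Gibbs refresh of active effects
    for (k in seq_len(q)) {
      A <- which(gamma[k, ] == 1L)
      if (length(A) == 0) { theta[k, ] <- 0; E[, k] <- Y[, k]; next }
      b <- sel_b(k)
      sc <- .sel_score(A, XtX, b, Omega[k, k], tau)
      theta[k, ] <- 0
      theta[k, A] <- .draw_block(sc)
      E[, k] <- Y[, k] - X %*% theta[k, ]
    }

    ## (iii) intercepts
    if (intercepts) {
      Prec <- n * Omega + diag(1 / prior$intercept_variance, q)
      chP <- chol(Prec)
      rhs <- Omega %*% colSums(E)
      mmean <- backsolve(chP, backsolve(chP, rhs, transpose = TRUE))
      mu <- as.vector(mmean + backsolve(chP, stats::rnorm(q)))
    }
    Ec <- if (intercepts) sweep(E, 2, mu) else E
    S <- crossprod(Ec)

    ## (iv) residual-graph move with the covariance integrated out
    if (q > 1 && is.null(fix_graph)) {
      pick <- edge_pairs[sample.int(nrow(edge_pairs), 1), ]
      adj2 <- adj
      adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <-
        1L - adj2[pick[1], pick[2]]
      att["graph"] <- att["graph"] + 1
      if (is_decomposable(adj2)) {
        lr <- hiw_log_marginal(S, n, adj2, prior$hiw_df, Dpr) -
          hiw_log_marginal(S, n, adj, prior$hiw_df, Dpr) +
          log_edge_prior(sum(adj2) / 2) - log_edge_prior(sum(adj) / 2)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          adj <- adj2
          acc["graph"] <- acc["graph"] + 1
        }
      }
    }

    ## (v) covariance from its HIW full conditional
    Sigma <- rhiw(prior$hiw_df + n, Dpr + S, adj)
    Omega <- chol2inv(chol(Sigma))
    delta2 <- diag(Sigma)
    R <- Sigma / sqrt(outer(delta2, delta2))

    if (it > n_burnin && (it - n_burnin) %% thin == 0) {
      d <- (it - n_burnin) %/% thin
      draws$gamma[d, , ] <- gamma
      draws$theta[d, , ] <- theta
      draws$R[d, , ] <- R
      draws$graph[d, , ] <- adj
      draws$delta2[d, ] <- delta2
      draws$mu[d, ] <- mu
      draws$loglik[d] <- mr2_log_likelihood(theta, R, delta2, data, mu)
    }
    if (verbose && it %% 1000 == 0)
      message("sweep ", it, " / ", n_iter)
  }

  structure(list(draws = draws, n_draws = n_keep,
                 acceptance = ifelse(att > 0, acc / att, NA_real_),
                 attempts = att,
                 exposure_names = data$exposure_names,
                 outcome_names = data$outcome_names,
                 n = n, p = p, q = q,
                 prior = prior, seed = seed,
                 n_iter = n_iter, n_burnin = n_burnin, thin = thin,
                 intercepts = intercepts),
            class = "mr2_fit")
}

#' @export
print.mr2_fit <- function(x, ...) {
  cat(sprintf("Multi-response MR fit: %d variants, %d exposures, %d outcomes\n",
              x$n, x$p, x$q))
  cat(sprintf("%d stored draws (%d sweeps, %d burn-in, thin %d), seed %d\n",
              x$n_draws, x$n_iter, x$n_burnin, x$thin, x$seed))
  cat("acceptance rates:",
      paste(names(x$acceptance),
            sprintf("%.2f", x$acceptance), collapse = ", "), "\n")
  invisible(x)
}
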