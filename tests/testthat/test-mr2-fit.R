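## direct multivariate-normal density oracle, written independently of the
## sampler's precision-based evaluation
dmvn_sum <- function(Y, M, Sigma) {
  n <- nrow(Y); q <- ncol(Y)
  Si <- solve(Sigma)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus[1]
  s <- 0
  for (i in seq_len(n)) {
    e <- Y[i, ] - M[i, ]
    s <- s - 0.5 * (q * log(2 * pi) + ld + drop(t(e) %*% Si %*% e))
  }
  s
}

test_that("the model log likelihood matches a brute-force density oracle", {
  ## q = 1 standard-normal special case
  Y0 <- matrix(0, 7, 1)
  std0 <- as_std(matrix(rnorm(7), 7, 1), Y0)
  expect_equal(mr2_log_likelihood(matrix(0, 1, 1), diag(1), 1, std0),
               -(7 / 2) * log(2 * pi))

  set.seed(5)
  n <- 12; p <- 3; q <- 3
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * q), n, q)
  theta <- matrix(rnorm(q * p, 0, 0.5), q, p)
  R <- cov2cor(crossprod(matrix(rnorm(5 * q), 5, q)) + diag(q))
  delta2 <- runif(q, 0.5, 2)
  std <- as_std(X, Y)
  Sigma <- diag(sqrt(delta2)) %*% R %*% diag(sqrt(delta2))
  expect_equal(mr2_log_likelihood(theta, R, delta2, std),
               dmvn_sum(Y, X %*% t(theta), Sigma), tolerance = 1e-10)

  ## identity correlation splits into independent single-response terms
  ll2 <- mr2_log_likelihood(theta, diag(q), delta2, std)
  parts <- sapply(1:q, function(k)
    mr2_log_likelihood(theta[k, , drop = FALSE], diag(1), delta2[k],
                       as_std(X, Y[, k, drop = FALSE])))
  expect_equal(ll2, sum(parts))
})

test_that("posterior model frequencies match exhaustive enumeration on two exposures", {
  set.seed(7)
  n <- 30
  X <- scale(matrix(rnorm(n * 2), n, 2))
  y <- 0.5 * X[, 1] + rnorm(n, 0, 1)
  std <- as_std(X, matrix(y, ncol = 1))
  tau <- 1; del <- 3; tau_hiw <- 1

  ## oracle: closed-form Gaussian marginal given sigma2, numerically
  ## integrated against the inverse-gamma prior IG(del/2, tau_hiw/2)
  log_m_sig <- function(A, s2) {
    V <- diag(s2, n)
    if (length(A) > 0)
      V <- V + tau * X[, A, drop = FALSE] %*% t(X[, A, drop = FALSE])
    ch <- chol(V)
    -0.5 * n * log(2 * pi) - sum(log(diag(ch))) -
      0.5 * sum(backsolve(ch, y, transpose = TRUE)^2)
  }
  dig <- function(s2, a, b) b^a / gamma(a) * s2^(-a - 1) * exp(-b / s2)
  marg <- function(A) {
    shift <- log_m_sig(A, 1)        # stabilizes the integrand
    log(integrate(function(s2) sapply(s2, function(v)
      exp(log_m_sig(A, v) - shift) * dig(v, del / 2, tau_hiw / 2)),
      lower = 0, upper = Inf, rel.tol = 1e-11,
      subdivisions = 2000L)$value) + shift
  }
  models <- list(integer(0), 1L, 2L, c(1L, 2L))
  prior_g <- sapply(c(0, 1, 1, 2), function(s) lbeta(1 + s, 1 + 2 - s) -
                      lbeta(1, 1))
  lpost <- sapply(models, marg) + prior_g
  post <- exp(lpost - max(lpost))
  post <- post / sum(post)

  fit <- fit_mr2(std, n_iter = 34000, n_burnin = 4000, seed = 3)
  g <- fit$draws$gamma[, 1, ]
  freq <- c(mean(g[, 1] == 0 & g[, 2] == 0),
            mean(g[, 1] == 1 & g[, 2] == 0),
            mean(g[, 1] == 0 & g[, 2] == 1),
            mean(g[, 1] == 1 & g[, 2] == 1))
  expect_lt(max(abs(freq - post)), 0.02)
})

test_that("with fixed selection the effect posterior matches the conjugate form", {
  set.seed(8)
  n <- 400; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  theta_true <- c(0.6, -0.4, 0)
  s2 <- 0.8
  y <- X %*% theta_true + rnorm(n, 0, sqrt(s2))
  std <- as_std(X, matrix(y, ncol = 1))
  gam <- matrix(c(1, 1, 0), 1, 3)
  fit <- fit_mr2(std, n_iter = 3000, n_burnin = 500, seed = 2,
                 fix_gamma = gam)
  post_mean <- colMeans(fit$draws$theta[, 1, ])
  ## closed-form ridge posterior mean at the true error variance
  A <- 1:2
  P <- crossprod(X[, A]) / s2 + diag(2)
  m <- solve(P, crossprod(X[, A], y) / s2)
  expect_equal(post_mean[A], as.vector(m), tolerance = 0.03)
  expect_equal(post_mean[3], 0)
  ## overdispersion concentrates near the truth
  expect_equal(mean(fit$draws$delta2), s2, tolerance = 0.15)
})

test_that("graph-move frequencies match the exact two-model posterior", {
  set.seed(9)
  n <- 60; rho <- 0.5
  E <- matrix(rnorm(n * 2), n, 2) %*% chol(matrix(c(1, rho, rho, 1), 2, 2))
  std <- as_std(matrix(rnorm(n), n, 1), E)
  ## freeze selection at the empty model so the residuals are the data
  fit <- fit_mr2(std, n_iter = 22000, n_burnin = 2000, seed = 4,
                 fix_gamma = matrix(0, 2, 1))
  S <- crossprod(E); del <- 3
  ## independently coded marginals (see test-hiw.R)
  lmg2 <- function(a) 0.5 * log(pi) + lgamma(a) + lgamma(a - 0.5)
  a0 <- (del + 1) / 2; a1 <- (del + n + 1) / 2
  lm_full <- -n * log(2 * pi) + (a0 * determinant(diag(2) / 2)$modulus[1] -
    lmg2(a0)) - (a1 * determinant((diag(2) + S) / 2)$modulus[1] - lmg2(a1))
  uni <- function(s) -(n / 2) * log(2 * pi) + (del / 2) * log(1 / 2) +
    lgamma((del + n) / 2) - lgamma(del / 2) -
    ((del + n) / 2) * log((1 + s) / 2)
  lm_empty <- uni(S[1, 1]) + uni(S[2, 2])
  p_edge <- 1 / (1 + exp(lm_empty - lm_full))   # edge prior 0.5 cancels
  eppi <- mean(fit$draws$graph[, 1, 2])
  expect_equal(eppi, p_edge, tolerance = 0.03)
})

test_that("edge_prior zero pins the chain at the empty graph", {
  set.seed(10)
  E <- matrix(rnorm(80), 40, 2) %*% chol(matrix(c(1, .6, .6, 1), 2, 2))
  std <- as_std(matrix(rnorm(40), 40, 1), E)
  fit <- fit_mr2(std, prior = mr2_prior(edge_prior = 0),
                 n_iter = 600, n_burnin = 100, seed = 1,
                 fix_gamma = matrix(0, 2, 1))
  expect_true(all(fit$draws$graph == 0))
  expect_true(all(abs(fit$draws$R[, 1, 2]) < 1e-12))
})

test_that("strong simulated residual correlation is recovered", {
  set.seed(11)
  n <- 500; rho <- 0.6
  E <- matrix(rnorm(n * 2), n, 2) %*% chol(matrix(c(1, rho, rho, 1), 2, 2))
  std <- as_std(matrix(rnorm(n), n, 1), E)
  fit <- fit_mr2(std, n_iter = 3000, n_burnin = 500, seed = 5,
                 fix_gamma = matrix(0, 2, 1))
  expect_equal(mean(fit$draws$R[, 1, 2]), rho, tolerance = 0.1)
})

test_that("chains are deterministic in the seed", {
  set.seed(12)
  X <- matrix(rnorm(60), 20, 3); Y <- matrix(rnorm(40), 20, 2)
  std <- as_std(X, Y)
  a <- fit_mr2(std, n_iter = 400, n_burnin = 100, seed = 42)
  b <- fit_mr2(std, n_iter = 400, n_burnin = 100, seed = 42)
  expect_identical(a$draws, b$draws)
  c <- fit_mr2(std, n_iter = 400, n_burnin = 100, seed = 43)
  expect_false(identical(a$draws$theta, c$draws$theta))
})

test_that("a vanishing slab removes the data from the selection decision", {
  set.seed(13)
  X <- scale(matrix(rnorm(200), 50, 4))
  y <- X %*% c(1, 1, 0, 0) + rnorm(50, 0, 0.3)
  std <- as_std(X, matrix(y, ncol = 1))
  fit <- fit_mr2(std, prior = mr2_prior(slab_variance = 1e-12),
                 n_iter = 6000, n_burnin = 1000, seed = 6)
  mppi <- colMeans(fit$draws$gamma[, 1, ])
  ## spike-dominated limit: inclusion reverts to its Beta(1,1) prior mean
  ## and proposed effects collapse to zero
  expect_true(all(abs(mppi - 0.5) < 0.15))
  expect_lt(max(abs(fit$draws$theta)), 1e-4)
})

test_that("every stored state satisfies the model invariants", {
  set.seed(14)
  cfg <- fast_cfg("III_undirected_pleiotropy", seed = 31, N = 20000)
  std <- ivw_standardize(extract_summary(simulate_individual(cfg)))
  fit <- fit_mr2(std, n_iter = 500, n_burnin = 200, seed = 7)
  for (i in seq(1, fit$n_draws, by = 37)) {
    R <- fit$draws$R[i, , ]
    expect_equal(diag(R), rep(1, 5))
    expect_true(isSymmetric(R, tol = 1e-12))
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    ## precision vanishes off the sampled graph
    P <- solve(fit$draws$R[i, , ] * sqrt(outer(fit$draws$delta2[i, ],
                                               fit$draws$delta2[i, ])))
    adj <- fit$draws$graph[i, , ]
    off <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
    if (nrow(off) > 0)
      expect_lt(max(abs(P[off])), 1e-8)
    expect_true(mr2:::is_decomposable(adj))
    ## spike-and-slab consistency
    expect_true(all(fit$draws$theta[i, , ][fit$draws$gamma[i, , ] == 0] == 0))
    expect_true(all(fit$draws$delta2[i, ] > 0))
  }
  expect_true(all(fit$acceptance >= 0 & fit$acceptance <= 1, na.rm = TRUE))
})

test_that("outcome relabeling permutes the posterior summaries coherently", {
  set.seed(15)
  cfg <- fast_cfg("V_dependence", seed = 32, N = 20000, n_exposures = 6,
                  n_outcomes = 3)
  std <- ivw_standardize(extract_summary(simulate_individual(cfg)))
  perm <- c(3, 1, 2)
  std_p <- std
  std_p$beta_y_std <- std$beta_y_std[, perm]
  std_p$outcome_names <- std$outcome_names[perm]
  f1 <- fit_mr2(std, n_iter = 4000, n_burnin = 1500, seed = 8)
  f2 <- fit_mr2(std_p, n_iter = 4000, n_burnin = 1500, seed = 9)
  m1 <- summary(f1)$mppi
  m2 <- summary(f2)$mppi
  expect_lt(max(abs(m1[perm, ] - m2)), 0.2)
})

test_that("enabled intercepts absorb constant outcome offsets", {
  set.seed(16)
  n <- 80
  X <- matrix(rnorm(n * 2), n, 2)
  Y <- cbind(1.5 + X %*% c(0.8, 0) + rnorm(n, 0, 0.4),
             -0.7 + rnorm(n, 0, 0.4))
  std <- as_std(X, Y)
  fit <- fit_mr2(std, n_iter = 2500, n_burnin = 800, seed = 2,
                 intercepts = TRUE)
  expect_equal(colMeans(fit$draws$mu), c(1.5, -0.7), tolerance = 0.25)
  ## default convention keeps them at zero
  fit0 <- fit_mr2(std, n_iter = 300, n_burnin = 100, seed = 2)
  expect_true(all(fit0$draws$mu == 0))
})

test_that("guards refuse degenerate inputs and warn on few instruments", {
  X <- matrix(rnorm(4), 2, 2); Y <- matrix(rnorm(4), 2, 2)
  expect_error(fit_mr2(as_std(X, Y)), "at least 3")
  X2 <- matrix(rnorm(30), 10, 3); Y2 <- matrix(rnorm(20), 10, 2)
  X2[1, 1] <- NA
  expect_error(fit_mr2(as_std(X2, Y2)), "missing")
  X3 <- matrix(rnorm(24), 8, 3); Y3 <- matrix(rnorm(16), 8, 2)
  expect_warning(fit_mr2(as_std(X3, Y3), n_iter = 60, n_burnin = 10,
                         seed = 1), "few instruments")
})
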