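#' Configuration for the synthetic two-sample MR study
#'
#' Defines one simulation condition of the study design: individual-level
#' data are generated for N subjects as
#' \deqn{Y_k = X\theta_k + A\theta_A + U\theta_{YU} + \varepsilon_k,}
#' where X are p correlated exposures instrumented by n independent biallelic
#' variants, U is a confounder of exposures and outcomes, A is an unmeasured
#' pleiotropic pathway shared by all outcomes (a descendant of the
#' instruments), and the errors \eqn{\varepsilon_k} may be equicorrelated
#' across outcomes. Half of the subjects provide the exposure GWAS, half the
#' outcome GWAS (two-sample design).
#'
#' Scenarios:
#' \describe{
#'   \item{I_null}{no causal effects, no confounder; equicorrelated outcome
#'     errors (`r_y`, default 0.6).}
#'   \item{II_confounding}{30\% nonzero effects plus a joint confounder U.}
#'   \item{III_undirected_pleiotropy}{as II plus a shared pathway A that can
#'     raise or lower the outcomes (A symmetric about its mean).}
#'   \item{IV_directed_pleiotropy}{as III but A strictly positive.}
#'   \item{V_dependence}{as II plus equicorrelated outcome errors (`r_y`).}
#' }
#'
#' @param scenario one of `"I_null"`, `"II_confounding"`,
#'   `"III_undirected_pleiotropy"`, `"IV_directed_pleiotropy"`,
#'   `"V_dependence"` (prefixes accepted).
#' @param n_variants number of instruments n (default 100).
#' @param n_exposures p (default 15).
#' @param n_outcomes q (default 5).
#' @param n_individuals N, split half/half into exposure and outcome samples
#'   (default 100000; must be even).
#' @param sparsity fraction of exposure-outcome pairs with a nonzero direct
#'   effect (default 0.30; exactly `round(sparsity*p*q)` entries are nonzero).
#' @param r_x pairwise correlation of the exposures, induced identically in
#'   their genetic and non-genetic components so the summary-level design
#'   matrix inherits it (default 0.6).
#' @param r_y equicorrelation of the individual-level outcome errors; default
#'   0.6 in scenarios I and V, 0 otherwise.
#' @param theta_xu,theta_yu confounder effects on exposures / outcomes
#'   (defaults 2 and 1; forced to 0 in scenario I).
#' @param theta_a pleiotropic-pathway effect on every outcome (default 1 in
#'   scenarios III/IV, 0 otherwise).
#' @param mu_a,sigma2_a mean and variance of the pathway A (defaults 0, 1).
#' @param h_x fraction of outcome variance explained by the exposures,
#'   relative to the exposure + confounder + error budget; the pathway A adds
#'   noise on top of this budget (default 0.10).
#' @param overlap fraction of shared individuals across the q outcome GWAS
#'   samples (1 = identical samples, 0 = disjoint; default 1).
#' @param effect_range magnitude range of nonzero effects, drawn uniformly
#'   (default `c(0.1, 0.3)`).
#' @param effect_sign `"positive"` (default) draws risk-increasing effects
#'   only, so that shared exposures contribute positively to the raw
#'   correlation between outcome summary statistics (the regime in which the
#'   raw correlation exceeds the residual one); `"random"` flips signs with
#'   probability one half.
#' @param exposure_h2 variance fraction of each exposure explained by the
#'   instruments (default 0.55, the strong-instrument regime of
#'   genome-wide-significant IVs for heritable polygenic exposures).
#' @param sigma2_u confounder variance (default 1).
#' @param a_genetic_ratio ratio of the genetic to the projection-level
#'   variance of the pathway's summary-level association; parameterized at
#'   the summary scale so behavior is invariant to N (default 25). Zero makes
#'   A a pure shared random intercept.
#' @param maf_range allele-frequency range for the instruments
#'   (default `c(0.05, 0.5)`).
#' @param seed integer RNG seed.
#' @return An object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(scenario = c("II_confounding", "I_null",
                                         "III_undirected_pleiotropy",
                                         "IV_directed_pleiotropy",
                                         "V_dependence"),
                            n_variants = 100, n_exposures = 15,
                            n_outcomes = 5, n_individuals = 100000,
                            sparsity = 0.30, r_x = 0.6, r_y = NULL,
                            theta_xu = 2, theta_yu = 1, theta_a = NULL,
                            mu_a = 0, sigma2_a = 1, h_x = 0.10,
                            overlap = 1.0, effect_range = c(0.1, 0.3),
                            effect_sign = c("positive", "random"),
                            exposure_h2 = 0.55, sigma2_u = 1,
                            a_genetic_ratio = 25,
                            maf_range = c(0.05, 0.5), seed = 1) {
  scenario <- match.arg(scenario)
  effect_sign <- match.arg(effect_sign)
  if (is.null(r_y)) r_y <- if (scenario %in% c("I_null", "V_dependence")) 0.6 else 0
  if (is.null(theta_a))
    theta_a <- if (scenario %in% c("III_undirected_pleiotropy",
                                   "IV_directed_pleiotropy")) 1 else 0
  if (scenario == "I_null") { theta_xu <- 0; theta_yu <- 0; theta_a <- 0 }
  if (!(scenario %in% c("III_undirected_pleiotropy", "IV_directed_pleiotropy")))
    theta_a <- 0

  if (sparsity < 0 || sparsity > 1) stop("sparsity must be in [0, 1]")
  if (abs(r_x) >= 1 || abs(r_y) >= 1) stop("|r_x| and |r_y| must be < 1")
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")
  if (n_individuals %% 2 != 0) stop("n_individuals must be even")
  if (h_x <= 0 || h_x >= 1) stop("h_x must be in (0, 1)")
  if (exposure_h2 <= 0 || exposure_h2 >= 1) stop("exposure_h2 must be in (0, 1)")
  if (r_y < -1 / (n_outcomes - 1))
    stop("equicorrelation r_y = ", r_y, " is not positive definite for q = ",
         n_outcomes)
  if (sigma2_a <= 0 || sigma2_u < 0) stop("variances must be positive")
  n2 <- n_individuals / 2
  if (a_genetic_ratio < 0 || a_genetic_ratio >= n2 / n_variants)
    stop("a_genetic_ratio must lie in [0, N/(2n))")

  structure(list(scenario = scenario, n_variants = n_variants,
                 n_exposures = n_exposures, n_outcomes = n_outcomes,
                 n_individuals = n_individuals, sparsity = sparsity,
                 r_x = r_x, r_y = r_y, theta_xu = theta_xu,
                 theta_yu = theta_yu, theta_a = theta_a, mu_a = mu_a,
                 sigma2_a = sigma2_a, h_x = h_x, overlap = overlap,
                 effect_range = effect_range, effect_sign = effect_sign,
                 exposure_h2 = exposure_h2,
                 sigma2_u = sigma2_u, a_genetic_ratio = a_genetic_ratio,
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate individual-level data under a scenario configuration
#'
#' Draws genotypes as independent Binomial(2, f) dosages with
#' f ~ U(`maf_range`), builds exposures with genetic and non-genetic
#' components sharing pairwise correlation `r_x`, adds the confounder and
#' (scenario III/IV) the shared pleiotropic pathway, and scales the residual
#' errors so the exposures explain `h_x` of the outcome variance (pathway
#' excluded from that budget, so pleiotropy adds noise on top).
#'
#' @param config a [scenario_config()].
#' @return An object of class `individual_data`: genotypes `G` (N x n),
#'   exposures `X` (N x p), pathway `A`, confounder `U`, outcomes `Y`
#'   (N x q), the truth (`true_theta`, `true_gamma`, q x p), the realized
#'   error scales `delta2`, the effective pathway variance at the summary
#'   scale `sigma2_a_eff`, and the generating `config`.
#' @export
simulate_individual <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n_variants; p <- config$n_exposures; q <- config$n_outcomes
  N <- config$n_individuals; N2 <- N / 2

  f <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  G <- matrix(stats::rbinom(N * n, 2L, rep(f, each = N)), nrow = N)
  het <- 2 * f * (1 - f)                     # per-variant genotype variance

  ## exposures: genetic weights and non-genetic factors both share r_x
  h2 <- config$exposure_h2; rx <- config$r_x
  sw <- sqrt(h2 / sum(het))
  w0 <- stats::rnorm(n, 0, sw)
  W <- sqrt(rx) * matrix(w0, n, p) +
    sqrt(1 - rx) * matrix(stats::rnorm(n * p, 0, sw), n, p)
  U <- stats::rnorm(N, 0, sqrt(config$sigma2_u))
  Fc <- stats::rnorm(N)
  Ex <- matrix(stats::rnorm(N * p), N, p)
  X <- G %*% W +
    sqrt(1 - h2) * (sqrt(rx) * Fc + sqrt(1 - rx) * Ex) +
    config$theta_xu * U

  ## pleiotropic pathway A = G w_A + eta; w_A variance set at the summary
  ## scale: genetic share = a_genetic_ratio times the projection-level
  ## variance sigma2_a / mean(Sgg) in the outcome sample
  A <- rep(0, N); sigma2_a_eff <- 0
  if (config$theta_a != 0) {
    phi <- config$a_genetic_ratio
    mean_sgg2 <- mean(het) * N2
    s2wa <- phi * config$sigma2_a / mean_sgg2
    gen_var <- s2wa * sum(het)               # = phi * sigma2_a * n / N2
    eta_var <- config$sigma2_a - gen_var
    wA <- stats::rnorm(n, 0, sqrt(s2wa))
    A <- config$mu_a + as.vector(G %*% wA) +
      stats::rnorm(N, 0, sqrt(eta_var))
    if (config$scenario == "IV_directed_pleiotropy") A <- abs(A)
    sigma2_a_eff <- config$sigma2_a * (1 + phi - phi * n / N2)
  }

  ## truth: exactly round(sparsity * p * q) nonzero effects
  theta <- matrix(0, q, p)
  k_nz <- round(config$sparsity * p * q)
  if (config$scenario != "I_null" && k_nz > 0) {
    cells <- sample.int(p * q, k_nz)
    theta[cells] <- stats::runif(k_nz, config$effect_range[1],
                                 config$effect_range[2])
    if (config$effect_sign == "random")
      theta[cells] <- theta[cells] * sample(c(-1, 1), k_nz, replace = TRUE)
  }
  gamma <- (theta != 0) * 1L

  ## residual scales from the h_x budget (exposures vs confounder + error)
  XB <- X %*% t(theta)                       # N x q causal signal
  var_sig <- apply(XB, 2, stats::var)
  c_u <- config$theta_yu^2 * config$sigma2_u
  delta2 <- var_sig * (1 / config$h_x - 1) - c_u
  if (config$scenario == "I_null") {
    delta2 <- rep(1, q)
  } else {
    fallback <- if (any(delta2 > 0)) stats::median(delta2[delta2 > 0]) else 1
    delta2[!is.finite(delta2) | delta2 <= 0] <- fallback
  }

  ## errors, equicorrelated when r_y != 0
  if (config$r_y != 0) {
    Cy <- matrix(config$r_y, q, q); diag(Cy) <- 1
    ev <- eigen(Cy, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("equicorrelation matrix for r_y is not positive definite")
    eps <- matrix(stats::rnorm(N * q), N, q) %*% chol(Cy)
  } else {
    eps <- matrix(stats::rnorm(N * q), N, q)
  }
  eps <- sweep(eps, 2, sqrt(delta2), "*")

  Y <- XB + config$theta_a * A + config$theta_yu * U + eps

  structure(list(G = G, X = X, A = A, U = U, Y = Y,
                 true_theta = theta, true_gamma = gamma,
                 delta2 = delta2, sigma2_a_eff = sigma2_a_eff,
                 confounder_var = c_u, config = config),
            class = "individual_data")
}

#' Ground-truth record of a simulated dataset
#'
#' @param ind an `individual_data` object.
#' @return A list with `true_theta`, `true_gamma` and the scenario
#'   provenance, suitable for serialization.
#' @export
truth_record <- function(ind) {
  stopifnot(inherits(ind, "individual_data"))
  list(true_theta = ind$true_theta, true_gamma = ind$true_gamma,
       scenario = ind$config$scenario, seed = ind$config$seed,
       delta2 = ind$delta2, sigma2_a_eff = ind$sigma2_a_eff)
}

#' Extract two-sample summary statistics from individual-level data
#'
#' Runs per-variant univariable regressions (with intercept) of each exposure
#' on each variant in the first half of the sample and of each outcome on
#' each variant in the second half, mirroring how GWAS summary statistics are
#' produced. Overlap between the per-outcome samples is controlled by
#' `config$overlap`: 1 regresses every outcome on the same individuals, 0
#' gives each outcome a disjoint subsample.
#'
#' @param ind an `individual_data` object.
#' @return A [summary_data()] object with n rows.
#' @export
extract_summary <- function(ind) {
  stopifnot(inherits(ind, "individual_data"))
  cfg <- ind$config
  n <- cfg$n_variants; N <- cfg$n_individuals; N2 <- N / 2
  if (N < 2 * n + 10) stop("need N well above 2n for the two-sample split")

  uni_gwas <- function(Gs, Ts) {
    m <- nrow(Gs)
    cg <- scale(Gs, center = TRUE, scale = FALSE)
    ct <- scale(Ts, center = TRUE, scale = FALSE)
    sgg <- colSums(cg^2)
    slope <- crossprod(cg, ct) / sgg
    syy <- colSums(ct^2)
    rss <- pmax(matrix(syy, nrow = length(sgg), ncol = length(syy),
                       byrow = TRUE) - slope^2 * sgg, 0)
    se <- sqrt(rss / (m - 2) / sgg)
    list(beta = slope, se = se)
  }

  idx1 <- seq_len(N2)
  ex <- uni_gwas(ind$G[idx1, , drop = FALSE], ind$X[idx1, , drop = FALSE])

  idx2 <- N2 + seq_len(N2)
  q <- cfg$n_outcomes
  if (cfg$overlap >= 1) {
    oy <- uni_gwas(ind$G[idx2, , drop = FALSE], ind$Y[idx2, , drop = FALSE])
    by <- oy$beta; sy <- oy$se
  } else {
    m_shared <- round(cfg$overlap * N2)
    chunk <- floor((N2 - m_shared) / q)
    if (m_shared + chunk < n + 5)
      stop("overlap < 1 leaves too few individuals per outcome sample")
    by <- matrix(0, n, q); sy <- matrix(0, n, q)
    for (k in seq_len(q)) {
      own <- idx2[m_shared + (k - 1) * chunk + seq_len(chunk)]
      sel <- c(idx2[seq_len(m_shared)], own)
      ok <- uni_gwas(ind$G[sel, , drop = FALSE],
                     ind$Y[sel, k, drop = FALSE])
      by[, k] <- ok$beta; sy[, k] <- ok$se
    }
  }

  summary_data(ex$beta, ex$se, by, sy,
               variant_ids = paste0("rs", seq_len(n)),
               exposure_names = paste0("X", seq_len(cfg$n_exposures)),
               outcome_names = paste0("Y", seq_len(q)))
}

#' Simulate a summary-level dataset in one call
#'
#' Convenience wrapper: [simulate_individual()] followed by
#' [extract_summary()]; the truth is attached as attribute `"truth"`.
#'
#' @param config a [scenario_config()].
#' @return A [summary_data()] object with attribute `truth`
#'   (see [truth_record()]).
#' @export
simulate_summary <- function(config) {
  ind <- simulate_individual(config)
  out <- extract_summary(ind)
  attr(out, "truth") <- truth_record(ind)
  out
}

#' Theoretical residual correlation between summary-level outcomes
#'
#' Closed form for the correlation between the residuals of two summary-level
#' outcome regressions induced by an unmeasured shared pleiotropic pathway
#' with effect \eqn{\theta_A} and variance \eqn{\sigma^2_A}, plus any
#' covariance \eqn{\sigma_{kk'}} between the individual-level errors:
#' \deqn{\rho = \frac{\theta_A^2\sigma_A^2 + \sigma_{kk'}}
#'   {\sqrt{\theta_A^2\sigma_A^2 + \delta_k^2}
#'    \sqrt{\theta_A^2\sigma_A^2 + \delta_{k'}^2}}.}
#' The pleiotropy contribution is positive regardless of the sign of
#' \eqn{\theta_A} and of whether the pathway is directed or undirected.
#'
#' @param theta_a pathway effect.
#' @param sigma2_a pathway variance (at the summary/projection scale).
#' @param delta2_k,delta2_k2 error variances of the two outcomes.
#' @param sigma_kk2 covariance between the two outcomes' individual-level
#'   errors (default 0).
#' @return The residual correlation, a number in \[-1, 1\].
#' @export
theoretical_residual_correlation <- function(theta_a, sigma2_a, delta2_k,
                                             delta2_k2, sigma_kk2 = 0) {
  if (sigma2_a < 0 || delta2_k <= 0 || delta2_k2 <= 0)
    stop("variances must be positive")
  s <- theta_a^2 * sigma2_a
  rho <- (s + sigma_kk2) / sqrt((s + delta2_k) * (s + delta2_k2))
  if (!is.finite(rho) || abs(rho) > 1)
    stop("inconsistent covariance: implied correlation ", format(rho),
         " outside [-1, 1]")
  rho
}

#' Predicted residual-correlation matrix for a simulated dataset
#'
#' Applies [theoretical_residual_correlation()] pairwise using the
#' generator's realized components: the effective summary-scale pathway
#' variance, the confounder contribution (which behaves as a shared error),
#' and any equicorrelation of the individual-level errors.
#'
#' @param ind an `individual_data` object.
#' @return q x q matrix of predicted residual correlations.
#' @export
theoretical_outcome_correlation <- function(ind) {
  stopifnot(inherits(ind, "individual_data"))
  cfg <- ind$config
  q <- cfg$n_outcomes
  c_u <- ind$confounder_var
  d2 <- ind$delta2 + c_u
  out <- diag(q)
  for (k in seq_len(q - 1)) for (l in (k + 1):q) {
    skl <- c_u + cfg$r_y * sqrt(ind$delta2[k] * ind$delta2[l])
    out[k, l] <- out[l, k] <- theoretical_residual_correlation(
      cfg$theta_a, ind$sigma2_a_eff, d2[k], d2[l], skl)
  }
  out
}
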