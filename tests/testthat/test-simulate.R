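test_that("scenario configuration enforces its invariants", {
  expect_error(scenario_config(sparsity = 1.2), "sparsity")
  expect_error(scenario_config(r_x = 1), "r_x")
  expect_error(scenario_config(overlap = 2), "overlap")
  expect_error(scenario_config(n_individuals = 101), "even")
  expect_error(scenario_config("V_dependence", r_y = -0.9,
                               n_outcomes = 5), "positive definite")
  ## scenario-dependent defaults
  expect_equal(scenario_config("I_null")$r_y, 0.6)
  expect_equal(scenario_config("II_confounding")$r_y, 0)
  expect_equal(scenario_config("III_undirected_pleiotropy")$theta_a, 1)
  expect_equal(scenario_config("I_null")$theta_xu, 0)
})

test_that("the null scenario has no effects and no confounder pathway", {
  ind <- simulate_individual(fast_cfg("I_null", seed = 3, N = 4000))
  expect_true(all(ind$true_theta == 0))
  expect_true(all(ind$true_gamma == 0))
  ## U has no pathway into Y (theta_yu = 0), so corr(U, Y) is pure noise
  expect_lt(max(abs(cor(ind$U, ind$Y))), 0.06)
})

test_that("the nonzero-effect count is exact and signs follow the convention", {
  cfg <- fast_cfg("II_confounding", seed = 8, N = 2000)
  ind <- simulate_individual(cfg)
  expect_equal(sum(ind$true_gamma), round(0.30 * 15 * 5))
  expect_true(all(ind$true_theta[ind$true_gamma == 1] >=
                    cfg$effect_range[1]))
  expect_true(all(ind$true_theta[ind$true_gamma == 1] <=
                    cfg$effect_range[2]))
  cfg2 <- fast_cfg("II_confounding", seed = 8, N = 2000,
                   effect_sign = "random")
  ind2 <- simulate_individual(cfg2)
  expect_true(any(ind2$true_theta < 0))
  expect_equal(abs(ind2$true_theta), abs(ind$true_theta))
})

test_that("outcomes decompose exactly into the stored components", {
  ind <- simulate_individual(fast_cfg("III_undirected_pleiotropy",
                                      seed = 4, N = 2000))
  resid <- ind$Y - ind$X %*% t(ind$true_theta) -
    ind$config$theta_a * ind$A - ind$config$theta_yu * ind$U
  ## residual variance matches the h_x budget scales
  expect_equal(unname(apply(resid, 2, var)), ind$delta2, tolerance = 0.1)
})

test_that("pathway-free pleiotropy scenario reduces to the confounding one", {
  a <- simulate_individual(fast_cfg("III_undirected_pleiotropy",
                                    seed = 5, N = 2000, theta_a = 0))
  b <- simulate_individual(fast_cfg("II_confounding", seed = 5, N = 2000))
  expect_identical(a$Y, b$Y)
  expect_identical(a$X, b$X)
})

test_that("scenario V error correlation matches its target", {
  cfg <- fast_cfg("V_dependence", seed = 6, N = 20000, r_y = 0.6)
  ind <- simulate_individual(cfg)
  eps <- ind$Y - ind$X %*% t(ind$true_theta) - cfg$theta_yu * ind$U
  cc <- cor(eps)
  expect_equal(offdiag_mean(cc), 0.6, tolerance = 0.02)
  expect_true(all(abs(cc[upper.tri(cc)] - 0.6) < 0.04))
})

test_that("directed and undirected pathways differ only in sign support", {
  und <- simulate_individual(fast_cfg("III_undirected_pleiotropy",
                                      seed = 7, N = 2000))
  dir <- simulate_individual(fast_cfg("IV_directed_pleiotropy",
                                      seed = 7, N = 2000))
  expect_true(any(und$A < 0) && any(und$A > 0))
  expect_true(all(dir$A > 0))
  expect_identical(abs(und$A), dir$A)
})

test_that("same seed is bit-identical, different seeds differ", {
  cfg <- fast_cfg("II_confounding", seed = 10, N = 2000)
  a <- extract_summary(simulate_individual(cfg))
  b <- extract_summary(simulate_individual(cfg))
  expect_identical(a$beta_y, b$beta_y)
  cfg2 <- fast_cfg("II_confounding", seed = 11, N = 2000)
  expect_false(identical(
    extract_summary(simulate_individual(cfg2))$beta_y, a$beta_y))
})

test_that("summary extraction matches dimensions and a brute-force OLS", {
  cfg <- fast_cfg("II_confounding", seed = 12, N = 4000, n_variants = 50)
  ind <- simulate_individual(cfg)
  dat <- extract_summary(ind)
  expect_equal(c(dat$n, dat$p, dat$q), c(50, 15, 5))

  ## per-variant univariable regressions in the correct half-samples
  N2 <- cfg$n_individuals / 2
  for (i in c(1, 17, 50)) {
    fx <- summary(lm(ind$X[1:N2, 3] ~ ind$G[1:N2, i]))$coefficients
    expect_equal(unname(dat$beta_x[i, 3]), fx[2, 1], tolerance = 1e-10)
    expect_equal(unname(dat$se_x[i, 3]), fx[2, 2], tolerance = 1e-8)
    fy <- summary(lm(ind$Y[(N2 + 1):(2 * N2), 2] ~
                       ind$G[(N2 + 1):(2 * N2), i]))$coefficients
    expect_equal(unname(dat$beta_y[i, 2]), fy[2, 1], tolerance = 1e-10)
    expect_equal(unname(dat$se_y[i, 2]), fy[2, 2], tolerance = 1e-8)
  }
})

test_that("closed-form residual correlation obeys its algebra", {
  expect_equal(theoretical_residual_correlation(0, 1, 1, 1, 0), 0)
  expect_equal(theoretical_residual_correlation(1, 1, 1, 1, 0), 0.5)
  ## sign of theta_a is irrelevant, contribution always positive
  expect_equal(theoretical_residual_correlation(-1, 1, 1, 1, 0), 0.5)
  ## monotone over the pathway-effect grid
  grid <- c(0.25, 0.5, 0.75, 1, 1.5, 2)
  vals <- sapply(grid, theoretical_residual_correlation,
                 sigma2_a = 1, delta2_k = 2, delta2_k2 = 3, sigma_kk2 = 0)
  expect_true(all(diff(vals) > 0))
  expect_error(theoretical_residual_correlation(1, -1, 1, 1), "positive")
  expect_error(theoretical_residual_correlation(0, 1, 0.1, 0.1, 5),
               "outside")
})

test_that("residual correlation with no sample overlap keeps only the genetic pathway channel", {
  ## shared-error mechanism (scenario V) vanishes without overlap ...
  cfg_v <- fast_cfg("V_dependence", seed = 21, N = 60000, overlap = 0,
                    theta_yu = 0, sigma2_u = 0)
  rv <- residual_outcome_correlation(extract_summary(simulate_individual(cfg_v)))
  ## ... while a shared pathway with a genetic component survives
  cfg_p <- fast_cfg("III_undirected_pleiotropy", seed = 21, N = 60000,
                    overlap = 0, theta_yu = 0, sigma2_u = 0)
  rp <- residual_outcome_correlation(extract_summary(simulate_individual(cfg_p)))
  expect_lt(abs(offdiag_mean(rv)), 0.1)
  expect_gt(offdiag_mean(rp), 0.2)
})

test_that("simulate_summary attaches the truth record", {
  dat <- simulate_summary(fast_cfg("II_confounding", seed = 13, N = 2000))
  tr <- attr(dat, "truth")
  expect_equal(dim(tr$true_theta), c(5, 15))
  expect_equal(tr$scenario, "II_confounding")
})
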