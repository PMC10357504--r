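#' Rank-based area under the ROC curve
#'
#' Mann-Whitney formulation with midrank tie correction: the probability
#' that a randomly chosen true pair scores higher than a randomly chosen
#' null pair, ties counting one half.
#'
#' @param scores numeric vector or matrix of scores (higher = more likely
#'   causal); for inclusion probabilities pass the mPPIs, for p-value
#'   methods pass 1 - p.
#' @param truth binary vector or matrix of the same shape.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, truth) {
  s <- as.vector(scores); t <- as.vector(truth)
  stopifnot(length(s) == length(t))
  t <- as.integer(t != 0)
  n1 <- sum(t == 1); n0 <- sum(t == 0)
  if (n1 == 0 || n0 == 0)
    stop("truth must contain both classes; AUC undefined")
  r <- rank(s)
  (sum(r[t == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sum of squared errors of effect estimates
#'
#' @param theta_hat estimated q x p effect matrix (for the Bayesian model,
#'   the unconditional posterior means: zeros when excluded).
#' @param theta_true true q x p effect matrix.
#' @return Sum over all entries of the squared deviation.
#' @export
sse <- function(theta_hat, theta_true) {
  stopifnot(identical(dim(as.matrix(theta_hat)), dim(as.matrix(theta_true))))
  sum((theta_hat - theta_true)^2)
}

.bench_methods <- c("mvmr", "mvmr_egger", "ivw", "mr2")

#' Benchmark MR methods on simulated scenarios
#'
#' For each scenario and replicate: simulate individual-level data, extract
#' two-sample summary statistics, standardize, fit each requested method,
#' and score exposure discrimination (AUC of mPPIs or 1 - p over all q x p
#' pairs against the simulated truth) and effect estimation (SSE).
#' Replicate seeds are derived deterministically from `seed`, so results
#' are reproducible regardless of evaluation order; a method failing on a
#' replicate is logged and excluded from that method's aggregate.
#'
#' @param scenarios character vector of scenario names
#'   (see [scenario_config()]).
#' @param methods subset of `"mvmr"`, `"mvmr_egger"`, `"ivw"`, `"mr2"`.
#' @param replicates replicates per scenario (default 50).
#' @param seed master seed.
#' @param config named list of [scenario_config()] overrides applied to
#'   every scenario (e.g. `list(theta_a = 2, n_individuals = 20000)`).
#' @param mr2_args named list of [fit_mr2()] settings
#'   (e.g. `list(n_iter = 6000, n_burnin = 2000)`).
#' @return An object of class `benchmark_result`: `metrics` (one row per
#'   scenario/method/replicate with auc and sse), `summary` (means and SDs),
#'   `failures`, and the resolved configuration.
#' @export
run_benchmark <- function(scenarios, methods = c("mvmr", "mr2"),
                          replicates = 50, seed = 1, config = list(),
                          mr2_args = list()) {
  methods <- match.arg(methods, .bench_methods, several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(2^30, replicates)
  rows <- list(); failures <- list()

  for (sc in scenarios) {
    for (r in seq_len(replicates)) {
      cfg <- do.call(scenario_config,
                     c(list(scenario = sc, seed = rep_seeds[r]), config))
      ind <- simulate_individual(cfg)
      dat <- extract_summary(ind)
      truth <- ind$true_gamma
      for (m in methods) {
        res <- tryCatch({
          if (m == "mvmr" || m == "mvmr_egger") {
            egger <- m == "mvmr_egger"
            th <- matrix(0, cfg$n_outcomes, cfg$n_exposures)
            pv <- th
            for (k in seq_len(cfg$n_outcomes)) {
              f <- fit_mvmr(dat, k, egger = egger)
              th[k, ] <- f$theta; pv[k, ] <- f$p_value
            }
            list(score = 1 - pv, theta = th)
          } else if (m == "ivw") {
            th <- matrix(0, cfg$n_outcomes, cfg$n_exposures)
            pv <- th
            for (k in seq_len(cfg$n_outcomes))
              for (j in seq_len(cfg$n_exposures)) {
                f <- fit_univariable_ivw(dat, j, k)
                th[k, j] <- f$theta; pv[k, j] <- f$p_value
              }
            list(score = 1 - pv, theta = th)
          } else {
            std <- ivw_standardize(dat)
            fa <- c(list(data = std,
                         seed = (rep_seeds[r] + 7L) %% 2147483647L),
                    mr2_args)
            fit <- do.call(fit_mr2, fa)
            sm <- summary(fit)
            list(score = sm$mppi, theta = sm$theta_mean)
          }
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1]] <-
            list(scenario = sc, method = m, replicate = r,
                 message = conditionMessage(res))
          next
        }
        auc <- if (all(truth == truth[1])) NA_real_ else
          roc_auc(res$score, truth)
        rows[[length(rows) + 1]] <-
          data.frame(scenario = sc, method = m, replicate = r,
                     auc = auc, sse = sse(res$theta, ind$true_theta),
                     stringsAsFactors = FALSE)
      }
    }
  }

  metrics <- do.call(rbind, rows)
  if (is.null(metrics)) {
    warning("every replicate failed for every method")
    return(structure(list(metrics = NULL, summary = NULL,
                          failures = failures, scenarios = scenarios,
                          methods = methods, replicates = replicates,
                          seed = seed, config = config,
                          mr2_args = mr2_args),
                     class = "benchmark_result"))
  }
  agg <- do.call(rbind, lapply(split(metrics,
                                     metrics[c("scenario", "method")],
                                     drop = TRUE), function(d)
    data.frame(scenario = d$scenario[1], method = d$method[1],
               replicates = nrow(d),
               auc_mean = mean(d$auc, na.rm = TRUE),
               auc_sd = stats::sd(d$auc[!is.na(d$auc)]),
               sse_mean = mean(d$sse), sse_sd = stats::sd(d$sse),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  structure(list(metrics = metrics, summary = agg, failures = failures,
                 scenarios = scenarios, methods = methods,
                 replicates = replicates, seed = seed,
                 config = config, mr2_args = mr2_args),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, digits = 3, ...) {
  cat(sprintf("Benchmark: %d replicate(s) per scenario, seed %d\n",
              x$replicates, x$seed))
  df <- x$summary
  df[] <- lapply(df, function(cc) if (is.numeric(cc)) round(cc, digits) else cc)
  print(df)
  if (length(x$failures) > 0)
    cat(length(x$failures), "replicate/method failure(s) excluded\n")
  invisible(x)
}
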