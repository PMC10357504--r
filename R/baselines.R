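## Single-outcome reference methods: classical weighted-regression MR fitted
## one response at a time, with a multiplicative overdispersion delta^2 >= 1
## inflating the first-order variances (random-effect style).

.wls_mr <- function(Xd, y, w, coef_names, egger) {
  n <- length(y); pp <- ncol(Xd)
  if (n <= pp) stop("need more variants than regression coefficients")
  Xs <- Xd * sqrt(w)
  qrX <- qr(Xs)
  if (qrX$rank < pp) {
    bad <- coef_names[qrX$pivot[(qrX$rank + 1):pp]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  ys <- y * sqrt(w)
  coef <- qr.coef(qrX, ys)
  res <- ys - qr.fitted(qrX, ys)
  df <- n - pp
  sigma2 <- sum(res^2) / df
  delta2 <- max(1, sigma2)                  # overdispersion, truncated at 1
  XtWX_inv <- chol2inv(chol(crossprod(Xs)))
  se <- sqrt(delta2 * diag(XtWX_inv))
  tval <- coef / se
  pval <- 2 * stats::pt(-abs(tval), df)
  names(coef) <- names(se) <- names(pval) <- coef_names
  keep <- if (egger) -1 else TRUE
  structure(list(theta = coef[keep], se = se[keep], p_value = pval[keep],
                 intercept = if (egger) coef[1] else 0,
                 intercept_se = if (egger) se[1] else NA_real_,
                 intercept_p = if (egger) pval[1] else NA_real_,
                 delta2 = delta2, df = df, egger = egger),
            class = "mvmr_fit")
}

#' Univariable inverse-variance-weighted Mendelian randomization
#'
#' Weighted regression (no intercept) of the variant-outcome associations on
#' the variant-exposure associations with first-order weights
#' se(beta_Y)^-2, with multiplicative overdispersion bounded below at 1.
#'
#' @param data a [summary_data()] object.
#' @param exposure exposure index or name.
#' @param outcome outcome index or name.
#' @return An object of class `mvmr_fit` with `theta`, `se`, `p_value`,
#'   `delta2`.
#' @export
fit_univariable_ivw <- function(data, exposure, outcome) {
  stopifnot(inherits(data, "summary_data"))
  if (is.character(exposure)) exposure <- match(exposure, data$exposure_names)
  if (is.character(outcome)) outcome <- match(outcome, data$outcome_names)
  if (data$n < 3) stop("need at least 3 variants")
  x <- data$beta_x[, exposure]
  if (stats::sd(x) == 0 && all(x == 0)) stop("zero-variance exposure column")
  .wls_mr(matrix(x, ncol = 1), data$beta_y[, outcome],
          data$se_y[, outcome]^-2,
          data$exposure_names[exposure], egger = FALSE)
}

#' Multivariable Mendelian randomization for one outcome
#'
#' Weighted regression of one outcome's associations on the associations
#' with all p exposures (first-order weights se(beta_Y)^-2), estimating the
#' direct causal effect of each exposure conditional on the others. With
#' `egger = TRUE` an intercept is included, capturing unmeasured directional
#' horizontal pleiotropy.
#'
#' @param data a [summary_data()] object.
#' @param outcome outcome index or name.
#' @param egger include the pleiotropy intercept (default `FALSE`).
#' @return An object of class `mvmr_fit`: per-exposure `theta`, `se`,
#'   `p_value` (t tests with overdispersion-inflated variances), the
#'   truncated overdispersion `delta2`, and (Egger only) the intercept
#'   estimate and its p value.
#' @export
fit_mvmr <- function(data, outcome, egger = FALSE) {
  stopifnot(inherits(data, "summary_data"))
  if (is.character(outcome)) outcome <- match(outcome, data$outcome_names)
  Xd <- data$beta_x
  if (egger) Xd <- cbind(`(intercept)` = 1, Xd)
  .wls_mr(Xd, data$beta_y[, outcome], data$se_y[, outcome]^-2,
          colnames(Xd), egger = egger)
}

#' @export
print.mvmr_fit <- function(x, digits = 3, ...) {
  cat(if (x$egger) "MV-MR-Egger fit\n" else "weighted-regression MR fit\n")
  tab <- cbind(estimate = x$theta, se = x$se, p = x$p_value)
  print(round(tab, digits))
  if (x$egger)
    cat(sprintf("intercept %.3f (p = %.3g)\n", x$intercept, x$intercept_p))
  cat(sprintf("overdispersion delta^2 = %.3f\n", x$delta2))
  invisible(x)
}
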