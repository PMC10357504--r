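#' Summary-level Mendelian randomization data
#'
#' Container for two-sample summary statistics: per-variant beta coefficients
#' and standard errors for the genetic associations with p exposures and q
#' outcomes. Each genetic variant (instrumental variable) contributes one row.
#'
#' @param beta_x n x p numeric matrix of variant-exposure associations.
#' @param se_x n x p matrix of strictly positive standard errors for `beta_x`.
#' @param beta_y n x q numeric matrix of variant-outcome associations.
#' @param se_y n x q matrix of strictly positive standard errors for `beta_y`.
#' @param variant_ids optional character vector of n variant identifiers.
#' @param exposure_names optional character vector of p exposure labels.
#' @param outcome_names optional character vector of q outcome labels.
#'
#' @return An object of class `summary_data`: a list with the validated
#'   matrices and label vectors. Dimensions are available via `dim()` fields
#'   `n`, `p`, `q`.
#' @export
summary_data <- function(beta_x, se_x, beta_y, se_y,
                         variant_ids = NULL, exposure_names = NULL,
                         outcome_names = NULL) {
  beta_x <- as.matrix(beta_x); se_x <- as.matrix(se_x)
  beta_y <- as.matrix(beta_y); se_y <- as.matrix(se_y)
  n <- nrow(beta_x)
  if (nrow(se_x) != n || nrow(beta_y) != n || nrow(se_y) != n)
    stop("all matrices must share the same number of rows (variants)")
  if (!identical(dim(beta_x), dim(se_x)))
    stop("beta_x and se_x dimensions differ")
  if (!identical(dim(beta_y), dim(se_y)))
    stop("beta_y and se_y dimensions differ")
  for (m in list(beta_x, se_x, beta_y, se_y))
    if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
      stop("summary matrices must be finite numeric with no missing cells")
  bad_se <- which(se_x <= 0, arr.ind = TRUE)
  if (nrow(bad_se) > 0)
    stop("non-positive exposure standard error at row ", bad_se[1, 1])
  bad_se <- which(se_y <= 0, arr.ind = TRUE)
  if (nrow(bad_se) > 0)
    stop("non-positive outcome standard error at row ", bad_se[1, 1])

  p <- ncol(beta_x); q <- ncol(beta_y)
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(n))
  if (is.null(exposure_names)) exposure_names <- colnames(beta_x)
  if (is.null(exposure_names)) exposure_names <- paste0("X", seq_len(p))
  if (is.null(outcome_names)) outcome_names <- colnames(beta_y)
  if (is.null(outcome_names)) outcome_names <- paste0("Y", seq_len(q))
  stopifnot(length(variant_ids) == n, length(exposure_names) == p,
            length(outcome_names) == q)
  dimnames(beta_x) <- dimnames(se_x) <- list(variant_ids, exposure_names)
  dimnames(beta_y) <- dimnames(se_y) <- list(variant_ids, outcome_names)

  structure(list(variant_ids = as.character(variant_ids),
                 exposure_names = as.character(exposure_names),
                 outcome_names = as.character(outcome_names),
                 beta_x = beta_x, se_x = se_x,
                 beta_y = beta_y, se_y = se_y,
                 n = n, p = p, q = q),
            class = "summary_data")
}

#' @export
print.summary_data <- function(x, ...) {
  cat(sprintf("Summary-level MR data: %d variants, %d exposures, %d outcomes\n",
              x$n, x$p, x$q))
  cat("exposures:", paste(utils::head(x$exposure_names, 8), collapse = ", "),
      if (x$p > 8) "..." else "", "\n")
  cat("outcomes: ", paste(utils::head(x$outcome_names, 8), collapse = ", "),
      if (x$q > 8) "..." else "", "\n")
  invisible(x)
}

## Column layout used by the writer and, by default, the reader:
##   variant, bx_<exposure>, sebx_<exposure>, by_<outcome>, seby_<outcome>
.sd_colnames <- function(exposures, outcomes) {
  c("variant",
    as.vector(rbind(paste0("bx_", exposures), paste0("sebx_", exposures))),
    as.vector(rbind(paste0("by_", outcomes), paste0("seby_", outcomes))))
}

#' Read summary-level MR data from a delimited text file
#'
#' Reads a header-ed TSV/CSV holding one row per genetic variant. By default
#' the columns follow the layout emitted by [write_summary_data()]:
#' `variant`, then `bx_<name>`/`sebx_<name>` per exposure and
#' `by_<name>`/`seby_<name>` per outcome. Arbitrary column names can be
#' mapped via `column_map`. Rows containing missing cells are dropped with a
#' message (complete-case per variant); non-numeric garbage in a beta/SE cell
#' is an error naming the row.
#'
#' @param path file path; `.csv` implies comma separation, anything else tab.
#' @param column_map optional list with entries `variant` (column name) and
#'   `exposures`/`outcomes`: named lists mapping trait label to
#'   `c(beta = <col>, se = <col>)`.
#' @param sep field separator; overrides the extension heuristic.
#' @return A [summary_data()] object.
#' @export
read_summary_data <- function(path, column_map = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0L) stop("no data rows in ", path)

  if (is.null(column_map)) {
    cn <- colnames(raw)
    if (!("variant" %in% cn)) stop("missing mandatory column 'variant'")
    exp_names <- sub("^bx_", "", grep("^bx_", cn, value = TRUE))
    out_names <- sub("^by_", "", grep("^by_", cn, value = TRUE))
    if (length(exp_names) == 0L) stop("no exposure columns (bx_*) found")
    if (length(out_names) == 0L) stop("no outcome columns (by_*) found")
    column_map <- list(
      variant = "variant",
      exposures = stats::setNames(lapply(exp_names, function(nm)
        c(beta = paste0("bx_", nm), se = paste0("sebx_", nm))), exp_names),
      outcomes = stats::setNames(lapply(out_names, function(nm)
        c(beta = paste0("by_", nm), se = paste0("seby_", nm))), out_names))
  }
  need <- c(column_map$variant,
            unlist(column_map$exposures), unlist(column_map$outcomes))
  absent <- setdiff(need, colnames(raw))
  if (length(absent) > 0)
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "))

  grab <- function(cols) {
    m <- as.matrix(raw[, cols, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m)))
    garbled <- is.na(num) & !(is.na(m) | trimws(m) %in% c("", "NA", "na", "NaN"))
    if (any(garbled)) {
      idx <- which(garbled, arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric value '%s' in column '%s', data row %d",
                   m[idx[1], idx[2]], cols[idx[2]], idx[1]))
    }
    num
  }
  exp_names <- names(column_map$exposures)
  out_names <- names(column_map$outcomes)
  bx  <- grab(vapply(column_map$exposures, `[[`, "", "beta"))
  sbx <- grab(vapply(column_map$exposures, `[[`, "", "se"))
  by  <- grab(vapply(column_map$outcomes, `[[`, "", "beta"))
  sby <- grab(vapply(column_map$outcomes, `[[`, "", "se"))

  keep <- !(rowSums(is.na(bx)) + rowSums(is.na(sbx)) +
              rowSums(is.na(by)) + rowSums(is.na(sby)) > 0)
  if (any(!keep))
    message(sum(!keep), " row(s) with missing cells dropped")
  if (!any(keep)) stop("all rows contain missing cells")

  bx <- bx[keep, , drop = FALSE]; sbx <- sbx[keep, , drop = FALSE]
  by <- by[keep, , drop = FALSE]; sby <- sby[keep, , drop = FALSE]
  ids <- raw[[column_map$variant]][keep]
  bad <- which(sbx <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-positive standard error for exposure '", exp_names[bad[1, 2]],
         "' at variant '", ids[bad[1, 1]], "'")
  bad <- which(sby <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-positive standard error for outcome '", out_names[bad[1, 2]],
         "' at variant '", ids[bad[1, 1]], "'")

  summary_data(bx, sbx, by, sby, variant_ids = ids,
               exposure_names = exp_names, outcome_names = out_names)
}

#' Write summary-level MR data to a delimited text file
#'
#' Inverse of [read_summary_data()] under the default column layout.
#'
#' @param data a [summary_data()] object.
#' @param path output path; `.csv` implies comma separation, else tab.
#' @param sep field separator override.
#' @return `path`, invisibly.
#' @export
write_summary_data <- function(data, path, sep = NULL) {
  stopifnot(inherits(data, "summary_data"))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- data.frame(variant = data$variant_ids, stringsAsFactors = FALSE)
  for (j in seq_len(data$p)) {
    out[[paste0("bx_", data$exposure_names[j])]] <- data$beta_x[, j]
    out[[paste0("sebx_", data$exposure_names[j])]] <- data$se_x[, j]
  }
  for (k in seq_len(data$q)) {
    out[[paste0("by_", data$outcome_names[k])]] <- data$beta_y[, k]
    out[[paste0("seby_", data$outcome_names[k])]] <- data$se_y[, k]
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Inverse-variance-weighted standardization for multi-response MR
#'
#' Rescales each variant's summary statistics by a per-variant scale so that
#' the regression of standardized outcome associations on standardized
#' exposure associations with unit weights reproduces inverse-variance
#' weighting. With several outcomes the weight is derived jointly from all
#' responses: row i of both `beta_y` and `beta_x` is divided by
#' \deqn{v_i = \left(q^{-1} \sum_k \mathrm{se}(\beta_{Y_{ik}})^{-2}\right)^{-1/2},}
#' the precision-averaged per-variant scale; the residual covariance of the
#' standardized system then has a response-independent diagonal, which is the
#' form the multi-response likelihood assumes. For a single outcome
#' (`mode = "per_outcome"`, q = 1 only) this reduces to the classical
#' first-order IVW weights se(\eqn{\beta_Y})^{-1}.
#'
#' @param data a [summary_data()] object.
#' @param mode `"joint_precision"` (default), `"per_outcome"` (q = 1 only) or
#'   `"none"`.
#' @return An object of class `standardized_data`: list with `beta_x_std`,
#'   `beta_y_std`, `weights` (the \eqn{v_i}), `standardization_mode`, and the
#'   label vectors. Re-standardizing an already standardized object errors.
#' @export
ivw_standardize <- function(data,
                            mode = c("joint_precision", "per_outcome", "none")) {
  if (inherits(data, "standardized_data"))
    stop("data are already standardized; applying weights twice is not allowed")
  stopifnot(inherits(data, "summary_data"))
  mode <- match.arg(mode)
  if (mode == "per_outcome" && data$q > 1)
    stop("per_outcome standardization is only defined for a single outcome; ",
         "use joint_precision for q > 1")
  v <- switch(mode,
    joint_precision = 1 / sqrt(rowMeans(data$se_y^-2)),
    per_outcome = data$se_y[, 1],
    none = rep(1, data$n))
  v <- unname(v)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("non-finite or non-positive standardization weights")
  structure(list(beta_x_std = data$beta_x / v,
                 beta_y_std = data$beta_y / v,
                 weights = v,
                 standardization_mode = mode,
                 variant_ids = data$variant_ids,
                 exposure_names = data$exposure_names,
                 outcome_names = data$outcome_names,
                 n = data$n, p = data$p, q = data$q),
            class = "standardized_data")
}

#' Empirical correlation between outcome summary statistics
#'
#' Pairwise correlation across variants of the genetic associations with the
#' outcomes. This raw correlation mixes exposure-driven correlation with
#' residual (pleiotropy- or error-driven) correlation; contrast it with the
#' residual correlation estimated by [fit_mr2()] or with
#' [residual_outcome_correlation()].
#'
#' @param data a [summary_data()] or `standardized_data` object.
#' @return q x q correlation matrix.
#' @export
empirical_outcome_correlation <- function(data) {
  by <- if (inherits(data, "standardized_data")) data$beta_y_std else data$beta_y
  if (nrow(by) < 3) stop("need at least 3 variants")
  sds <- apply(by, 2, stats::sd)
  if (any(sds == 0))
    stop("constant outcome column: correlation undefined for '",
         colnames(by)[which(sds == 0)[1]], "'")
  stats::cor(by)
}

#' Residual correlation between outcomes after regressing out the exposures
#'
#' Least-squares analogue of the model-based residual correlation: each
#' outcome association column is regressed on all exposure association
#' columns, and the correlation of the residuals is returned.
#'
#' @param data a [summary_data()] or `standardized_data` object.
#' @return q x q correlation matrix of exposure-adjusted outcome residuals.
#' @export
residual_outcome_correlation <- function(data) {
  if (inherits(data, "standardized_data")) {
    bx <- data$beta_x_std; by <- data$beta_y_std
  } else {
    bx <- data$beta_x; by <- data$beta_y
  }
  if (nrow(by) < ncol(bx) + 3) stop("too few variants to adjust for exposures")
  res <- stats::lm.fit(cbind(1, bx), by)$residuals
  stats::cor(res)
}
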