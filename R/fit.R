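#' Coefficient of determination and derived fit statistics
#'
#' `r_squared` computes \eqn{R^2 = 1 - SSE/SST} with the total sum of
#' squares taken about the observed mean. `adjusted_r_squared` applies the
#' degrees-of-freedom correction \eqn{1 - (1-R^2)(n-1)/(n-p-1)} and
#' `f_statistic` the overall regression F,
#' \eqn{F = (R^2/p) / ((1-R^2)/(n-p-1))}, on (p, n-p-1) degrees of freedom.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param r2 An R-squared value.
#' @param n Sample count.
#' @param p Number of non-intercept model terms.
#' @return A single numeric value.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) {
    stop("observed response has zero variance; R-squared undefined",
         call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / sst
}

#' @rdname r_squared
#' @export
adjusted_r_squared <- function(r2, n, p) {
  stopifnot(n > p + 1)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' @rdname r_squared
#' @export
f_statistic <- function(r2, n, p) {
  stopifnot(n > p + 1)
  (r2 / p) / ((1 - r2) / (n - p - 1))
}

#' Friedman lack-of-fit score
#'
#' The model-selection criterion used as the fitness of the genetic
#' function approximation search:
#' \deqn{LOF = \frac{SSE/n}{\left(1 - (c + d\,p)/n\right)^2}}
#' where `c` counts the basis functions (non-intercept terms), `p` the
#' total number of estimated coefficients including the intercept, and `d`
#' is the smoothing factor (default 0.5, the study setting). Lower is
#' better; at fixed SSE the score grows with model size, penalizing
#' over-fitting on small training sets.
#'
#' @param sse Sum of squared residuals.
#' @param n Sample count.
#' @param c_basis Number of non-intercept basis functions in the model.
#' @param p_params Total number of coefficients including the intercept.
#' @param d_smooth Smoothing factor d (default 0.5).
#' @return The LOF score (numeric).
#' @examples
#' friedman_lof(0.005291, n = 12, c_basis = 5, p_params = 6) # about 0.00397
#' @export
friedman_lof <- function(sse, n, c_basis, p_params, d_smooth = 0.5) {
  stopifnot(sse >= 0, n > 0, c_basis >= 0, p_params >= 1, d_smooth >= 0)
  denom <- 1 - (c_basis + d_smooth * p_params) / n
  if (denom <= 0) {
    stop("LOF undefined: c + d*p >= n (model too large for the sample)",
         call. = FALSE)
  }
  (sse / n) / denom^2
}

ols_engine <- function(X, y) {
  Xf <- cbind("(Intercept)" = 1, X)
  n <- nrow(Xf)
  p <- ncol(X)
  if (n < ncol(Xf)) {
    stop("need at least p + 1 = ", ncol(Xf), " rows to fit ", p,
         " terms; got ", n, call. = FALSE)
  }
  qrx <- qr(Xf)
  if (qrx$rank < ncol(Xf)) {
    dropped <- colnames(Xf)[qrx$pivot[seq(qrx$rank + 1L, ncol(Xf))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  fitted <- as.numeric(Xf %*% beta)
  hat <- rowSums(qr.Q(qrx)^2)
  list(beta = beta, fitted = fitted, residuals = y - fitted, hat = hat,
       n = n, p = p)
}

fit_stats <- function(y, fitted, n, p, hat = NULL, d_smooth = 0.5) {
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  exact <- n == p + 1
  q2 <- NA_real_
  if (!is.null(hat) && n >= p + 3 && all(hat < 1 - 1e-10)) {
    press <- sum(((y - fitted) / (1 - hat))^2)
    q2 <- 1 - press / sst
  }
  lof <- if (p + d_smooth * (p + 1) < n) {
    friedman_lof(sse, n, c_basis = p, p_params = p + 1, d_smooth = d_smooth)
  } else {
    NA_real_ # model saturates the sample; LOF denominator vanishes
  }
  structure(list(
    n = n, p = p, SSE = sse, SST = sst, R2 = r2,
    R2_adj = if (exact) NA_real_ else adjusted_r_squared(r2, n, p),
    F = if (exact) NA_real_ else f_statistic(r2, n, p),
    LOF = lof,
    q2_loo = q2
  ), class = "qsar_fit_stats")
}

#' @export
print.qsar_fit_stats <- function(x, ...) {
  cat(sprintf(
    "n = %d, p = %d, SSE = %.6g, R2 = %.4f, R2_adj = %.4f, F = %.2f,\nLOF = %.5g, LOO q2 = %.4f\n",
    x$n, x$p, x$SSE, x$R2, x$R2_adj, x$F, x$LOF, x$q2_loo))
  invisible(x)
}

#' Ordinary least-squares fit of a QSAR model
#'
#' Fits an intercept plus the requested terms to a descriptor table by
#' least squares and returns the fitted [qsar_model()] together with the
#' full validation-statistics suite: SSE, SST, R2, adjusted R2, F,
#' Friedman lack-of-fit ([friedman_lof()]) and leave-one-out
#' cross-validated q2 (computed through the hat-matrix identity;
#' see [loo_q2()]).
#'
#' A rank-deficient design (collinear descriptors) is an explicit error
#' naming the offending columns. Fitting requires at least `p + 1` rows;
#' with exactly `p + 1` the fit interpolates and the degrees-of-freedom
#' statistics are `NA`.
#'
#' @param table A [descriptor_table()] (typically the training rows).
#' @param terms Character vector of descriptor names (identity terms) or a
#'   list of [model_term()]s.
#' @param response Response column name (default "observed_log").
#' @param lipase_id Optional label recorded in the returned model.
#' @param d_smooth LOF smoothing factor (default 0.5).
#' @param provenance Provenance tag for the fitted model.
#' @return A list of class `qsar_fit` with elements `model` ([qsar_model()])
#'   and `stats` (`qsar_fit_stats`).
#' @examples
#' tbl <- load_fixture("L-A1")
#' fit <- fit_ols(training_rows(tbl),
#'                c("ALogP_MR", "Molecular_Volume", "Molecular_PolarSASA",
#'                  "Shadow_XYfrac", "Jurs_PPSA_3"))
#' fit$stats$R2 # about 0.983
#' @export
fit_ols <- function(table, terms, response = "observed_log",
                    lipase_id = attr(table, "lipase_id"), d_smooth = 0.5,
                    provenance = "fitted") {
  terms <- as_term_list(terms)
  y <- table[[response]]
  if (is.null(y)) stop("response column '", response, "' not found",
                       call. = FALSE)
  X <- design_matrix(table, terms)
  eng <- ols_engine(X, y)
  fitted_terms <- Map(function(tm, b) {
    tm$coefficient <- b
    tm
  }, terms, as.numeric(eng$beta[-1]))
  model <- qsar_model(eng$beta[[1]], fitted_terms, lipase_id = lipase_id,
                      provenance = provenance,
                      aliases = attr(table, "aliases"))
  stats <- fit_stats(y, eng$fitted, eng$n, eng$p, hat = eng$hat,
                     d_smooth = d_smooth)
  structure(list(model = model, stats = stats, fitted = eng$fitted,
                 residuals = eng$residuals, response = response),
            class = "qsar_fit")
}

#' @export
print.qsar_fit <- function(x, ...) {
  print(x$model)
  print(x$stats)
  invisible(x)
}

#' Leave-one-out cross-validated q2
#'
#' For each row the model is refitted on the remaining n - 1 rows and used
#' to predict the held-out observation; the criterion is
#' \eqn{q^2 = 1 - PRESS/SST}. For least squares the deleted residuals are
#' obtained exactly through the hat-matrix identity
#' \eqn{e_{(i)} = e_i / (1 - h_{ii})}, which equals the literal n-refit
#' loop to machine precision.
#'
#' @inheritParams fit_ols
#' @return The q2 value.
#' @export
loo_q2 <- function(table, terms, response = "observed_log") {
  terms <- as_term_list(terms)
  y <- table[[response]]
  X <- design_matrix(table, terms)
  eng <- ols_engine(X, y)
  if (eng$n < eng$p + 3) {
    stop("need at least p + 3 rows for leave-one-out validation",
         call. = FALSE)
  }
  if (any(eng$hat >= 1 - 1e-10)) {
    stop("a leave-one-out refit is rank-deficient (leverage 1 row)",
         call. = FALSE)
  }
  press <- sum((eng$residuals / (1 - eng$hat))^2)
  1 - press / sum((y - mean(y))^2)
}

#' Standardized regression coefficients and descriptor importance
#'
#' For each model term the standardized magnitude
#' \eqn{|b_j| \cdot sd(x_j) / sd(y)} is computed, where \eqn{x_j} is the
#' transformed regressor column and y the response; terms are returned in
#' decreasing order of magnitude (ties broken by term label), giving the
#' descriptor-importance ranking. The measure is invariant to rescaling a
#' descriptor column, since the coefficient absorbs the inverse scale.
#'
#' @param model A fitted [qsar_model()].
#' @param table The table the model was fitted on.
#' @param response Response column name.
#' @return A data.frame with columns `term`, `descriptor`,
#'   `std_coefficient` and `rank`.
#' @export
standardized_coefficients <- function(model, table,
                                      response = "observed_log") {
  stopifnot(inherits(model, "qsar_model"))
  y <- table[[response]]
  aliases <- attr(table, "aliases") %||% model$aliases
  X <- design_matrix(table, model$terms, aliases = aliases)
  sds <- apply(X, 2, sd)
  if (any(sds <= 0)) {
    stop("zero-variance regressor: ",
         paste(colnames(X)[sds <= 0], collapse = ", "), call. = FALSE)
  }
  coefs <- vapply(model$terms, function(tm) tm$coefficient, 0)
  std <- abs(coefs) * sds / sd(y)
  out <- data.frame(
    term = colnames(X),
    descriptor = vapply(model$terms, function(tm) tm$descriptor, ""),
    std_coefficient = std,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$std_coefficient, out$term), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Partial least squares fit of a QSAR term set (G/PLS refinement)
#'
#' Fits a PLS regression on the transformed design of the given terms,
#' as the post-search refinement applied to a GFA-selected term set. With
#' `n_components` equal to the number of terms on a full-rank design the
#' coefficients coincide with [fit_ols()]. Requires the mixOmics package.
#'
#' @inheritParams fit_ols
#' @param n_components Number of latent components, between 1 and the
#'   number of terms.
#' @param scale Autoscale the regressors before extraction (default TRUE).
#' @return A `qsar_fit` list with the PLS-coefficient model (provenance
#'   "gpls") and its training statistics (q2 is left `NA`; use [loo_q2()]
#'   on the term set for cross-validation).
#' @export
fit_gpls <- function(table, terms, response = "observed_log",
                     n_components, scale = TRUE,
                     lipase_id = attr(table, "lipase_id")) {
  if (!requireNamespace("mixOmics", quietly = TRUE)) {
    stop("fit_gpls requires the mixOmics package", call. = FALSE)
  }
  terms <- as_term_list(terms)
  y <- table[[response]]
  X <- design_matrix(table, terms)
  p <- ncol(X)
  if (n_components < 1 || n_components > p) {
    stop("n_components must be between 1 and ", p, call. = FALSE)
  }
  fit <- mixOmics::pls(X, matrix(y, ncol = 1), ncomp = n_components,
                       mode = "regression", scale = scale)
  probe <- rbind(0, diag(p))
  colnames(probe) <- colnames(X)
  pr <- predict(fit, probe)$predict[, 1, n_components]
  intercept <- pr[1]
  beta <- pr[-1] - intercept
  fitted_terms <- Map(function(tm, b) {
    tm$coefficient <- b
    tm
  }, terms, as.numeric(beta))
  model <- qsar_model(intercept, fitted_terms, lipase_id = lipase_id,
                      provenance = "gpls",
                      aliases = attr(table, "aliases"))
  fitted <- as.numeric(intercept + X %*% beta)
  stats <- fit_stats(y, fitted, nrow(X), p)
  stats$q2_loo <- NA_real_
  structure(list(model = model, stats = stats, fitted = fitted,
                 residuals = y - fitted, response = response,
                 n_components = n_components),
            class = "qsar_fit")
}

#' Per-row validation report for a fitted model
#'
#' @param model A fitted [qsar_model()].
#' @param table A [descriptor_table()] with an observed response.
#' @param response Response column name.
#' @return A data.frame with `substrate_id`, `role`, observed, predicted
#'   and residual (observed - predicted) columns.
#' @export
validation_report <- function(model, table, response = "observed_log") {
  pred <- predict(model, table)
  out <- data.frame(
    substrate_id = table$substrate_id,
    role = table$role,
    observed_log = table[[response]],
    predicted_log = pred,
    residual = table[[response]] - pred,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
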