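#' Validate a published lipase model against its bundled study table
#'
#' Runs the full reproduction battery for one lipase:
#' \itemize{
#'   \item column statistics: R2 and adjusted R2 computed between the
#'     observed and originally printed predicted training columns,
#'     compared to the reported values at `r2_tol`;
#'   \item refit reproduction: OLS refit of the published term set on the
#'     12 training rows, per-row agreement with the printed prediction
#'     column at `prediction_tol`;
#'   \item leave-one-out q2 of the refitted term set, compared to the
#'     reported cross-validated R2 at `q2_tol`.
#' }
#'
#' @param lipase_id One of "L-A1", "L-A2", "L-A3".
#' @param r2_tol Tolerance on R2 / adjusted R2 (default 0.002; the printed
#'   prediction columns are rounded to 3 decimals).
#' @param prediction_tol Per-row tolerance in log10 units (default 0.02).
#' @param q2_tol Tolerance on q2 (default 0.05).
#' @return A list of class `lipase_validation`: `lipase_id`, `checks`
#'   (data.frame quantity/computed/reported/tol/pass), `rows` (the
#'   [reproduce_prediction_columns()] report), `fit` (the refit
#'   `qsar_fit`), and `pass` (all checks passed).
#' @examples
#' v <- validate_lipase_model("L-A1")
#' v$checks
#' @export
validate_lipase_model <- function(lipase_id, r2_tol = 0.002,
                                  prediction_tol = 0.02, q2_tol = 0.05) {
  tbl <- load_fixture(lipase_id)
  rec <- published_model(lipase_id)
  printed <- rec$printed_stats
  train <- training_rows(tbl)

  col_r2 <- r_squared(train$observed_log, train$published_pred)
  col_r2_adj <- adjusted_r_squared(col_r2, n = nrow(train), p = 5)

  rows <- reproduce_prediction_columns(lipase_id,
                                       prediction_tol = prediction_tol)
  fit <- attr(rows, "fit")
  q2 <- fit$stats$q2_loo
  max_delta <- max(abs(rows$delta[rows$gated]))

  checks <- data.frame(
    quantity = c("R2 (obs vs printed pred, training)",
                 "adjusted R2 (n=12, p=5)",
                 "max |refit - printed pred| (training)",
                 "LOO q2 (refit term set)"),
    computed = c(col_r2, col_r2_adj, max_delta, q2),
    reported = c(printed$R2, printed$R2_adj, 0, printed$R2_cv),
    tol = c(r2_tol, r2_tol, prediction_tol, q2_tol),
    stringsAsFactors = FALSE
  )
  checks$pass <- abs(checks$computed - checks$reported) <= checks$tol
  structure(list(lipase_id = lipase_id, checks = checks, rows = rows,
                 fit = fit, pass = all(checks$pass)),
            class = "lipase_validation")
}

#' @export
print.lipase_validation <- function(x, ...) {
  cat("Validation of the published", x$lipase_id, "model\n")
  print(x$checks, digits = 4, row.names = FALSE)
  cat(if (x$pass) "all checks passed\n" else "some checks FAILED\n")
  invisible(x)
}

#' Write a validation report to CSV
#'
#' Per-row observed/predicted/residual table followed by a commented
#' stats block (n, p, R2, R2_adj, F, LOF, q2), matching the package's
#' standard report layout.
#'
#' @param fit A `qsar_fit` (from [fit_ols()] or [fit_gpls()]).
#' @param table The table to report on.
#' @param path Output CSV path.
#' @param seed Optional seed to record in the provenance header.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(fit, table, path, seed = NULL) {
  rep <- validation_report(fit$model, table)
  s <- fit$stats
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lipaseQSAR %s%s",
                     as.character(utils::packageVersion("lipaseQSAR")),
                     if (is.null(seed)) "" else paste0(", seed ", seed)),
             con)
  writeLines(sprintf(
    "# n=%d p=%d R2=%.6f R2_adj=%.6f F=%.4f LOF=%.6g q2_loo=%.6f",
    s$n, s$p, s$R2, s$R2_adj, s$F, s$LOF, s$q2_loo), con)
  write.csv(rep, con, row.names = FALSE)
  invisible(path)
}
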