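#' Lipase activity from an NaOH titration record
#'
#' Converts a titrimetric assay record to lipase activity. Free fatty acids
#' released during the 60 min incubation are titrated with standard NaOH;
#' one activity unit (U) is one micromole of fatty acid released per minute,
#' reported per ml of enzyme solution. The conversion is
#' \deqn{X = (B - A) \cdot \frac{c}{0.05} \cdot 50 \cdot \frac{1}{60} \cdot n}
#' where 1 ml of 0.05 mol/L NaOH is equivalent to 50 umol fatty acid and
#' 1/60 converts the 60 min reaction to a per-minute rate.
#'
#' @param B Sample titrant consumption, ml.
#' @param A Blank titrant consumption, ml. Must satisfy `A <= B`.
#' @param c_naoh NaOH concentration, mol/L. Default 0.05 (the standard
#'   solution used in the assay).
#' @param dilution Dilution/normalization factor `n` (dimensionless,
#'   default 1). Activity is linear in this factor.
#' @return Activity in U/ml (vectorized over the inputs).
#' @examples
#' activity_from_titration(B = 2.0, A = 1.0, c_naoh = 0.05) # 50/60 U/ml
#' @export
activity_from_titration <- function(B, A, c_naoh = 0.05, dilution = 1) {
  if (any(!is.finite(B)) || any(!is.finite(A))) {
    stop("titrant volumes must be finite numbers", call. = FALSE)
  }
  if (any(A < 0)) stop("blank volume A must be >= 0", call. = FALSE)
  if (any(B < A)) {
    stop("sample volume B must be >= blank volume A (negative activity)",
         call. = FALSE)
  }
  if (any(c_naoh <= 0)) stop("NaOH concentration must be > 0", call. = FALSE)
  if (any(dilution <= 0)) stop("dilution factor must be > 0", call. = FALSE)
  (B - A) * (c_naoh / 0.05) * 50 * (1 / 60) * dilution
}

#' Log10 transform of lipase activity and its inverse
#'
#' Activities are modeled on the log10 scale throughout; conversion happens
#' only at the I/O edges. Zero or negative activities are rejected rather
#' than clamped, since a silent floor would corrupt model fitting.
#'
#' @param activity Activity in U/ml, strictly positive.
#' @param log_activity log10 activity.
#' @return `to_log_activity` returns log10(activity); `from_log_activity`
#'   returns 10^log_activity.
#' @examples
#' to_log_activity(10)        # 1
#' from_log_activity(1.389)   # about 24.5 U/ml
#' @export
to_log_activity <- function(activity) {
  if (any(!is.finite(activity)) || any(activity <= 0)) {
    stop("activity must be finite and > 0 for the log transform",
         call. = FALSE)
  }
  log10(activity)
}

#' @rdname to_log_activity
#' @export
from_log_activity <- function(log_activity) {
  if (any(!is.finite(log_activity))) {
    stop("log activity must be finite", call. = FALSE)
  }
  10^log_activity
}
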