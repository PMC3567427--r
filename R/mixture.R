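#' Default homotriglyceride molar masses
#'
#' Natural oils are modeled as mixtures of homotriglycerides (all three
#' acyl chains identical). Molar masses in g/mol for the five fatty acids
#' of the bundled oil compositions: tripalmitin 807.3, tristearin 891.5,
#' triolein 885.4, trilinolenin 873.3, trilinolein 879.4.
#'
#' @return Named numeric vector, names are fatty acid names.
#' @export
default_triglyceride_masses <- function() {
  c(palmitic = 807.3, stearic = 891.5, oleic = 885.4,
    linolenic = 873.3, linoleic = 879.4)
}

#' Oil composition
#'
#' Represents a natural oil as a set of homotriglyceride components with
#' mass fractions (percent by mass) and triglyceride molar masses.
#' Components at or below `min_fraction_pct` (default 1 percent, the
#' study's inclusion rule) are dropped with a message. Mass fractions may
#' sum to slightly more than 100 because printed compositions are rounded;
#' more than 101 is an error.
#'
#' @param oil Oil name.
#' @param fatty_acid Character vector of fatty acid names.
#' @param mass_fraction_pct Mass fractions, percent by mass.
#' @param molar_mass Triglyceride molar masses in g/mol; defaults come
#'   from [default_triglyceride_masses()] keyed by fatty acid name.
#' @param mass_fraction_sd_pct Optional reported uncertainty of the mass
#'   fractions (carried along, never used in the point prediction).
#' @param min_fraction_pct Inclusion threshold (default 1).
#' @return A data.frame of class `oil_composition`.
#' @examples
#' olive <- oil_composition("Olive oil",
#'   c("palmitic", "stearic", "oleic", "linolenic", "linoleic"),
#'   c(14.5, 2.5, 70.0, 1.5, 12.0))
#' mole_fractions(olive)
#' @export
oil_composition <- function(oil, fatty_acid, mass_fraction_pct,
                            molar_mass = NULL,
                            mass_fraction_sd_pct = NULL,
                            min_fraction_pct = 1) {
  stopifnot(length(fatty_acid) == length(mass_fraction_pct),
            length(fatty_acid) >= 1L)
  if (anyDuplicated(fatty_acid)) {
    stop("duplicated fatty acid in composition", call. = FALSE)
  }
  if (is.null(molar_mass)) {
    defaults <- default_triglyceride_masses()
    unknown <- setdiff(fatty_acid, names(defaults))
    if (length(unknown)) {
      stop("no default triglyceride molar mass for: ",
           paste(unknown, collapse = ", "),
           "; supply `molar_mass` explicitly", call. = FALSE)
    }
    molar_mass <- unname(defaults[fatty_acid])
  }
  if (any(!is.finite(molar_mass)) || any(molar_mass <= 0)) {
    stop("molar masses must be finite and > 0", call. = FALSE)
  }
  if (any(mass_fraction_pct < 0)) {
    stop("mass fractions must be >= 0", call. = FALSE)
  }
  if (sum(mass_fraction_pct) > 101) {
    stop("mass fractions sum to more than 100% (", sum(mass_fraction_pct),
         ")", call. = FALSE)
  }
  keep <- mass_fraction_pct > min_fraction_pct
  if (!any(keep)) stop("no component above the inclusion threshold",
                       call. = FALSE)
  if (any(!keep)) {
    message("dropping component(s) at or below ", min_fraction_pct, "%: ",
            paste(fatty_acid[!keep], collapse = ", "))
  }
  out <- data.frame(
    fatty_acid = fatty_acid[keep],
    mass_fraction_pct = mass_fraction_pct[keep],
    molar_mass = molar_mass[keep],
    stringsAsFactors = FALSE
  )
  if (!is.null(mass_fraction_sd_pct)) {
    out$mass_fraction_sd_pct <- mass_fraction_sd_pct[keep]
  }
  rownames(out) <- NULL
  structure(out, oil = oil, class = c("oil_composition", "data.frame"))
}

#' Mole fractions of an oil's triglyceride components
#'
#' Converts mass fractions to normalized mole fractions:
#' \deqn{w_i = \frac{y_i / M_i}{\sum_j y_j / M_j}}
#' where `y_i` is the mass fraction and `M_i` the triglyceride molar mass.
#' The weights sum to 1 and are invariant to proportional rescaling of all
#' mass fractions.
#'
#' @param comp An [oil_composition()].
#' @return Named numeric vector of weights summing to 1.
#' @export
mole_fractions <- function(comp) {
  stopifnot(inherits(comp, "oil_composition"), nrow(comp) >= 1L)
  m <- comp$mass_fraction_pct / comp$molar_mass
  setNames(m / sum(m), comp$fatty_acid)
}

#' Mixture activity as the weighted mean of component activities
#'
#' The hydrolysis activity of a lipase on a mixed substrate is modeled as
#' the mole-fraction-weighted arithmetic mean of the activities on its
#' components, on the linear U/ml scale (titration activity is additive in
#' released fatty acids):
#' \deqn{X_{mix} = \sum_i w_i X_i}
#' The result is a convex combination, so it always lies between the
#' smallest and largest component activity. `mode = "simple_mean"` gives
#' the unweighted average over components instead (an alternative reading
#' of the mixture rule; the mole-weighted form is the default).
#'
#' @param weights Component weights (must sum to 1 for the weighted mode).
#' @param activities Component activities X_i in U/ml, nonnegative.
#' @param mode "mole_weighted" (default) or "simple_mean".
#' @return A list of class `mixture_prediction` with `X_mix`, `weights`,
#'   `activities` and `mode`.
#' @export
predict_mixture <- function(weights, activities,
                            mode = c("mole_weighted", "simple_mean")) {
  mode <- match.arg(mode)
  if (length(weights) != length(activities)) {
    stop("weights and activities must have the same length", call. = FALSE)
  }
  if (any(activities < 0)) stop("activities must be >= 0", call. = FALSE)
  if (mode == "mole_weighted") {
    if (abs(sum(weights) - 1) > 1e-8) {
      stop("weights must sum to 1", call. = FALSE)
    }
    x_mix <- sum(weights * activities)
  } else {
    weights <- rep(1 / length(activities), length(activities))
    x_mix <- mean(activities)
  }
  structure(list(X_mix = x_mix, weights = weights,
                 activities = activities, mode = mode),
            class = "mixture_prediction")
}

#' @export
print.mixture_prediction <- function(x, ...) {
  cat(sprintf("Predicted mixture activity X_mix = %.2f U/ml (%s)\n",
              x$X_mix, x$mode))
  if (!is.null(x$components)) print(x$components, digits = 4)
  invisible(x)
}

#' Predict lipase activity on a natural oil
#'
#' Chains the full mixture pipeline: evaluate a QSAR model on each
#' homotriglyceride component (log10 scale), back-transform to U/ml, then
#' average with mole-fraction weights ([mole_fractions()] +
#' [predict_mixture()]).
#'
#' @param lipase_id A lipase label whose published equation is used, or
#'   pass `model` directly.
#' @param comp An [oil_composition()].
#' @param component_table A data.frame with a `fatty_acid` column and one
#'   column per descriptor required by the model, one row per
#'   homotriglyceride. Components missing from it are an error listing the
#'   gaps (the bundled study tables cover only some homotriglycerides; the
#'   full component descriptor set was never published, so it must be
#'   supplied by the user).
#' @param model Optional [qsar_model()] overriding `lipase_id`'s published
#'   equation.
#' @param mode Averaging mode, see [predict_mixture()].
#' @return A `mixture_prediction` with an extra `components` data.frame
#'   (fatty acid, weight, predicted log activity, activity in U/ml) and
#'   the oil/lipase labels.
#' @export
predict_oil <- function(lipase_id, comp, component_table, model = NULL,
                        mode = c("mole_weighted", "simple_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(comp, "oil_composition"))
  if (is.null(model)) model <- published_model(lipase_id)$model
  if (!"fatty_acid" %in% names(component_table)) {
    stop("component_table needs a 'fatty_acid' column", call. = FALSE)
  }
  idx <- match(comp$fatty_acid, component_table$fatty_acid)
  if (anyNA(idx)) {
    stop("missing descriptor rows for component(s): ",
         paste(comp$fatty_acid[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  rows <- component_table[idx, , drop = FALSE]
  log_pred <- predict(model, rows)
  act <- from_log_activity(log_pred)
  w <- mole_fractions(comp)
  pred <- predict_mixture(unname(w), act, mode = mode)
  pred$components <- data.frame(
    fatty_acid = comp$fatty_acid,
    mass_fraction_pct = comp$mass_fraction_pct,
    molar_mass = comp$molar_mass,
    weight = unname(w),
    log_pred = log_pred,
    activity_Uml = act,
    stringsAsFactors = FALSE
  )
  pred$oil <- attr(comp, "oil")
  pred$lipase_id <- model$lipase_id
  pred
}

#' Bundled oil composition and activity tables
#'
#' `load_oil_compositions()` returns the two bundled vegetable oil
#' compositions (soybean and olive; mass fractions with reported
#' uncertainties) as a named list of [oil_composition()] objects with
#' default triglyceride molar masses. `load_oil_activity_table()` returns
#' the measured and originally predicted activities (U/ml) for those oils
#' under all three lipases.
#'
#' @return See description.
#' @export
load_oil_compositions <- function() {
  path <- system.file("extdata", "table1_oils.csv", package = "lipaseQSAR",
                      mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(raw, raw$oil), function(d) {
    oil_composition(d$oil[1], d$fatty_acid, d$mass_fraction_pct,
                    mass_fraction_sd_pct = d$mass_fraction_sd_pct)
  })
  out[unique(raw$oil)]
}

#' @rdname load_oil_compositions
#' @export
load_oil_activity_table <- function() {
  path <- system.file("extdata", "table5_oil_activities.csv",
                      package = "lipaseQSAR", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
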