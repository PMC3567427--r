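#' QSAR model terms
#'
#' A model term pairs a descriptor with a coefficient and a basis
#' transform. Besides the identity, the truncated-linear (hockey-stick)
#' spline bases used by genetic function approximation are supported:
#' `spline_above` with knot `k` contributes `max(x - k, 0)` (written
#' `<x - k>`), `spline_below` contributes `max(k - x, 0)` (written
#' `<k - x>`). Both are piecewise linear, continuous and nonnegative.
#'
#' @param descriptor Descriptor name.
#' @param coefficient Regression coefficient (may be `NA` before fitting).
#' @param transform One of "identity", "spline_above", "spline_below".
#' @param knot Spline knot; required (finite) for the spline transforms.
#' @return An object of class `model_term`.
#' @export
model_term <- function(descriptor, coefficient = NA_real_,
                       transform = c("identity", "spline_above",
                                     "spline_below"),
                       knot = NA_real_) {
  transform <- match.arg(transform)
  stopifnot(is.character(descriptor), length(descriptor) == 1L,
            nzchar(descriptor))
  if (transform != "identity" && !is.finite(knot)) {
    stop("spline transforms require a finite knot", call. = FALSE)
  }
  structure(list(descriptor = descriptor,
                 coefficient = as.numeric(coefficient),
                 transform = transform,
                 knot = as.numeric(knot)),
            class = "model_term")
}

apply_transform <- function(x, transform, knot = NA_real_) {
  switch(transform,
         identity = x,
         spline_above = pmax(x - knot, 0),
         spline_below = pmax(knot - x, 0),
         stop("unknown transform: ", transform, call. = FALSE))
}

term_label <- function(term) {
  switch(term$transform,
         identity = term$descriptor,
         spline_above = sprintf("<%s - %g>", term$descriptor, term$knot),
         spline_below = sprintf("<%g - %s>", term$knot, term$descriptor))
}

term_id <- function(term) paste(term$descriptor, term$transform, sep = ":")

as_term_list <- function(terms) {
  if (inherits(terms, "model_term")) return(list(terms))
  if (is.character(terms)) return(lapply(terms, model_term))
  if (is.list(terms) && all(vapply(terms, inherits, TRUE, "model_term"))) {
    return(terms)
  }
  stop("`terms` must be a character vector of descriptor names or a list ",
       "of model_term objects", call. = FALSE)
}

#' Linear-plus-spline QSAR models
#'
#' The object form of a fitted or published lipase activity equation:
#' an intercept plus a list of [model_term()]s, predicting log10 activity
#' (U/ml).
#'
#' @param intercept Model intercept.
#' @param terms List of [model_term()]s (or character vector of descriptor
#'   names for identity terms). At least one term; `(descriptor, transform)`
#'   pairs must be unique.
#' @param lipase_id Optional lipase label.
#' @param provenance One of "published", "fitted", "gfa", "gpls".
#' @param aliases Named character vector mapping model descriptor symbols to
#'   table column names, consulted when a symbol is absent from a table.
#' @return An object of class `qsar_model`.
#' @export
qsar_model <- function(intercept, terms, lipase_id = NULL,
                       provenance = c("fitted", "published", "gfa", "gpls"),
                       aliases = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))
  terms <- as_term_list(terms)
  if (length(terms) < 1L) stop("a model needs at least one term",
                               call. = FALSE)
  ids <- vapply(terms, term_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate (descriptor, transform) pair in model terms",
         call. = FALSE)
  }
  structure(list(intercept = as.numeric(intercept), terms = terms,
                 lipase_id = lipase_id, provenance = provenance,
                 aliases = aliases),
            class = "qsar_model")
}

resolve_column <- function(descriptor, table, aliases) {
  if (descriptor %in% names(table)) return(descriptor)
  if (!is.null(aliases) && descriptor %in% names(aliases) &&
      aliases[[descriptor]] %in% names(table)) {
    return(aliases[[descriptor]])
  }
  NA_character_
}

#' Design matrix for a set of model terms
#'
#' Applies each term's basis transform to its descriptor column, row-wise,
#' without an intercept column. Descriptor symbols are resolved directly or
#' through the alias maps of the model/table.
#'
#' @param table A [descriptor_table()] or data.frame.
#' @param terms List of [model_term()]s or character vector of descriptors.
#' @param aliases Optional named character vector of symbol-to-column
#'   aliases; defaults to the table's alias attribute.
#' @return Numeric matrix, one column per term, labeled with the term's
#'   printed form.
#' @export
design_matrix <- function(table, terms, aliases = NULL) {
  terms <- as_term_list(terms)
  aliases <- aliases %||% attr(table, "aliases")
  cols <- vapply(terms, function(tm) {
    resolve_column(tm$descriptor, table, aliases)
  }, "")
  if (anyNA(cols)) {
    miss <- vapply(terms[is.na(cols)], function(tm) tm$descriptor, "")
    stop("descriptor(s) not found in table: ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  }
  X <- vapply(seq_along(terms), function(j) {
    apply_transform(table[[cols[j]]], terms[[j]]$transform, terms[[j]]$knot)
  }, numeric(nrow(table)))
  X <- matrix(X, nrow = nrow(table))
  colnames(X) <- vapply(terms, term_label, "")
  X
}

#' Predict log10 activity from a QSAR model
#'
#' @param object A [qsar_model()] with non-missing coefficients.
#' @param table A [descriptor_table()] or data.frame supplying the model's
#'   descriptors.
#' @param ... Unused.
#' @return Numeric vector of predicted log10 activities (U/ml).
#' @export
predict.qsar_model <- function(object, table, ...) {
  coefs <- vapply(object$terms, function(tm) tm$coefficient, 0)
  if (anyNA(coefs)) {
    stop("model has unfitted (NA) coefficients", call. = FALSE)
  }
  aliases <- attr(table, "aliases") %||% object$aliases
  X <- design_matrix(table, object$terms, aliases = aliases)
  as.numeric(object$intercept + X %*% coefs)
}

#' @export
print.qsar_model <- function(x, ...) {
  rhs <- vapply(x$terms, function(tm) {
    sprintf("%s %g*%s", if (tm$coefficient < 0) "-" else "+",
            abs(tm$coefficient), term_label(tm))
  }, "")
  cat(sprintf("QSAR model%s [%s]\n",
              if (is.null(x$lipase_id)) "" else paste0(" ", x$lipase_id),
              x$provenance))
  cat("  log10(X) =", format(x$intercept), paste(rhs, collapse = " "), "\n")
  invisible(x)
}

#' Serialize a QSAR model to JSON and back
#'
#' The JSON document stores the lipase label, intercept, term list
#' (descriptor, coefficient, transform, knot), provenance and alias map,
#' and round-trips losslessly at full double precision.
#'
#' @param model A [qsar_model()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @param json A JSON string or file path produced by `model_to_json`.
#' @return `model_to_json`: the JSON string (invisibly if written to file);
#'   `model_from_json`: the reconstructed [qsar_model()].
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "qsar_model"))
  doc <- list(
    lipase_id = model$lipase_id,
    intercept = model$intercept,
    terms = lapply(model$terms, function(tm) {
      list(descriptor = tm$descriptor, coefficient = tm$coefficient,
           transform = tm$transform, knot = tm$knot)
    }),
    provenance = model$provenance,
    aliases = as.list(model$aliases)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(json) {
  if (length(json) == 1L && !grepl("\\{", json) && file.exists(json)) {
    json <- paste(readLines(json), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  terms <- lapply(doc$terms, function(tm) {
    model_term(tm$descriptor,
               coefficient = tm$coefficient %||% NA_real_,
               transform = tm$transform,
               knot = tm$knot %||% NA_real_)
  })
  aliases <- if (length(doc$aliases)) unlist(doc$aliases) else NULL
  qsar_model(doc$intercept, terms, lipase_id = doc$lipase_id,
             provenance = doc$provenance, aliases = aliases)
}
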