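#' Descriptor tables
#'
#' A descriptor table holds one ester substrate per row: an integer
#' `substrate_id`, a `role` ("training" or "test"), one numeric column per
#' molecular descriptor, and optionally `observed_log` (log10 activity in
#' U/ml) plus, for the bundled study tables, `published_pred` and
#' `published_residual` columns transcribed from the original report.
#'
#' `descriptor_table()` validates a data.frame and attaches the descriptor
#' metadata; `descriptors()` retrieves the descriptor column names.
#'
#' @param df A data.frame with at least `substrate_id` and `role` columns.
#' @param descriptors Character vector naming the descriptor columns.
#'   Defaults to every column other than `substrate_id`, `role`,
#'   `observed_log`, `published_pred` and `published_residual`.
#' @param lipase_id Optional label ("L-A1", "L-A2", "L-A3", ...).
#' @param aliases Optional named character vector mapping a model's
#'   descriptor symbol to the column that stores it (see [load_fixture()]).
#' @return An object of class `descriptor_table` (a data.frame).
#' @export
descriptor_table <- function(df, descriptors = NULL, lipase_id = NULL,
                             aliases = NULL) {
  if (!is.data.frame(df)) stop("`df` must be a data.frame", call. = FALSE)
  if (nrow(df) == 0L) stop("descriptor table has no rows", call. = FALSE)
  required <- c("substrate_id", "role")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$substrate_id)) {
    dup <- unique(df$substrate_id[duplicated(df$substrate_id)])
    stop("duplicated substrate_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$role %in% c("training", "test"))) {
    stop("role must be 'training' or 'test'", call. = FALSE)
  }
  reserved <- c("substrate_id", "role", "observed_log",
                "published_pred", "published_residual")
  if (is.null(descriptors)) descriptors <- setdiff(names(df), reserved)
  if (anyDuplicated(descriptors)) {
    stop("descriptor names must be unique", call. = FALSE)
  }
  absent <- setdiff(descriptors, names(df))
  if (length(absent)) {
    stop("descriptor column(s) not in table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(c(descriptors, "observed_log"), names(df))) {
    if (!is.numeric(df[[col]])) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
    if (anyNA(df[[col]])) {
      stop("column '", col, "' contains missing values", call. = FALSE)
    }
  }
  structure(df,
            descriptors = descriptors,
            lipase_id = lipase_id,
            aliases = aliases,
            class = c("descriptor_table", "data.frame"))
}

#' @rdname descriptor_table
#' @param x A `descriptor_table`.
#' @export
descriptors <- function(x) attr(x, "descriptors")

#' Training / test subsets of a descriptor table
#'
#' @param x A `descriptor_table`.
#' @return The rows with the requested role, still a `descriptor_table`.
#' @export
training_rows <- function(x) subset_rows(x, x$role == "training")

#' @rdname training_rows
#' @export
test_rows <- function(x) subset_rows(x, x$role == "test")

subset_rows <- function(x, keep) {
  out <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(out) <- NULL
  descriptor_table(out, descriptors = attr(x, "descriptors"),
                   lipase_id = attr(x, "lipase_id"),
                   aliases = attr(x, "aliases"))
}

#' Read a descriptor table from CSV
#'
#' The CSV dialect is fixed: comma separated, UTF-8, "." decimal separator,
#' mandatory header row. Unparseable numeric cells are hard errors, never
#' silently dropped.
#'
#' @param path Path to a CSV file.
#' @inheritParams descriptor_table
#' @return A [descriptor_table()].
#' @export
read_descriptor_table <- function(path, descriptors = NULL,
                                  lipase_id = NULL, aliases = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty descriptor table: ", path, call. = FALSE)
  required <- c("substrate_id", "role")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  numeric_cols <- setdiff(names(raw), "role")
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & nzchar(trimws(raw[[col]])))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "', row ", bad[1],
           ": '", raw[[col]][bad[1]], "'", call. = FALSE)
    }
    raw[[col]] <- vals
  }
  raw$substrate_id <- as.integer(raw$substrate_id)
  descriptor_table(raw, descriptors = descriptors, lipase_id = lipase_id,
                   aliases = aliases)
}

#' Write a descriptor table to CSV
#'
#' @param x A `descriptor_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fixture_files <- c(
  "L-A1" = "table2_LA1.csv",
  "L-A2" = "table3_LA2.csv",
  "L-A3" = "table4_LA3.csv"
)

#' Load a bundled lipase study table
#'
#' Returns the descriptor/activity table for one of the three alkaline
#' lipases, transcribed verbatim from the original study (16 ester
#' substrates: 12 training, 4 test). Each of the three tables is
#' self-contained; substrate ids are never joined across lipases, because
#' identically numbered rows carry incompatible descriptor values in
#' different tables.
#'
#' For L-A2 the published equation names the descriptor `Jurs_PNSA_1` while
#' the study table's corresponding column is headed `Jurs_FPSA_1`; the
#' column is stored under the printed header and the equation symbol is
#' bound to it through the table's alias map.
#'
#' @param lipase_id One of "L-A1", "L-A2", "L-A3".
#' @return A [descriptor_table()] with `observed_log`, `published_pred` and
#'   `published_residual` columns.
#' @examples
#' tbl <- load_fixture("L-A1")
#' nrow(training_rows(tbl)) # 12
#' @export
load_fixture <- function(lipase_id) {
  if (!is.character(lipase_id) || length(lipase_id) != 1L ||
      !lipase_id %in% names(fixture_files)) {
    stop("unknown lipase_id; expected one of ",
         paste(names(fixture_files), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", fixture_files[[lipase_id]],
                      package = "lipaseQSAR", mustWork = TRUE)
  aliases <- if (lipase_id == "L-A2") c(Jurs_PNSA_1 = "Jurs_FPSA_1") else NULL
  read_descriptor_table(path, lipase_id = lipase_id, aliases = aliases)
}

#' @export
print.descriptor_table <- function(x, ...) {
  id <- attr(x, "lipase_id")
  cat("Descriptor table", if (!is.null(id)) paste0("(", id, ")"), "-",
      nrow(x), "substrates,", length(descriptors(x)), "descriptors,",
      sum(x$role == "training"), "training /", sum(x$role == "test"),
      "test\n")
  print(as.data.frame(x), ...)
  invisible(x)
}
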