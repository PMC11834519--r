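# The performance panel: one row per decision-making unit (DMU), nonnegative
# input columns X and output columns Y, each column tied to an indicator
# definition carrying its role (input/output), 4E dimension and scale.

# shortest decimal string that round-trips exactly: prefer as.character()
# (clean) and fall back to 17 significant digits where it loses precision
fmt_num <- function(x) {
  s <- as.character(x)
  lossy <- !is.na(x) & is.finite(x) & as.numeric(s) != x
  s[lossy] <- sprintf("%.17g", x[lossy])
  s
}

#' Construct a validated DMU input-output panel
#'
#' The panel is the object every analysis stage consumes: `n` facilities
#' (DMUs) by `m` input and `p` output indicators, all entries nonnegative
#' (zeros are legal; the delta-SBM model is designed to tolerate them).
#'
#' @param perspective `"economic"`, `"social"`, or any label for custom
#'   panels.
#' @param dmu_ids character vector of unique DMU identifiers, length `n >= 2`.
#' @param X numeric `n x m` input matrix, `m >= 1`.
#' @param Y numeric `n x p` output matrix, `p >= 1`.
#' @param columns schema data.frame (one row per column of `cbind(X, Y)`,
#'   inputs first) with columns `code`, `name`, `dimension`, `role`, `scale`.
#' @return object of class `performance_panel`: list with elements
#'   `perspective`, `dmu_ids`, `X`, `Y`, `columns`.
#' @seealso [read_panel()], [generate_panel()]
#' @export
performance_panel <- function(perspective, dmu_ids, X, Y, columns) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  validate_schema(columns)
  n <- length(dmu_ids)
  if (n < 2)
    cb_error("carebench_bad_size", sprintf("a panel needs n >= 2 DMUs (got %d)", n))
  if (nrow(X) != n || nrow(Y) != n)
    cb_error("carebench_bad_size", "X and Y must have one row per DMU")
  if (ncol(X) < 1 || ncol(Y) < 1)
    cb_error("carebench_bad_size", "need at least one input and one output column")
  if (anyDuplicated(dmu_ids))
    cb_error("carebench_duplicate_dmu", sprintf(
      "duplicate dmu_id(s): %s",
      paste(unique(dmu_ids[duplicated(dmu_ids)]), collapse = ", ")))
  if (nrow(columns) != ncol(X) + ncol(Y))
    cb_error("carebench_bad_schema", "schema must have one row per panel column")
  roles <- c(rep("input", ncol(X)), rep("output", ncol(Y)))
  if (!all(columns$role == roles))
    cb_error("carebench_bad_schema",
             "schema roles must list all inputs first, then all outputs, matching X and Y")
  M <- cbind(X, Y)
  if (anyNA(M)) {
    idx <- which(is.na(M), arr.ind = TRUE)[1, ]
    cb_error("carebench_missing_value", sprintf(
      "missing value at dmu_id '%s', column '%s'",
      dmu_ids[idx[1]], columns$code[idx[2]]))
  }
  if (any(M < 0)) {
    idx <- which(M < 0, arr.ind = TRUE)[1, ]
    cb_error("carebench_negative_value", sprintf(
      "negative value %g at dmu_id '%s', column '%s'",
      M[idx[1], idx[2]], dmu_ids[idx[1]], columns$code[idx[2]]))
  }
  colnames(X) <- columns$code[columns$role == "input"]
  colnames(Y) <- columns$code[columns$role == "output"]
  rownames(X) <- rownames(Y) <- dmu_ids
  structure(list(perspective = perspective, dmu_ids = as.character(dmu_ids),
                 X = X, Y = Y, columns = columns),
            class = "performance_panel")
}

#' Read a DMU panel from CSV plus a schema sidecar
#'
#' The CSV must have a `dmu_id` column plus exactly one column per schema
#' entry; column roles and 4E dimensions always come from the schema
#' (a data.frame, the built-in names `"economic"`/`"social"`, or a sidecar
#' file path — see [read_schema()]), never from the CSV headers.
#' Validation failures raise distinct classed errors naming the offending
#' row and column: `carebench_missing_column`, `carebench_negative_value`,
#' `carebench_non_numeric`, `carebench_duplicate_dmu`.
#'
#' @param path CSV file path.
#' @param schema schema specification (see above).
#' @param perspective optional perspective label; defaults to `"economic"`
#'   or `"social"` when the corresponding built-in schema is used, else
#'   `"custom"`.
#' @return a [performance_panel()].
#' @export
read_panel <- function(path, schema, perspective = NULL) {
  if (!file.exists(path))
    cb_error("carebench_missing_file", sprintf("panel file not found: %s", path))
  sc <- resolve_schema(schema)
  if (is.null(perspective)) {
    perspective <- if (identical(sc$code, economic_schema()$code)) "economic"
                   else if (identical(sc$code, social_schema()$code)) "social"
                   else "custom"
  }
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (!"dmu_id" %in% names(df))
    cb_error("carebench_missing_column", "panel file has no 'dmu_id' column")
  missing <- setdiff(sc$code, names(df))
  if (length(missing) > 0)
    cb_error("carebench_missing_column", sprintf(
      "panel file is missing schema column(s): %s", paste(missing, collapse = ", ")))
  dmu_ids <- df$dmu_id
  if (anyDuplicated(dmu_ids))
    cb_error("carebench_duplicate_dmu", sprintf(
      "duplicate dmu_id(s): %s",
      paste(unique(dmu_ids[duplicated(dmu_ids)]), collapse = ", ")))
  M <- matrix(NA_real_, nrow(df), nrow(sc),
              dimnames = list(NULL, sc$code))
  for (j in seq_len(nrow(sc))) {
    raw <- df[[sc$code[j]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & trimws(raw) != "")
    if (length(bad) > 0)
      cb_error("carebench_non_numeric", sprintf(
        "non-numeric cell '%s' at dmu_id '%s', column '%s'",
        raw[bad[1]], dmu_ids[bad[1]], sc$code[j]))
    M[, j] <- val
  }
  performance_panel(perspective, dmu_ids,
                    X = M[, sc$role == "input", drop = FALSE],
                    Y = M[, sc$role == "output", drop = FALSE],
                    columns = sc)
}

#' Write a DMU panel to CSV
#'
#' Numbers are written with R's shortest round-trip representation, so
#' `read_panel()` on the written file reproduces the panel bit-exactly.
#'
#' @param panel a [performance_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "performance_panel"))
  M <- cbind(panel$X, panel$Y)
  out <- data.frame(dmu_id = panel$dmu_ids, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(M))) out[[colnames(M)[j]]] <- fmt_num(M[, j])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.performance_panel <- function(x, ...) {
  cat(sprintf("Performance panel (%s perspective): %d DMUs, %d inputs, %d outputs\n",
              x$perspective, length(x$dmu_ids), ncol(x$X), ncol(x$Y)))
  cat(sprintf("  inputs:  %s\n", paste(colnames(x$X), collapse = ", ")))
  cat(sprintf("  outputs: %s\n", paste(colnames(x$Y), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.performance_panel <- function(x, ...) {
  data.frame(dmu_id = x$dmu_ids, cbind(x$X, x$Y), check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}
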