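# 4E indicator system: the candidate catalog, the final economic and social
# input-output schemas, and Spearman-based screening of collinear indicators.

FOUR_E <- c("Economy", "Efficiency", "Effectiveness", "Equity")
SCALES <- c("monetary", "count", "ratio", "rating")
ROLES <- c("input", "output", "candidate")

cb_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "carebench_error", "error")))
}

new_schema <- function(code, name, dimension, role, scale) {
  df <- data.frame(code = code, name = name, dimension = dimension,
                   role = role, scale = scale, stringsAsFactors = FALSE)
  validate_schema(df)
  df
}

validate_schema <- function(schema) {
  need <- c("code", "name", "dimension", "role", "scale")
  if (!is.data.frame(schema) || !all(need %in% names(schema)))
    cb_error("carebench_bad_schema",
             "schema must be a data.frame with columns code, name, dimension, role, scale")
  if (anyDuplicated(schema$code))
    cb_error("carebench_bad_schema", sprintf(
      "duplicate indicator code(s): %s",
      paste(unique(schema$code[duplicated(schema$code)]), collapse = ", ")))
  bad <- setdiff(schema$dimension, FOUR_E)
  if (length(bad) > 0)
    cb_error("carebench_bad_schema",
             sprintf("dimension must be one of %s (got: %s)",
                     paste(FOUR_E, collapse = "/"), paste(bad, collapse = ", ")))
  if (!all(schema$role %in% ROLES))
    cb_error("carebench_bad_schema", "role must be input, output or candidate")
  if (!all(schema$scale %in% SCALES))
    cb_error("carebench_bad_schema",
             sprintf("scale must be one of %s", paste(SCALES, collapse = "/")))
  invisible(schema)
}

#' Candidate performance indicators for community-care facilities
#'
#' The full candidate catalog of 25 indicators (codes `C1`..`C25`) organised
#' by the four 4E dimensions: Economy (construction/operating costs and
#' subsidies, profitability), Efficiency (personnel and service counts,
#' coverage rate), Effectiveness (service functions, satisfaction, quality
#' of life, re-employment) and Equity (institutional ratings, equity of
#' delivery, complaint status). These are candidates for Spearman screening;
#' the final perspectives are in [economic_schema()] and [social_schema()].
#'
#' @return data.frame with columns `code`, `name`, `dimension`, `role`
#'   (all `"candidate"`) and `scale`.
#' @seealso [screen_indicators()], [economic_schema()], [social_schema()]
#' @export
indicator_catalog <- function() {
  new_schema(
    code = paste0("C", 1:25),
    name = c(
      "Construction Costs",
      "Center's self-raised Construction Costs",
      "Construction Costs Subsidized by the Government",
      "Annual Operating Costs",
      "Center's Self-raised Annual Operating Costs",
      "Annual Operating Subsidies Received from Government",
      "Profitability",
      "Number of Employees",
      "Number of Volunteers",
      "Total Personnel Count",
      "Annual Number of Services Completed",
      "Annual Number of Older People Served",
      "Community-Care Service Coverage Rate",
      "Number of Service Functions",
      "Older People Satisfaction with Service Experience",
      "Number of Older People with Improved Quality of Life",
      "Number of Rehired Laid-off Workers",
      "Overall Institutional Development",
      "Job System",
      "Security System",
      "Reward and Punishment System",
      "Feedback System",
      "Equity in Service Delivery",
      "Emergency Response Process Development",
      "Complaint Status"),
    dimension = c(rep("Economy", 7), rep("Efficiency", 6),
                  rep("Effectiveness", 4), rep("Equity", 8)),
    role = "candidate",
    scale = c(rep("monetary", 7), rep("count", 5), "ratio", "count",
              "rating", "count", "count", rep("rating", 8)))
}

#' Final input-output schema for the economic perspective
#'
#' Four inputs and five outputs assessing economic performance: self-raised
#' construction and operating costs and staffing/functions on the input
#' side; profitability, service volume and quality ratings on the output
#' side. Every DEA run under the economic perspective uses this column
#' structure.
#'
#' @return data.frame with columns `code`, `name`, `dimension`, `role`,
#'   `scale`; inputs first, then outputs.
#' @export
economic_schema <- function() {
  new_schema(
    code = c(paste0("E-Input", 1:4), paste0("E-Output", 1:5)),
    name = c(
      "Center's self-raised Annual Construction Costs",
      "Center's Self-raised Annual Operating Costs",
      "Number of Employees in CCFs",
      "Number of Service Functions",
      "Profitability",
      "Annual Number of Services Completed",
      "Older People Satisfaction with Service Experience",
      "Equity in Service Delivery",
      "Complaint Status"),
    dimension = c("Economy", "Economy", "Efficiency", "Effectiveness",
                  "Economy", "Efficiency", "Effectiveness", "Equity", "Equity"),
    role = c(rep("input", 4), rep("output", 5)),
    scale = c("monetary", "monetary", "count", "count",
              "monetary", "count", "rating", "rating", "rating"))
}

#' Final input-output schema for the social perspective
#'
#' Four inputs and eight outputs assessing social performance: government
#' construction and operating subsidies plus staffing/functions on the
#' input side; profitability, re-employment, service volume, coverage,
#' satisfaction, quality-of-life improvement and equity ratings on the
#' output side.
#'
#' @return data.frame with columns `code`, `name`, `dimension`, `role`,
#'   `scale`; inputs first, then outputs.
#' @export
social_schema <- function() {
  new_schema(
    code = c(paste0("S-input", 1:4), paste0("S-output", 1:8)),
    name = c(
      "Construction Costs Subsidized by the Government",
      "Annual Operating Subsidies Received from Government",
      "Number of Employees in CCFs",
      "Number of Service Functions",
      "Profitability",
      "Number of Rehired Laid-off Workers",
      "Annual Number of Services Completed",
      "Community Service Coverage Rate",
      "Older People Satisfaction with Service Experience",
      "Number of Older People with Improved Quality of Life",
      "Equity in Service Delivery",
      "Complaint Status"),
    dimension = c("Economy", "Economy", "Efficiency", "Effectiveness",
                  "Economy", "Efficiency", "Efficiency", "Efficiency",
                  "Effectiveness", "Effectiveness", "Equity", "Equity"),
    role = c(rep("input", 4), rep("output", 8)),
    scale = c("monetary", "monetary", "count", "count",
              "monetary", "count", "count", "ratio",
              "rating", "count", "rating", "rating"))
}

# resolve a schema argument: data.frame, built-in name, or sidecar file path
resolve_schema <- function(schema) {
  if (is.data.frame(schema)) return(validate_schema(schema))
  if (is.character(schema) && length(schema) == 1) {
    if (schema == "economic") return(economic_schema())
    if (schema == "social") return(social_schema())
    if (file.exists(schema)) return(read_schema(schema))
  }
  cb_error("carebench_bad_schema",
           "schema must be a data.frame, 'economic', 'social', or a sidecar file path")
}

#' Read / write a schema sidecar file
#'
#' The sidecar is a plain-text tab-separated file with one line per
#' indicator and columns `code`, `role`, `dimension`, `scale`, `name`
#' (lines starting with `#` are comments). It tells [read_panel()] the
#' role and 4E dimension of each panel column, so roles are never guessed
#' from CSV headers.
#'
#' @param path file path.
#' @return `read_schema()`: a validated schema data.frame (inputs and
#'   outputs in file order); `write_schema()`: `path`, invisibly.
#' @export
read_schema <- function(path) {
  if (!file.exists(path))
    cb_error("carebench_missing_file", sprintf("schema file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 4L)
  if (length(bad) > 0)
    cb_error("carebench_bad_schema",
             sprintf("schema line %d has fewer than 4 tab-separated fields", bad[1]))
  df <- data.frame(
    code = vapply(parts, `[[`, "", 1L),
    role = vapply(parts, `[[`, "", 2L),
    dimension = vapply(parts, `[[`, "", 3L),
    scale = vapply(parts, `[[`, "", 4L),
    name = vapply(parts, function(p) if (length(p) >= 5L) p[[5L]] else "", ""),
    stringsAsFactors = FALSE)
  validate_schema(df[, c("code", "name", "dimension", "role", "scale")])
}

#' @rdname read_schema
#' @param schema schema data.frame (as from [economic_schema()]).
#' @export
write_schema <- function(schema, path) {
  validate_schema(schema)
  lines <- c("# code\trole\tdimension\tscale\tname",
             sprintf("%s\t%s\t%s\t%s\t%s", schema$code, schema$role,
                     schema$dimension, schema$scale, schema$name))
  writeLines(lines, path)
  invisible(path)
}

#' Spearman rank correlation between two indicator series
#'
#' Rank correlation with average ranks for ties. A constant series has no
#' defined rank correlation; the result is then the `NA` "undefined"
#' sentinel rather than a silent zero, and [screen_indicators()] carries
#' such pairs through as not screenable.
#'
#' @param a,b numeric vectors of equal length (at least 3).
#' @return correlation in `[-1, 1]`, or `NA` when either series is constant.
#' @examples
#' spearman_rho(1:3, c(10, 20, 30))   # 1
#' spearman_rho(1:4, c(2, 1, 4, 3))   # 0.6
#' @export
spearman_rho <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b))
    cb_error("carebench_non_numeric", "spearman_rho expects numeric vectors")
  if (length(a) != length(b))
    cb_error("carebench_length_mismatch", sprintf(
      "length mismatch: %d vs %d", length(a), length(b)))
  if (length(a) < 3)
    cb_error("carebench_bad_size", "spearman_rho needs at least 3 observations")
  if (anyNA(a) || anyNA(b))
    cb_error("carebench_missing_value", "spearman_rho does not accept missing values")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(rank(a), rank(b), method = "pearson")
}

#' Screen collinear indicators by Spearman correlation
#'
#' Within each role group (or across all columns with
#' `within_roles = FALSE`), any pair with `|rho| >= threshold` drops the
#' later column in panel order, so the result is deterministic given the
#' column order. The full pairwise correlation matrix is returned for
#' audit; pairs involving a constant column are listed as not screenable.
#'
#' @param panel a [performance_panel()] whose columns are the candidates.
#' @param threshold drop threshold on `|rho|`, in `(0, 1]` (a value above 1
#'   retains everything). Default 0.8.
#' @param within_roles screen inputs and outputs separately (default) or
#'   across all columns.
#' @return object of class `screening_result`: list with `pairwise_rho`
#'   (diagonal exactly 1), `retained`, `dropped` (code, reason, rho) and
#'   `not_screenable`.
#' @export
screen_indicators <- function(panel, threshold = 0.8, within_roles = TRUE) {
  stopifnot(inherits(panel, "performance_panel"))
  M <- cbind(panel$X, panel$Y)
  codes <- panel$columns$code
  roles <- panel$columns$role
  k <- ncol(M)
  if (k < 2)
    cb_error("carebench_bad_size", "screening needs at least 2 candidate columns")
  R <- matrix(NA_real_, k, k, dimnames = list(codes, codes))
  for (i in seq_len(k))
    for (j in seq_len(k))
      if (i < j) R[i, j] <- R[j, i] <- spearman_rho(M[, i], M[, j])
  diag(R) <- 1
  keep <- rep(TRUE, k)
  dropped <- data.frame(code = character(), reason = character(),
                        rho = numeric(), stringsAsFactors = FALSE)
  not_screenable <- data.frame(code_a = character(), code_b = character(),
                               stringsAsFactors = FALSE)
  for (i in seq_len(k - 1)) {
    if (!keep[i]) next
    for (j in seq((i + 1), k)) {
      if (!keep[j]) next
      if (within_roles && roles[i] != roles[j]) next
      if (is.na(R[i, j])) {
        not_screenable <- rbind(not_screenable,
                                data.frame(code_a = codes[i], code_b = codes[j],
                                           stringsAsFactors = FALSE))
        next
      }
      if (abs(R[i, j]) >= threshold) {
        keep[j] <- FALSE
        dropped <- rbind(dropped, data.frame(
          code = codes[j],
          reason = sprintf("|rho| >= %g with %s", threshold, codes[i]),
          rho = R[i, j], stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(pairwise_rho = R, retained = codes[keep], dropped = dropped,
                 not_screenable = not_screenable, threshold = threshold,
                 within_roles = within_roles),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("Indicator screening (|rho| >= %g, %s)\n", x$threshold,
              if (x$within_roles) "within role groups" else "across all columns"))
  cat(sprintf("  retained: %s\n", paste(x$retained, collapse = ", ")))
  if (nrow(x$dropped) > 0) {
    cat("  dropped:\n")
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("    %s (%s, rho = %.3f)\n", x$dropped$code[i],
                  x$dropped$reason[i], x$dropped$rho[i]))
  } else cat("  dropped: none\n")
  if (nrow(x$not_screenable) > 0)
    cat(sprintf("  not screenable (undefined rho): %s\n",
                paste(paste(x$not_screenable$code_a, x$not_screenable$code_b,
                            sep = "~"), collapse = ", ")))
  invisible(x)
}
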