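# Projection diagnostics: slack expressed as a percentage of the observed
# value -- redundancy rates for inputs, shortfall rates for outputs -- and
# the benchmarking report for low-performing DMUs.

rate_percent <- function(observed, slack, tol = 1e-12) {
  out <- rep(NA_real_, length(observed))
  zero_slack <- slack <= tol
  out[zero_slack] <- 0
  pos <- !zero_slack & observed > 0
  out[pos] <- slack[pos] / observed[pos] * 100
  # observed 0 with positive slack stays NA: the "undefined rate" sentinel
  out
}

#' Input redundancy rate
#'
#' The share of an observed input that is pure slack, as a percentage:
#' `slack / observed * 100`, and exactly 0 when the slack is 0. A rate of
#' 100 means the entire input is redundant. When `observed` is 0 with a
#' positive slack the rate is undefined and the `NA` sentinel is returned,
#' never a silent infinity.
#'
#' @param observed observed input value(s), nonnegative.
#' @param slack optimal input slack(s), nonnegative.
#' @return percentage(s) in `[0, 100]` for frontier-consistent slacks, or
#'   `NA` where undefined.
#' @examples
#' redundancy_rate(4, 2)    # 50
#' redundancy_rate(10, 0)   # 0
#' @export
redundancy_rate <- function(observed, slack) {
  if (any(observed < 0) || any(slack < 0))
    cb_error("carebench_negative_value", "observed and slack must be nonnegative")
  rate_percent(observed, slack)
}

#' Output shortfall rate
#'
#' The output expansion needed to reach the frontier, as a percentage of
#' the observed value: `slack / observed * 100`. Unlike input redundancy
#' this is unbounded above -- an output far below its projection can show
#' a rate of several hundred percent. `observed = 0` with positive slack
#' yields the `NA` undefined sentinel.
#'
#' @inheritParams redundancy_rate
#' @return percentage(s) `>= 0`, or `NA` where undefined.
#' @examples
#' shortfall_rate(100, 965.2)  # 965.2
#' @export
shortfall_rate <- function(observed, slack) {
  if (any(observed < 0) || any(slack < 0))
    cb_error("carebench_negative_value", "observed and slack must be nonnegative")
  rate_percent(observed, slack)
}

#' Benchmarking report for low-performing DMUs
#'
#' One row per (DMU, indicator) pair for every DMU whose band is in
#' `band_filter` (default: all non-efficient bands): the observed value,
#' the optimal slack, the redundancy/shortfall rate, and the projection
#' target. Rows are ordered by DMU (panel order) then indicator (column
#' order). A per-indicator tally counts how many reported DMUs carry a
#' positive slack on that indicator -- the "k facilities show redundancy"
#' diagnostic.
#'
#' @param evaluation a `dea_evaluation` from [evaluate_panel()].
#' @param panel the [performance_panel()] the evaluation was run on.
#' @param band_filter character vector of band labels to report.
#' @param slack_tol slacks at or below this are treated as zero in the
#'   tally.
#' @return object of class `projection_summary`: list with `rows`
#'   (data.frame `dmu_id`, `code`, `role`, `observed`, `slack`,
#'   `rate_percent`, `target`) and `tally` (data.frame `code`, `role`,
#'   `n_dmus_with_positive_slack`).
#' @export
projection_report <- function(evaluation, panel,
                              band_filter = c("First level", "Second level",
                                              "Third level"),
                              slack_tol = 1e-9) {
  stopifnot(inherits(evaluation, "dea_evaluation"),
            inherits(panel, "performance_panel"))
  if (!identical(evaluation$results$dmu_id, panel$dmu_ids))
    cb_error("carebench_id_mismatch",
             "evaluation and panel refer to different DMUs (or a different order)")
  sel <- which(evaluation$results$band %in% band_filter)
  codes_in <- colnames(panel$X); codes_out <- colnames(panel$Y)
  rows <- vector("list", length(sel))
  for (ii in seq_along(sel)) {
    l <- sel[ii]
    rows[[ii]] <- data.frame(
      dmu_id = panel$dmu_ids[l],
      code = c(codes_in, codes_out),
      role = c(rep("input", length(codes_in)), rep("output", length(codes_out))),
      observed = c(panel$X[l, ], panel$Y[l, ]),
      slack = c(evaluation$slacks_in[l, ], evaluation$slacks_out[l, ]),
      rate_percent = c(redundancy_rate(panel$X[l, ], evaluation$slacks_in[l, ]),
                       shortfall_rate(panel$Y[l, ], evaluation$slacks_out[l, ])),
      target = c(evaluation$targets_x[l, ], evaluation$targets_y[l, ]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  rows <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(dmu_id = character(), code = character(), role = character(),
               observed = numeric(), slack = numeric(),
               rate_percent = numeric(), target = numeric(),
               stringsAsFactors = FALSE)
  tally <- data.frame(
    code = c(codes_in, codes_out),
    role = c(rep("input", length(codes_in)), rep("output", length(codes_out))),
    n_dmus_with_positive_slack = vapply(c(codes_in, codes_out), function(cd)
      sum(rows$code == cd & rows$slack > slack_tol), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(rows = rows, tally = tally, band_filter = band_filter),
            class = "projection_summary")
}

#' @export
print.projection_summary <- function(x, ...) {
  cat(sprintf("Projection report: %d rows over %d DMUs (bands: %s)\n",
              nrow(x$rows), length(unique(x$rows$dmu_id)),
              paste(x$band_filter, collapse = ", ")))
  hot <- x$tally[x$tally$n_dmus_with_positive_slack > 0, ]
  if (nrow(hot) > 0) {
    cat("  DMUs with positive slack per indicator:\n")
    for (i in seq_len(nrow(hot)))
      cat(sprintf("    %s (%s): %d\n", hot$code[i], hot$role[i],
                  hot$n_dmus_with_positive_slack[i]))
  }
  invisible(x)
}

#' Write a projection report (and tally) to CSV
#'
#' @param report a `projection_summary` from [projection_report()].
#' @param path CSV path for the per-(DMU, indicator) rows.
#' @param tally_path optional CSV path for the per-indicator tally.
#' @return `path`, invisibly.
#' @export
write_projection_report <- function(report, path, tally_path = NULL) {
  stopifnot(inherits(report, "projection_summary"))
  df <- report$rows
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(tally_path))
    utils::write.csv(report$tally, tally_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
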