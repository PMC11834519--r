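# Perturbation sensitivity analysis: multiply targeted indicator columns by
# (1 + magnitude), re-evaluate the whole panel, and track score changes.

#' Perturb a panel
#'
#' Multiplies the targeted column(s) by `(1 + magnitude)` for every DMU,
#' leaving everything else untouched; the input panel is never modified.
#' `target` is an indicator code, or one of the groups `"all-inputs"` /
#' `"all-outputs"`.
#'
#' @param panel a [performance_panel()].
#' @param target indicator code or group name.
#' @param magnitude signed relative perturbation with `|magnitude| < 1`
#'   (keeps all entries nonnegative).
#' @return a new, perturbed [performance_panel()].
#' @examples
#' # magnitude +0.10 turns a column (10, 20) into (11, 22)
#' @export
perturb_panel <- function(panel, target, magnitude) {
  stopifnot(inherits(panel, "performance_panel"))
  if (!is.numeric(magnitude) || length(magnitude) != 1 || !is.finite(magnitude) ||
      abs(magnitude) >= 1)
    cb_error("carebench_bad_magnitude",
             "magnitude must be a finite scalar with |magnitude| < 1")
  X <- panel$X; Y <- panel$Y
  if (identical(target, "all-inputs")) {
    X <- X * (1 + magnitude)
  } else if (identical(target, "all-outputs")) {
    Y <- Y * (1 + magnitude)
  } else if (target %in% colnames(X)) {
    X[, target] <- X[, target] * (1 + magnitude)
  } else if (target %in% colnames(Y)) {
    Y[, target] <- Y[, target] * (1 + magnitude)
  } else {
    cb_error("carebench_unknown_target", sprintf(
      "unknown perturbation target '%s'", target))
  }
  performance_panel(panel$perspective, panel$dmu_ids, X, Y, panel$columns)
}

#' Perturbation sensitivity grid
#'
#' Re-evaluates the panel for every (target, magnitude) cell, where targets
#' are each indicator column (`mode = "per-indicator"`) or a single joint
#' group (`"all-inputs"`, `"all-outputs"`). Magnitude 0 is the unperturbed
#' baseline; if absent from `magnitudes` it is evaluated anyway and
#' reported as the baseline. Cells are independent full re-evaluations, so
#' the grid is deterministic and order-free. Solver failures in a cell are
#' flagged (`NA` score) without aborting the grid.
#'
#' @param panel a [performance_panel()].
#' @param config a [dea_config()] used for every cell.
#' @param magnitudes numeric vector of signed relative perturbations; the
#'   default grid is plus/minus 1%, 2%, 5% and 10%.
#' @param mode `"per-indicator"` (one-at-a-time, default), `"all-inputs"`
#'   or `"all-outputs"`.
#' @return object of class `sensitivity_grid`: list with `scores` (long
#'   data.frame `dmu_id`, `target`, `magnitude`, `score`), `baseline`
#'   (named score vector at magnitude 0), `max_abs_change` (per-DMU),
#'   `impact` (per-target maximum absolute score change, sorted), plus the
#'   grid metadata.
#' @export
sensitivity_grid <- function(panel, config = dea_config(),
                             magnitudes = c(-0.10, -0.05, -0.02, -0.01,
                                            0.01, 0.02, 0.05, 0.10),
                             mode = c("per-indicator", "all-inputs",
                                      "all-outputs")) {
  stopifnot(inherits(panel, "performance_panel"))
  mode <- match.arg(mode)
  magnitudes <- sort(unique(c(0, magnitudes)))
  targets <- switch(mode,
                    "per-indicator" = c(colnames(panel$X), colnames(panel$Y)),
                    "all-inputs" = "all-inputs",
                    "all-outputs" = "all-outputs")
  base_eval <- evaluate_panel(panel, config)
  baseline <- stats::setNames(base_eval$results$score, panel$dmu_ids)
  cells <- list()
  for (tg in targets) {
    for (mg in magnitudes) {
      if (mg == 0) {
        sc <- baseline
      } else {
        sc <- tryCatch({
          ev <- evaluate_panel(perturb_panel(panel, tg, mg), config)
          stats::setNames(ev$results$score, panel$dmu_ids)
        }, error = function(e) stats::setNames(rep(NA_real_, length(baseline)),
                                               panel$dmu_ids))
      }
      cells[[length(cells) + 1L]] <- data.frame(
        dmu_id = panel$dmu_ids, target = tg, magnitude = mg, score = sc,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  scores <- do.call(rbind, cells)
  dev <- abs(scores$score - baseline[scores$dmu_id])
  max_abs_change <- vapply(panel$dmu_ids, function(id)
    max(dev[scores$dmu_id == id], na.rm = TRUE), 0)
  impact <- vapply(targets, function(tg)
    max(dev[scores$target == tg], na.rm = TRUE), 0)
  impact <- sort(impact, decreasing = TRUE)
  structure(list(scores = scores, baseline = baseline,
                 max_abs_change = max_abs_change,
                 impact = data.frame(target = names(impact),
                                     max_abs_score_change = unname(impact),
                                     stringsAsFactors = FALSE),
                 magnitudes = magnitudes, mode = mode),
            class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("Sensitivity grid (%s): magnitudes %s\n", x$mode,
              paste(format(x$magnitudes), collapse = ", ")))
  cat(sprintf("  max |score change| over all DMUs: %.6g\n",
              max(x$max_abs_change)))
  cat("  most influential targets:\n")
  top <- utils::head(x$impact, 3)
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %s: %.6g\n", top$target[i], top$max_abs_score_change[i]))
  invisible(x)
}

#' Write a sensitivity grid to CSV (long format)
#'
#' @param grid a `sensitivity_grid`.
#' @param path output CSV path (`dmu_id`, `target`, `magnitude`, `score`).
#' @return `path`, invisibly.
#' @export
write_sensitivity_grid <- function(grid, path) {
  stopifnot(inherits(grid, "sensitivity_grid"))
  df <- grid$scores
  df$magnitude <- fmt_num(df$magnitude)
  df$score <- fmt_num(df$score)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
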