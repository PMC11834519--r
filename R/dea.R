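# delta-SBM data envelopment analysis under variable returns to scale.
#
# For DMU l the model maximises the weighted slack sum
#     max  sum_j w-_j s-_j + sum_k w+_k s+_k
# over the envelopment technology
#     sum_i lambda_i x_ij <= x_lj - s-_j      (inputs)
#     sum_i lambda_i y_ik >= y_lk + s+_k      (outputs)
#     sum_i lambda_i = 1 (VRS), lambda >= 0, s >= 0,
# then forms delta-perturbed targets
#     x*_lj = x_lj - s-*_j + delta-_j,   y*_lk = y_lk + s+*_k - delta+_k
# with scalar offsets delta-_j = delta * min(X), delta+_k = delta * min(Y),
# and scores the DMU by the ratio-of-ratios
#     tau_l = (sum_k w+ y_lk / sum_j w- x_lj) /
#             (sum_k w+ y*_lk / sum_j w- x*_lj).
# The small data-derived offsets sharpen discrimination and keep the score
# well defined when observed entries are zero.

#' DEA model configuration
#'
#' Holds every tunable of the delta-SBM evaluation. The defaults are the
#' model's reference parameterisation: `delta = 0.001`, all indicator
#' weights 1, variable returns to scale.
#'
#' @param delta nonnegative scalar controlling the data-derived target
#'   offsets (`delta- = delta * min(X)`, `delta+ = delta * min(Y)`).
#' @param input_weights,output_weights positive slack weights `w-`, `w+`;
#'   scalar values are recycled to the panel's column counts.
#' @param returns_to_scale `"vrs"` (adds the convexity constraint
#'   `sum(lambda) = 1`) or `"crs"`.
#' @param efficiency_tolerance base tolerance for score and slack
#'   comparisons when classifying a DMU as efficient; the classifier adds
#'   the exact score displacement caused by the delta offsets on top.
#' @param tie_break `"lexicographic"` (default): after the optimal slack sum
#'   is found, re-solve fixing the objective and maximise slacks column by
#'   column, giving a canonical slack vector when the LP has alternative
#'   optima; `"solver"`: accept the solver's vertex (faster, documented as
#'   potentially non-unique across formulations).
#' @param min_mode `"literal"` (default): the offsets use the literal global
#'   minimum of X / of Y, which may be zero; `"positive"`: use the smallest
#'   strictly positive entry.
#' @return object of class `dea_config`.
#' @export
dea_config <- function(delta = 0.001, input_weights = 1, output_weights = 1,
                       returns_to_scale = c("vrs", "crs"),
                       efficiency_tolerance = 1e-6,
                       tie_break = c("lexicographic", "solver"),
                       min_mode = c("literal", "positive")) {
  returns_to_scale <- match.arg(returns_to_scale)
  tie_break <- match.arg(tie_break)
  min_mode <- match.arg(min_mode)
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0)
    cb_error("carebench_bad_config", "delta must be a nonnegative scalar")
  if (any(input_weights <= 0) || any(output_weights <= 0))
    cb_error("carebench_bad_config", "all weights must be strictly positive")
  if (efficiency_tolerance <= 0)
    cb_error("carebench_bad_config", "efficiency_tolerance must be positive")
  structure(list(delta = delta, input_weights = input_weights,
                 output_weights = output_weights,
                 returns_to_scale = returns_to_scale,
                 efficiency_tolerance = efficiency_tolerance,
                 tie_break = tie_break, min_mode = min_mode),
            class = "dea_config")
}

panel_weights <- function(panel, config) {
  m <- ncol(panel$X); p <- ncol(panel$Y)
  w_in <- rep_len(config$input_weights, m)
  w_out <- rep_len(config$output_weights, p)
  list(w_in = w_in, w_out = w_out)
}

#' Data-derived delta offsets
#'
#' Scalar offsets applied to the projection targets: `delta_in` is
#' `delta` times the global minimum input entry, `delta_out` is `delta`
#' times the global minimum output entry (common to all inputs and all
#' outputs respectively). In `"literal"` mode a zero minimum gives a zero
#' offset; `"positive"` mode uses the smallest strictly positive entry.
#'
#' @param panel a [performance_panel()].
#' @param config a [dea_config()].
#' @return list with `delta_in` and `delta_out`.
#' @examples
#' # delta = 0.001, min input 5, min output 2 -> offsets 0.005 and 0.002
#' @export
delta_offsets <- function(panel, config = dea_config()) {
  stopifnot(inherits(panel, "performance_panel"))
  minval <- function(M) {
    if (config$min_mode == "positive") {
      pos <- M[M > 0]
      if (length(pos) == 0) return(0)
      min(pos)
    } else min(M)
  }
  list(delta_in = config$delta * minval(panel$X),
       delta_out = config$delta * minval(panel$Y))
}

# Build the envelopment constraint system for one DMU. Isolated so that an
# alternative (e.g. delta-perturbed-constraint) variant can be swapped in.
# Variable order: s- (m), s+ (p), lambda (n).
sbm_formulation <- function(X, Y, l, rts) {
  n <- nrow(X); m <- ncol(X); p <- ncol(Y)
  A1 <- cbind(diag(m), matrix(0, m, p), t(X))            # lambda'X + s- <= x_l
  A2 <- cbind(matrix(0, p, m), -diag(p), t(Y))           # lambda'Y - s+ >= y_l
  A <- rbind(A1, A2)
  b <- c(X[l, ], Y[l, ])
  dir <- c(rep("<=", m), rep(">=", p))
  if (rts == "vrs") {
    A <- rbind(A, c(rep(0, m + p), rep(1, n)))
    b <- c(b, 1)
    dir <- c(dir, "=")
  }
  list(A = A, b = b, dir = dir, n = n, m = m, p = p)
}

#' Solve the slack-maximisation LP for one DMU
#'
#' Maximises the weighted sum of input and output slacks for DMU
#' `dmu_index` over the (VRS or CRS) envelopment technology. With
#' `tie_break = "lexicographic"` the solver then fixes the optimal
#' objective and maximises each slack in column order (inputs first),
#' yielding a canonical solution when alternative optima exist.
#'
#' The LP is solved on data rescaled by the panel's largest entry, so the
#' procedure is invariant under a common rescaling of X and Y; slacks are
#' returned on the original scale.
#'
#' @param panel a [performance_panel()].
#' @param dmu_index integer index of the DMU under evaluation (1-based).
#' @param config a [dea_config()].
#' @return object of class `slack_solution`: list with `s_in` (m input
#'   slacks), `s_out` (p output slacks), `lambda` (n intensity weights),
#'   `objective` (weighted slack sum) and `status`.
#' @export
solve_delta_sbm <- function(panel, dmu_index, config = dea_config()) {
  stopifnot(inherits(panel, "performance_panel"))
  n <- nrow(panel$X)
  if (dmu_index < 1 || dmu_index > n)
    cb_error("carebench_bad_index", sprintf(
      "dmu_index must be in 1..%d (got %s)", n, format(dmu_index)))
  w <- panel_weights(panel, config)
  m <- ncol(panel$X); p <- ncol(panel$Y)

  sc <- max(panel$X, panel$Y)
  if (sc <= 0) sc <- 1
  X <- panel$X / sc
  Y <- panel$Y / sc

  f <- sbm_formulation(X, Y, dmu_index, config$returns_to_scale)
  obj <- c(w$w_in, w$w_out, rep(0, n))
  sol <- lp_solve(obj, f$A, f$b, f$dir, maximize = TRUE)
  if (sol$status != "optimal")
    cb_error("carebench_solver_failure", sprintf(
      "slack LP for DMU '%s' returned status '%s'",
      panel$dmu_ids[dmu_index], sol$status))
  z <- sol$value
  x <- sol$x

  if (config$tie_break == "lexicographic" && z > 0) {
    # keep the objective at its optimum, then maximise slacks one column at
    # a time in panel order; each solved value is fixed (as an equality)
    # before moving on, giving a canonical vertex
    A <- rbind(f$A, obj)
    b <- c(f$b, z)
    dir <- c(f$dir, "=")
    for (j in seq_len(m + p)) {
      ej <- rep(0, m + p + n); ej[j] <- 1
      sj <- lp_solve(ej, A, b, dir, maximize = TRUE)
      if (sj$status != "optimal") break
      x <- sj$x
      A <- rbind(A, ej)
      b <- c(b, sj$value)
      dir <- c(dir, "=")
    }
  }

  s_in <- pmax(x[seq_len(m)], 0) * sc
  s_out <- pmax(x[m + seq_len(p)], 0) * sc
  lambda <- pmax(x[m + p + seq_len(n)], 0)
  names(s_in) <- colnames(panel$X)
  names(s_out) <- colnames(panel$Y)
  names(lambda) <- panel$dmu_ids
  structure(list(s_in = s_in, s_out = s_out, lambda = lambda,
                 objective = sum(w$w_in * s_in) + sum(w$w_out * s_out),
                 status = "optimal"),
            class = "slack_solution")
}

#' Projection targets from a slack solution
#'
#' Applies the target equations exactly, with no clamping:
#' `x* = x - s_in + delta_in` and `y* = y + s_out - delta_out`.
#'
#' @param x,y observed input and output vectors of one DMU.
#' @param slacks a `slack_solution` (or any list with `s_in`, `s_out`).
#' @param offsets offsets list from [delta_offsets()].
#' @return list with `x_star` and `y_star`.
#' @export
compute_targets <- function(x, y, slacks, offsets = list(delta_in = 0, delta_out = 0)) {
  if (length(x) != length(slacks$s_in) || length(y) != length(slacks$s_out))
    cb_error("carebench_bad_size", "dimension mismatch between observations and slacks")
  list(x_star = x - slacks$s_in + offsets$delta_in,
       y_star = y + slacks$s_out - offsets$delta_out)
}

#' delta-SBM efficiency score
#'
#' The ratio of the DMU's aggregate output/input ratio at observed values
#' to the same ratio at its projection targets:
#' `tau = (sum(w+ y) / sum(w- x)) / (sum(w+ y*) / sum(w- x*))`.
#'
#' @param x,y observed input and output vectors.
#' @param targets list with `x_star`, `y_star` (see [compute_targets()]).
#' @param config a [dea_config()] supplying the weights.
#' @return the score `tau` (in `(0, 1]` when `delta = 0`; may slightly
#'   exceed 1 for zero-slack DMUs when `delta > 0`, because the targets are
#'   delta-worsened).
#' @export
compute_score <- function(x, y, targets, config = dea_config()) {
  w_in <- rep_len(config$input_weights, length(x))
  w_out <- rep_len(config$output_weights, length(y))
  den_obs <- sum(w_in * x)
  den_tar <- sum(w_in * targets$x_star)
  num_tar <- sum(w_out * targets$y_star)
  if (den_obs <= 0 || den_tar <= 0 || num_tar <= 0)
    cb_error("carebench_degenerate_score",
             "score undefined: an aggregate input or target aggregate is not positive")
  (sum(w_out * y) / den_obs) / (num_tar / den_tar)
}

BAND_LEVELS <- c("DEA Efficient", "First level", "Second level", "Third level")

#' Classify a score into its performance band
#'
#' The four-band partition used to summarise results: scores within
#' `tolerance` of 1 are "DEA Efficient"; `[0.8, 1)` is "First level",
#' `[0.4, 0.8)` "Second level" and `[0, 0.4)` "Third level" (the three
#' DEA-invalid grades).
#'
#' @param score nonnegative score (vectorised).
#' @param tolerance half-width of the efficient band around 1.
#' @return character vector of band labels.
#' @examples
#' classify_score(c(1, 0.8837, 0.6742, 0.3324))
#' @export
classify_score <- function(score, tolerance = 1e-6) {
  if (any(score < 0))
    cb_error("carebench_bad_score", "scores must be nonnegative")
  ifelse(abs(score - 1) <= tolerance, BAND_LEVELS[1],
         ifelse(score >= 0.8, BAND_LEVELS[2],
                ifelse(score >= 0.4, BAND_LEVELS[3], BAND_LEVELS[4])))
}

#' Evaluate every DMU of a panel
#'
#' Runs the delta-SBM model for each DMU in panel order and assembles
#' scores, slack vectors, intensity weights, projection targets and band
#' labels. Classification as "DEA Efficient" uses a per-DMU tolerance equal
#' to `config$efficiency_tolerance` plus the exact score displacement the
#' delta offsets cause for a zero-slack DMU, so raw scores slightly above 1
#' (a known consequence of delta-worsened targets) are still classified
#' efficient; the raw score is always reported unmodified.
#'
#' Per-DMU solver failures are recorded in the `status` column (with `NA`
#' score) without aborting the batch.
#'
#' @param panel a [performance_panel()].
#' @param config a [dea_config()].
#' @return object of class `dea_evaluation`: list with `results` (data.frame
#'   `dmu_id`, `score`, `band`, `objective`, `status`), `slacks_in`,
#'   `slacks_out`, `lambda`, `targets_x`, `targets_y` (matrices), `offsets`,
#'   `config`, `perspective`.
#' @seealso [band_summary()], [projection_report()]
#' @export
evaluate_panel <- function(panel, config = dea_config()) {
  stopifnot(inherits(panel, "performance_panel"))
  n <- nrow(panel$X); m <- ncol(panel$X); p <- ncol(panel$Y)
  off <- delta_offsets(panel, config)
  w <- panel_weights(panel, config)
  scores <- objectives <- rep(NA_real_, n)
  status <- rep("optimal", n)
  slacks_in <- matrix(NA_real_, n, m, dimnames = list(panel$dmu_ids, colnames(panel$X)))
  slacks_out <- matrix(NA_real_, n, p, dimnames = list(panel$dmu_ids, colnames(panel$Y)))
  lambda <- matrix(NA_real_, n, n, dimnames = list(panel$dmu_ids, panel$dmu_ids))
  targets_x <- slacks_in; targets_y <- slacks_out
  tol <- rep(config$efficiency_tolerance, n)
  for (l in seq_len(n)) {
    sol <- tryCatch(solve_delta_sbm(panel, l, config), error = function(e) e)
    if (inherits(sol, "error")) {
      status[l] <- conditionMessage(sol)
      next
    }
    tg <- compute_targets(panel$X[l, ], panel$Y[l, ], sol, off)
    scores[l] <- compute_score(panel$X[l, ], panel$Y[l, ], tg, config)
    objectives[l] <- sol$objective
    slacks_in[l, ] <- sol$s_in
    slacks_out[l, ] <- sol$s_out
    lambda[l, ] <- sol$lambda
    targets_x[l, ] <- tg$x_star
    targets_y[l, ] <- tg$y_star
    # exact displacement of the score for this DMU if its slacks were zero:
    # tau0 = (y/x ratio at observations) / (ratio at delta-worsened copies)
    tau0 <- tryCatch(compute_score(panel$X[l, ], panel$Y[l, ],
                                   list(x_star = panel$X[l, ] + off$delta_in,
                                        y_star = panel$Y[l, ] - off$delta_out),
                                   config),
                     error = function(e) 1)
    tol[l] <- config$efficiency_tolerance + abs(tau0 - 1)
  }
  band <- rep(NA_character_, n)
  ok <- !is.na(scores)
  # a DMU is efficient only if its maximal slack sum is (numerically) zero;
  # the score band then follows the four-level partition
  zero_slack <- ok & objectives <= config$efficiency_tolerance *
    max(1, max(panel$X, panel$Y))
  band[ok] <- classify_score(pmin(scores[ok], 1 - 1e-12))
  band[ok] <- ifelse(zero_slack[ok] |
                       mapply(function(s, t) abs(s - 1) <= t, scores[ok], tol[ok]),
                     BAND_LEVELS[1], band[ok])
  structure(list(results = data.frame(dmu_id = panel$dmu_ids, score = scores,
                                      band = band, objective = objectives,
                                      status = status, stringsAsFactors = FALSE),
                 slacks_in = slacks_in, slacks_out = slacks_out, lambda = lambda,
                 targets_x = targets_x, targets_y = targets_y,
                 offsets = off, config = config,
                 perspective = panel$perspective),
            class = "dea_evaluation")
}

#' Band-count summary of an evaluation
#'
#' Tabulates how many DMUs fall in each of the four performance bands, in
#' the standard summary layout (score ranges as rows).
#'
#' @param evaluation a `dea_evaluation` from [evaluate_panel()].
#' @return data.frame with columns `score_range`, `n_dmus`, `evaluation`.
#' @export
band_summary <- function(evaluation) {
  stopifnot(inherits(evaluation, "dea_evaluation"))
  counts <- vapply(BAND_LEVELS, function(b)
    sum(evaluation$results$band == b, na.rm = TRUE), 0L)
  data.frame(score_range = c("Score = 1", "0.8 <= Score < 1",
                             "0.4 <= Score < 0.8", "0 <= Score < 0.4"),
             n_dmus = as.integer(counts),
             evaluation = c("DEA Efficient", "DEA Invalid / First level",
                            "DEA Invalid / Second level",
                            "DEA Invalid / Third level"),
             stringsAsFactors = FALSE)
}

#' @export
print.dea_evaluation <- function(x, ...) {
  cat(sprintf("delta-SBM evaluation (%s perspective, %s, delta = %g)\n",
              x$perspective, toupper(x$config$returns_to_scale), x$config$delta))
  print(band_summary(x), row.names = FALSE)
  invisible(x)
}

#' Write evaluation results to CSV
#'
#' One row per DMU: `dmu_id`, `score`, `band`, one column per input slack
#' (`slack_<code>`), per output slack, and per target (`target_<code>`).
#' A band-count summary mirroring [band_summary()] is written alongside
#' when `summary_path` is given. Numbers use the shortest round-trip
#' representation so repeated runs yield byte-identical files.
#'
#' @param evaluation a `dea_evaluation`.
#' @param path output CSV path.
#' @param summary_path optional path for the band-count CSV.
#' @return `path`, invisibly.
#' @export
write_dea_results <- function(evaluation, path, summary_path = NULL) {
  stopifnot(inherits(evaluation, "dea_evaluation"))
  df <- evaluation$results[, c("dmu_id", "score", "band")]
  add <- function(M, prefix) {
    for (j in seq_len(ncol(M))) df[[paste0(prefix, colnames(M)[j])]] <<- M[, j]
  }
  add(evaluation$slacks_in, "slack_")
  add(evaluation$slacks_out, "slack_")
  add(evaluation$targets_x, "target_")
  add(evaluation$targets_y, "target_")
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path))
    utils::write.csv(band_summary(evaluation), summary_path,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
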