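# Spatial stage: ordinary least squares of facility performance on regional
# GDP per capita, and geographically weighted regression (GWR) with a
# Gaussian distance kernel to expose spatial heterogeneity in the slope.

#' Ordinary least squares with classical inference
#'
#' Fits `y = beta0 + beta1 x + e` by least squares and reports classical
#' standard errors, t statistics and two-sided p-values.
#'
#' @param x predictor (e.g. street-level GDP per capita), not constant.
#' @param y response (e.g. DEA performance score), same length, `n >= 3`.
#' @return object of class `ols_fit`: list with `beta0`, `beta1`, `se`
#'   (length 2), `t`, `p`, `residuals`, `sigma`, `r_squared`, `n`.
#' @examples
#' f <- fit_ols(c(0, 1, 2), c(0, 0, 3))  # beta0 = -0.5, beta1 = 1.5
#' @export
fit_ols <- function(x, y) {
  if (length(x) != length(y))
    cb_error("carebench_length_mismatch", "x and y must have equal length")
  if (length(x) < 3)
    cb_error("carebench_bad_size", "OLS needs at least 3 observations")
  if (stats::sd(x) == 0)
    cb_error("carebench_rank_deficient", "x is constant: slope is not identified")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exactly collinear response; perfect fits are a
  # legal (noise-free) input here
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  structure(list(beta0 = unname(co[1, 1]), beta1 = unname(co[2, 1]),
                 se = unname(co[, 2]), t = unname(co[, 3]), p = unname(co[, 4]),
                 residuals = unname(stats::residuals(fit)),
                 sigma = sm$sigma, r_squared = sm$r.squared, n = length(x)),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): beta0 = %.4f, beta1 = %.4f (se %.4f, p = %.4g)\n",
              x$n, x$beta0, x$beta1, x$se[2], x$p[2]))
  invisible(x)
}

#' Gaussian GWR weights for one location
#'
#' `w_ij = exp(-0.5 (d_ij / bandwidth)^2)` with Euclidean distances in the
#' (projected, planar) coordinate units; the own-location weight is 1 and
#' an infinite bandwidth gives uniform weights 1.
#'
#' @param coords numeric `n x 2` matrix of planar coordinates.
#' @param i index of the regression location.
#' @param bandwidth positive kernel bandwidth (same unit as the
#'   coordinates); may be `Inf`.
#' @param kernel currently only `"gaussian"`.
#' @return numeric vector of `n` nonnegative weights.
#' @export
gwr_weights <- function(coords, i, bandwidth, kernel = "gaussian") {
  coords <- as.matrix(coords)
  if (!identical(kernel, "gaussian"))
    cb_error("carebench_bad_config", sprintf("unknown kernel '%s'", kernel))
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 || bandwidth <= 0)
    cb_error("carebench_bad_config", "bandwidth must be a positive scalar")
  d <- sqrt((coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2)
  if (is.infinite(bandwidth)) return(rep(1, nrow(coords)))
  exp(-0.5 * (d / bandwidth)^2)
}

gwr_fit_at <- function(Z, y, w) {
  # weighted least squares at one location; NULL signals rank deficiency
  sw <- sqrt(w)
  Zw <- Z * sw
  qr_ <- qr(Zw)
  if (qr_$rank < ncol(Z)) return(NULL)
  qr.coef(qr_, y * sw)
}

gwr_cv_score <- function(coords, Z, y, bandwidth, kernel) {
  n <- nrow(Z)
  err <- 0
  for (i in seq_len(n)) {
    w <- gwr_weights(coords, i, bandwidth, kernel)
    w[i] <- 0                               # leave-one-out
    beta <- gwr_fit_at(Z, y, w)
    if (is.null(beta) || anyNA(beta)) return(Inf)
    err <- err + (y[i] - sum(Z[i, ] * beta))^2
  }
  err
}

golden_section <- function(f, lo, hi, tol = 1e-4, max_iter = 100L) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - phi * (b - a); d_ <- a + phi * (b - a)
  fc <- f(c_); fd <- f(d_)
  for (k in seq_len(max_iter)) {
    if (abs(b - a) < tol * (abs(a) + abs(b))) break
    if (fc < fd) { b <- d_; d_ <- c_; fd <- fc; c_ <- b - phi * (b - a); fc <- f(c_) }
    else { a <- c_; c_ <- d_; fc <- fd; d_ <- a + phi * (b - a); fd <- f(d_) }
  }
  if (fc < fd) c_ else d_
}

#' Geographically weighted regression
#'
#' Fits a locally weighted linear regression at every sample location
#' using a Gaussian distance kernel, returning per-location coefficients,
#' the min-max interval of each coefficient across locations (the
#' "coefficient interval" used to judge spatial heterogeneity), and the
#' leave-one-out cross-validation score. With `bandwidth = "cv"` the
#' bandwidth minimising the LOO-CV score is selected by golden-section
#' search between the smallest non-zero inter-point distance and twice the
#' coordinate range. As the bandwidth grows the local fits converge to the
#' global OLS fit.
#'
#' Locations where the weighted design matrix is rank deficient are flagged
#' (coefficients `NA`) and the fit continues.
#'
#' @param points data.frame with coordinate columns (default `u`, `v`),
#'   covariate column(s) and a response column.
#' @param response name of the response column.
#' @param covariates character vector of covariate column names (default
#'   `"gdp_per_capita"`).
#' @param coords names of the two coordinate columns.
#' @param bandwidth positive number, `Inf`, or `"cv"` (default).
#' @param kernel currently `"gaussian"`.
#' @return object of class `gwr_fit`: list with `kernel`, `bandwidth`,
#'   `local_beta` (`n x (k+1)` matrix, intercept first), `fitted`,
#'   `residuals`, `cv_score`, `coef_interval` (min/max per coefficient),
#'   `flagged` (indices of rank-deficient locations).
#' @export
fit_gwr <- function(points, response = "score", covariates = "gdp_per_capita",
                    coords = c("u", "v"), bandwidth = "cv",
                    kernel = "gaussian") {
  stopifnot(is.data.frame(points))
  need <- c(coords, covariates, response)
  missing <- setdiff(need, names(points))
  if (length(missing) > 0)
    cb_error("carebench_missing_column", sprintf(
      "points data is missing column(s): %s", paste(missing, collapse = ", ")))
  xy <- as.matrix(points[, coords])
  if (!all(is.finite(xy)))
    cb_error("carebench_bad_coords", "coordinates must be finite")
  if (nrow(unique(xy)) < 3)
    cb_error("carebench_bad_size", "GWR needs at least 3 distinct locations")
  y <- points[[response]]
  Z <- cbind(`(Intercept)` = 1, as.matrix(points[, covariates, drop = FALSE]))
  n <- nrow(Z)

  if (identical(bandwidth, "cv")) {
    dmat <- as.matrix(stats::dist(xy))
    lo <- min(dmat[dmat > 0]) / 2
    hi <- 2 * max(dmat)
    # golden-section on log-bandwidth: the CV score varies over magnitudes
    bandwidth <- exp(golden_section(
      function(lb) gwr_cv_score(xy, Z, y, exp(lb), kernel), log(lo), log(hi)))
  }
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    cb_error("carebench_bad_config", "bandwidth must be positive (or 'cv')")

  local_beta <- matrix(NA_real_, n, ncol(Z),
                       dimnames = list(NULL, colnames(Z)))
  fitted <- rep(NA_real_, n)
  flagged <- integer(0)
  for (i in seq_len(n)) {
    w <- gwr_weights(xy, i, bandwidth, kernel)
    beta <- gwr_fit_at(Z, y, w)
    if (is.null(beta) || anyNA(beta)) {
      flagged <- c(flagged, i)
      next
    }
    local_beta[i, ] <- beta
    fitted[i] <- sum(Z[i, ] * beta)
  }
  ok <- stats::complete.cases(local_beta)
  coef_interval <- data.frame(
    coefficient = colnames(Z),
    min = if (any(ok)) apply(local_beta[ok, , drop = FALSE], 2, min)
          else rep(NA_real_, ncol(Z)),
    max = if (any(ok)) apply(local_beta[ok, , drop = FALSE], 2, max)
          else rep(NA_real_, ncol(Z)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(kernel = kernel, bandwidth = bandwidth,
                 local_beta = local_beta, fitted = fitted,
                 residuals = y - fitted,
                 cv_score = gwr_cv_score(xy, Z, y, bandwidth, kernel),
                 coef_interval = coef_interval, flagged = flagged),
            class = "gwr_fit")
}

#' @export
print.gwr_fit <- function(x, ...) {
  cat(sprintf("GWR fit (%s kernel, bandwidth %.6g, CV score %.6g)\n",
              x$kernel, x$bandwidth, x$cv_score))
  cat("  coefficient intervals across locations:\n")
  for (i in seq_len(nrow(x$coef_interval)))
    cat(sprintf("    %s: [%.6f, %.6f]\n", x$coef_interval$coefficient[i],
                x$coef_interval$min[i], x$coef_interval$max[i]))
  if (length(x$flagged) > 0)
    cat(sprintf("  flagged rank-deficient locations: %s\n",
                paste(x$flagged, collapse = ", ")))
  invisible(x)
}

#' Write GWR results to CSV
#'
#' Per-location coefficients followed by two summary rows holding the
#' minimum and maximum of each coefficient across locations.
#'
#' @param fit a `gwr_fit`.
#' @param path output CSV path.
#' @param dmu_ids optional identifiers for the rows.
#' @return `path`, invisibly.
#' @export
write_gwr_results <- function(fit, path, dmu_ids = NULL) {
  stopifnot(inherits(fit, "gwr_fit"))
  n <- nrow(fit$local_beta)
  ids <- if (is.null(dmu_ids)) sprintf("loc%03d", seq_len(n)) else dmu_ids
  df <- data.frame(dmu_id = c(ids, "min", "max"),
                   rbind(fit$local_beta,
                         t(fit$coef_interval$min), t(fit$coef_interval$max)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
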