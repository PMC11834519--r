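# Synthetic CCF-like panels and spatial samples with known ground truth.
#
# Frontier construction: planted efficient DMUs ("anchors") sit on a concave
# increasing input-output surface -- every continuous column is proportional
# to a common size factor r, and continuous outputs follow g(r) = sqrt(r),
# strictly concave. Each inefficient DMU is a copy of a random anchor with
# all inputs inflated by 1/u and all outputs deflated by u for a drawn
# efficiency factor u in (0, 1): it is strictly dominated by its parent, and
# Jensen's inequality on the concave output column guarantees every anchor
# keeps zero optimal slack, so at zero noise the planted set is exactly the
# DEA-efficient set.

#' Specification of a synthetic study
#'
#' The defaults emulate the reference cohort: 75 facilities, the economic
#' perspective's 4-input/5-output column structure, ratings on a 1-5
#' ordinal scale, a small planted frontier, and a GDP covariate with a
#' negative association with performance (planted slope -0.321 per
#' standardised GDP unit).
#'
#' @param n number of DMUs (default 75).
#' @param perspective `"economic"` (4 inputs, 5 outputs) or `"social"`
#'   (4 inputs, 8 outputs).
#' @param n_efficient number of planted frontier DMUs, in `1..n`.
#' @param inefficiency Beta shape parameters for the efficiency factor
#'   `u` of non-frontier DMUs; the default `c(2, 2)` concentrates scores
#'   across all four performance bands with most mass in the lower ones.
#' @param noise nonnegative relative noise applied multiplicatively to
#'   non-frontier entries (default 0.05; 0 gives the exact planted
#'   geometry).
#' @param rating_levels ordinal scale for rating indicators (default 5).
#' @param spatial_beta1 planted slope of performance on standardised GDP
#'   per capita (default -0.321).
#' @param spatial_noise residual standard deviation of the spatial
#'   response (default 0.5).
#' @param seed integer RNG seed; identical spec + seed gives byte-identical
#'   output.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 75, perspective = c("economic", "social"),
                           n_efficient = 5, inefficiency = c(2, 2),
                           noise = 0.05, rating_levels = 5,
                           spatial_beta1 = -0.321, spatial_noise = 0.5,
                           seed = 1L) {
  perspective <- match.arg(perspective)
  if (n < 2 || n_efficient < 1 || n_efficient > n)
    cb_error("carebench_bad_spec", "need n >= 2 and 1 <= n_efficient <= n")
  if (noise < 0 || spatial_noise < 0)
    cb_error("carebench_bad_spec", "noise levels must be nonnegative")
  if (length(inefficiency) != 2 || any(inefficiency <= 0))
    cb_error("carebench_bad_spec", "inefficiency must be two positive Beta shapes")
  if (rating_levels < 2)
    cb_error("carebench_bad_spec", "rating_levels must be at least 2")
  structure(list(n = as.integer(n), perspective = perspective,
                 n_efficient = as.integer(n_efficient),
                 inefficiency = inefficiency, noise = noise,
                 rating_levels = as.integer(rating_levels),
                 spatial_beta1 = spatial_beta1, spatial_noise = spatial_noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# per-column base magnitudes, chosen to look like facility survey data:
# monetary in units of 10k CNY, counts at facility scale, ratings on the
# ordinal scale, ratios in (0, 1)
column_base <- function(schema, rating_levels) {
  vapply(seq_len(nrow(schema)), function(j) {
    switch(schema$scale[j],
           monetary = c(80, 50, 30, 25)[1 + (j %% 4)],
           count = if (schema$role[j] == "input") 15 else 20000,
           ratio = 0.6,
           rating = rating_levels - 1)
  }, 1)
}

round_ordinal <- function(v, levels) pmin(levels, pmax(1, round(v)))

#' Generate a synthetic DMU panel with planted frontier membership
#'
#' Builds `n_efficient` mutually non-dominated frontier DMUs on a concave
#' increasing surface and fills the panel with inefficient DMUs, each a
#' strictly dominated `u`-scaled copy of a random frontier DMU (inputs
#' times `1/u`, outputs times `u`). With `noise = 0`, evaluating the panel
#' classifies exactly the planted DMUs as DEA Efficient. Rating columns are
#' rounded to the ordinal scale; count columns to integers; monetary and
#' ratio columns stay continuous (which is what preserves the planted
#' frontier geometry under rounding). Rows are shuffled so frontier
#' membership is not positional.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `panel` (a [performance_panel()]) and `truth`
#'   (data.frame `dmu_id`, `efficient`, `parent`, `u`).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  schema <- if (spec$perspective == "economic") economic_schema() else social_schema()
  m <- sum(schema$role == "input")
  p <- sum(schema$role == "output")
  base <- column_base(schema, spec$rating_levels)
  k <- spec$n_efficient

  # anchor size factors, spread over [0.3, 1]; g(r) = sqrt(r) on outputs
  r <- if (k == 1) 0.65 else sort(stats::runif(k, 0.3, 1))
  g <- sqrt(r)
  raw <- matrix(NA_real_, spec$n, m + p)
  parent <- rep(NA_integer_, spec$n)
  u <- rep(1, spec$n)
  for (a in seq_len(k)) raw[a, ] <- base * c(rep(r[a], m), rep(g[a], p))
  if (spec$n > k) {
    parent[(k + 1):spec$n] <- sample.int(k, spec$n - k, replace = TRUE)
    u[(k + 1):spec$n] <- stats::rbeta(spec$n - k, spec$inefficiency[1],
                                      spec$inefficiency[2])
    # keep factors away from the extremes so entries stay finite and positive
    u[(k + 1):spec$n] <- pmin(pmax(u[(k + 1):spec$n], 0.05), 0.99)
    for (i in (k + 1):spec$n) {
      pr <- raw[parent[i], ]
      raw[i, ] <- pr * c(rep(1 / u[i], m), rep(u[i], p))
      if (spec$noise > 0)
        raw[i, ] <- pmax(raw[i, ] * (1 + spec$noise * stats::rnorm(m + p)), 0)
    }
  }
  for (j in seq_len(m + p)) {
    if (schema$scale[j] == "rating")
      raw[, j] <- round_ordinal(raw[, j], spec$rating_levels)
    else if (schema$scale[j] == "count")
      raw[, j] <- pmax(round(raw[, j]), 1)
  }
  ord <- sample.int(spec$n)
  raw <- raw[ord, , drop = FALSE]
  parent <- parent[ord]
  u <- u[ord]
  efficient <- !is.na(match(ord, seq_len(k)))
  dmu_ids <- sprintf("DMU%02d", seq_len(spec$n))
  panel <- performance_panel(spec$perspective, dmu_ids,
                             X = raw[, schema$role == "input", drop = FALSE],
                             Y = raw[, schema$role == "output", drop = FALSE],
                             columns = schema)
  truth <- data.frame(dmu_id = dmu_ids, efficient = efficient,
                      parent = ifelse(is.na(parent), NA_character_,
                                      sprintf("anchor%02d", parent)),
                      u = u, stringsAsFactors = FALSE)
  list(panel = panel, truth = truth)
}

# smooth random surface on the unit square: a few random cosine bumps
smooth_field <- function(uv, n_terms = 4) {
  a <- stats::runif(n_terms, -1, 1)
  fx <- stats::runif(n_terms, 0.5, 2)
  fy <- stats::runif(n_terms, 0.5, 2)
  ph <- stats::runif(n_terms, 0, 2 * pi)
  val <- rep(0, nrow(uv))
  for (t in seq_len(n_terms))
    val <- val + a[t] * cos(2 * pi * (fx[t] * uv[, 1] + fy[t] * uv[, 2]) + ph[t])
  val / sqrt(n_terms)
}

#' Generate a synthetic spatial sample with a planted GDP slope
#'
#' Coordinates are uniform on the unit square (a stand-in for projected
#' planar coordinates); the GDP-per-capita covariate is a smooth spatial
#' field plus local variation; the response is
#' `beta0 + spatial_beta1 * standardised(GDP) + noise`, where the noise
#' mixes white and spatially correlated components with total standard
#' deviation `spatial_noise`. The response is generated on this unbounded
#' latent scale (it is not clamped to `[0, 1]`) so slope recovery is
#' unbiased.
#'
#' @param spec a [synthetic_spec()].
#' @param panel_scores `"simulate"` (default) to draw the response from the
#'   planted linear model, or a numeric vector of `n` scores (e.g. DEA
#'   scores from [evaluate_panel()]) to use as the response directly.
#' @return list with `points` (data.frame `dmu_id`, `u`, `v`,
#'   `gdp_per_capita`, `score`) and `truth` (list `beta0`, `beta1`).
#' @export
generate_spatial <- function(spec, panel_scores = "simulate") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1000L)
  n <- spec$n
  uv <- cbind(stats::runif(n), stats::runif(n))
  gdp <- 12 + 5 * smooth_field(uv) + stats::rnorm(n, 0, 1.5)  # 10k CNY per capita
  gdp <- pmax(gdp, 1)
  beta0 <- 0.6
  if (identical(panel_scores, "simulate")) {
    z <- (gdp - mean(gdp)) / stats::sd(gdp)
    eps <- spec$spatial_noise *
      (sqrt(0.7) * stats::rnorm(n) + sqrt(0.3) * smooth_field(uv))
    score <- beta0 + spec$spatial_beta1 * z + eps
  } else {
    if (!is.numeric(panel_scores) || length(panel_scores) != n)
      cb_error("carebench_bad_size",
               "panel_scores must be 'simulate' or a numeric vector of length n")
    score <- panel_scores
  }
  points <- data.frame(dmu_id = sprintf("DMU%02d", seq_len(n)),
                       u = uv[, 1], v = uv[, 2], gdp_per_capita = gdp,
                       score = score, stringsAsFactors = FALSE)
  list(points = points, truth = list(beta0 = beta0, beta1 = spec$spatial_beta1))
}

#' Write a spatial points table to CSV
#'
#' @param points data.frame as produced by [generate_spatial()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spatial_points <- function(points, path) {
  df <- points
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
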