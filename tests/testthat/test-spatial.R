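# brute-force oracle: minimise squared error over a coefficient grid,
# refined around the best cell
grid_ols <- function(x, y, span = 10, steps = 3) {
  b0 <- 0; b1 <- 0; width <- span
  for (s in seq_len(steps)) {
    g0 <- seq(b0 - width, b0 + width, length.out = 201)
    g1 <- seq(b1 - width, b1 + width, length.out = 201)
    sse <- outer(g0, g1, function(a, b)
      colSums((outer(y, rep(1, length(a))) - outer(rep(1, length(y)), a) -
                 x %o% b)^2))
    idx <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    b0 <- g0[idx[1]]; b1 <- g1[idx[2]]
    width <- width / 40
  }
  c(b0 = b0, b1 = b1)
}

test_that("fit_ols solves the normal equations with classical inference", {
  # exact line: zero residuals
  x <- c(0, 1, 2, 3)
  f <- fit_ols(x, 2 + 3 * x)
  expect_equal(f$beta0, 2)
  expect_equal(f$beta1, 3)
  expect_equal(f$residuals, rep(0, 4))
  expect_equal(sum(f$residuals), 0, tolerance = 1e-9)

  # hand-solved: x = (0,1,2), y = (0,0,3) -> slope 1.5, intercept -0.5
  f2 <- fit_ols(c(0, 1, 2), c(0, 0, 3))
  expect_equal(f2$beta1, 1.5)
  expect_equal(f2$beta0, -0.5)

  # agrees with a brute-force grid minimiser
  set.seed(401)
  x3 <- runif(15); y3 <- 1 - 2 * x3 + rnorm(15, 0, 0.3)
  f3 <- fit_ols(x3, y3)
  bf <- grid_ols(x3, y3)
  expect_equal(f3$beta0, unname(bf["b0"]), tolerance = 1e-3)
  expect_equal(f3$beta1, unname(bf["b1"]), tolerance = 1e-3)

  expect_error(fit_ols(rep(1, 5), 1:5), class = "carebench_rank_deficient")
  expect_error(fit_ols(1:2, 1:2), class = "carebench_bad_size")
})

test_that("gwr_weights implements the Gaussian kernel", {
  coords <- rbind(c(0, 0), c(3, 4), c(0, 5))
  w <- gwr_weights(coords, 1, bandwidth = 5)
  expect_equal(w[1], 1)                      # own location
  expect_equal(w[2], exp(-0.5))              # d = bandwidth
  expect_equal(w[3], exp(-0.5))
  expect_equal(gwr_weights(coords, 1, bandwidth = Inf), rep(1, 3))
  expect_error(gwr_weights(coords, 1, bandwidth = -1),
               class = "carebench_bad_config")
})

test_that("GWR with infinite bandwidth reproduces OLS at every location", {
  set.seed(402)
  n <- 40
  pts <- data.frame(dmu_id = seq_len(n), u = runif(n), v = runif(n),
                    gdp_per_capita = runif(n, 5, 20))
  pts$score <- 0.9 - 0.03 * pts$gdp_per_capita + rnorm(n, 0, 0.05)
  ols <- fit_ols(pts$gdp_per_capita, pts$score)
  gwr <- fit_gwr(pts, bandwidth = Inf)
  expect_true(all(abs(gwr$local_beta[, 1] - ols$beta0) < 1e-6))
  expect_true(all(abs(gwr$local_beta[, 2] - ols$beta1) < 1e-6))
  expect_lt(gwr$coef_interval$max[2] - gwr$coef_interval$min[2], 1e-10)
})

test_that("a small bandwidth resolves two spatial regimes of opposite slope", {
  set.seed(403)
  n <- 30
  # cluster 1 near (0, 0) with slope -0.3; cluster 2 near (10, 10) with +0.3
  u <- c(runif(n, 0, 1), runif(n, 10, 11))
  v <- c(runif(n, 0, 1), runif(n, 10, 11))
  x <- runif(2 * n, 0, 10)
  y <- c(2 - 0.3 * x[1:n], 2 + 0.3 * x[(n + 1):(2 * n)]) + rnorm(2 * n, 0, 0.01)
  pts <- data.frame(u = u, v = v, gdp_per_capita = x, score = y)
  gwr <- fit_gwr(pts, bandwidth = 1)
  expect_true(all(gwr$local_beta[1:n, 2] < -0.25))
  expect_true(all(gwr$local_beta[(n + 1):(2 * n), 2] > 0.25))
})

test_that("the coefficient interval narrows with bandwidth on homogeneous data", {
  set.seed(404)
  n <- 40
  pts <- data.frame(u = runif(n), v = runif(n), gdp_per_capita = runif(n, 5, 20))
  pts$score <- 1 - 0.3 * pts$gdp_per_capita + rnorm(n, 0, 0.02)
  widths <- vapply(c(0.3, 1, 5), function(bw) {
    ci <- fit_gwr(pts, bandwidth = bw)$coef_interval
    ci$max[2] - ci$min[2]
  }, 1)
  expect_true(all(diff(widths) < 1e-9))      # monotone non-increasing
  # and with a planted constant slope the interval is narrow around it
  ci <- fit_gwr(pts, bandwidth = 5)$coef_interval
  expect_lt(ci$max[2] - ci$min[2], 0.05)
  expect_lt(abs((ci$max[2] + ci$min[2]) / 2 + 0.3), 0.05)
})

test_that("CV bandwidth selection runs and beats a degenerate bandwidth", {
  set.seed(405)
  n <- 35
  pts <- data.frame(u = runif(n), v = runif(n), gdp_per_capita = runif(n, 5, 20))
  pts$score <- 1 - 0.2 * pts$gdp_per_capita + rnorm(n, 0, 0.05)
  gwr <- fit_gwr(pts, bandwidth = "cv")
  expect_gt(gwr$bandwidth, 0)
  expect_true(is.finite(gwr$cv_score))
  # data are homogeneous: CV must not pick a tiny, overfitting bandwidth
  d <- as.matrix(dist(cbind(pts$u, pts$v)))
  expect_gt(gwr$bandwidth, min(d[d > 0]))
})

test_that("rank-deficient locations are flagged without aborting", {
  # constant covariate makes every location rank deficient
  pts <- data.frame(u = runif(10), v = runif(10),
                    gdp_per_capita = rep(3, 10), score = rnorm(10))
  gwr <- fit_gwr(pts, bandwidth = 1)
  expect_equal(gwr$flagged, 1:10)
})
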