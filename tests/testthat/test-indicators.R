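test_that("the indicator catalog and final schemas have the 4E structure", {
  cat_ <- indicator_catalog()
  expect_equal(nrow(cat_), 25)
  expect_setequal(unique(cat_$dimension),
                  c("Economy", "Efficiency", "Effectiveness", "Equity"))
  expect_false(anyDuplicated(cat_$code) > 0)

  eco <- economic_schema()
  expect_equal(sum(eco$role == "input"), 4)
  expect_equal(sum(eco$role == "output"), 5)
  soc <- social_schema()
  expect_equal(sum(soc$role == "input"), 4)
  expect_equal(sum(soc$role == "output"), 8)
  # each final code belongs to exactly one of the two schemas
  expect_length(intersect(eco$code, soc$code), 0)
})

test_that("schema sidecars round-trip through file I/O", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_schema(social_schema(), path)
  back <- read_schema(path)
  expect_equal(back, social_schema())
  # the shipped fixtures load too
  shipped <- read_schema(system.file("extdata", "schema_economic.tsv",
                                     package = "carebench"))
  expect_equal(shipped, economic_schema())
})

test_that("spearman_rho matches the rank-formula on hand-checked cases", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(30, 20, 10)), -1)
  # ranks (1,2,3,4) vs (2,1,4,3): 1 - 6 * 4 / (4 * 15) = 0.6
  expect_equal(spearman_rho(1:4, c(2, 1, 4, 3)), 0.6)
  # invariant under strictly monotone transforms and symmetric
  set.seed(11)
  for (k in 1:20) {
    a <- runif(8); b <- runif(8)
    expect_equal(spearman_rho(a, b), spearman_rho(b, a))
    expect_equal(spearman_rho(exp(3 * a), b), spearman_rho(a, b))
    expect_equal(spearman_rho(a, -1 / (b + 1)), spearman_rho(a, b))
  }
  # ties get average ranks
  expect_equal(spearman_rho(c(1, 1, 2), c(1, 1, 2)), 1)
})

test_that("spearman_rho flags undefined and invalid input", {
  expect_true(is.na(spearman_rho(c(1, 1, 1), c(1, 2, 3))))
  expect_error(spearman_rho(1:3, 1:4), class = "carebench_length_mismatch")
  expect_error(spearman_rho(1:2, 1:2), class = "carebench_bad_size")
})

test_that("screening drops the later-indexed member of correlated pairs", {
  set.seed(5)
  base <- runif(20, 1, 10)
  # IN2 duplicates IN1 (rho = 1); OUT1 independent
  pan <- performance_panel(
    "custom", sprintf("D%02d", 1:20),
    X = cbind(base, base * 2), Y = matrix(runif(20, 1, 10)),
    new_test_schema(2, 1))
  scr <- screen_indicators(pan, threshold = 0.8)
  expect_equal(scr$dropped$code, "IN2")
  expect_equal(scr$dropped$rho, 1)
  expect_setequal(scr$retained, c("IN1", "OUT1"))
  expect_equal(unname(diag(scr$pairwise_rho)), rep(1, 3))

  # unreachable threshold retains everything
  scr2 <- screen_indicators(pan, threshold = 1.01)
  expect_setequal(scr2$retained, c("IN1", "IN2", "OUT1"))
  expect_equal(nrow(scr2$dropped), 0)
})

test_that("screening respects role groups and the all-columns flag", {
  set.seed(6)
  a <- sort(runif(15, 1, 10))
  # input IN1 and output OUT1 perfectly rank-correlated: only dropped when
  # screening across roles
  pan <- performance_panel("custom", sprintf("D%02d", 1:15),
                           X = cbind(a, runif(15, 1, 10)),
                           Y = matrix(a + 1), new_test_schema(2, 1))
  within <- screen_indicators(pan, threshold = 0.9)
  expect_true("OUT1" %in% within$retained)
  across <- screen_indicators(pan, threshold = 0.9, within_roles = FALSE)
  expect_false("OUT1" %in% across$retained)
})

test_that("three-column screening drops exactly the correlated later column", {
  set.seed(7)
  n <- 40
  a <- runif(n, 1, 10)
  b <- a + runif(n, 0, 0.4)        # rank-correlated with a above 0.9
  c_ <- runif(n, 1, 10)            # independent
  pan <- performance_panel("custom", sprintf("D%02d", 1:n),
                           X = cbind(a, b, c_), Y = matrix(runif(n, 1, 10)),
                           new_test_schema(3, 1))
  rho_ab <- spearman_rho(a, b)
  expect_gt(abs(rho_ab), 0.9)
  scr <- screen_indicators(pan, threshold = 0.9)
  expect_equal(scr$dropped$code, "IN2")
  expect_setequal(scr$retained, c("IN1", "IN3", "OUT1"))
})

test_that("constant columns propagate as not screenable", {
  pan <- performance_panel("custom", sprintf("D%02d", 1:10),
                           X = cbind(rep(5, 10), runif(10, 1, 2)),
                           Y = matrix(runif(10, 1, 2)), new_test_schema(2, 1))
  scr <- screen_indicators(pan, threshold = 0.8)
  expect_true(nrow(scr$not_screenable) >= 1)
  expect_true("IN1" %in% scr$retained)  # never silently dropped
})
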