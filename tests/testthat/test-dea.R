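# The 3-DMU worked example: A(x=2, y=2), B(4, 4), C(4, 2) under VRS.
# A and B span the frontier; C is dominated by A (same output, double the
# input), with maximal slack sum 2.
abc_panel <- function() panel_1x1(c(2, 4, 4), c(2, 4, 2))

test_that("delta offsets follow the min-of-data formula", {
  pan <- panel_1x1(c(5, 8), c(2, 9))
  off <- delta_offsets(pan, dea_config(delta = 0.001))
  expect_equal(off$delta_in, 0.005)
  expect_equal(off$delta_out, 0.002)
  expect_equal(delta_offsets(pan, dea_config(delta = 0)),
               list(delta_in = 0, delta_out = 0))
  # a zero entry: literal mode gives a zero offset, positive mode skips it
  pan0 <- panel_1x1(c(0, 8), c(2, 9))
  expect_equal(delta_offsets(pan0, dea_config())$delta_in, 0)
  expect_equal(delta_offsets(pan0, dea_config(min_mode = "positive"))$delta_in,
               0.008)
})

test_that("the slack LP solves the worked three-DMU example", {
  pan <- abc_panel()
  cfg <- dea_config(delta = 0)
  expect_equal(solve_delta_sbm(pan, 1, cfg)$objective, 0, tolerance = 1e-9)
  expect_equal(solve_delta_sbm(pan, 2, cfg)$objective, 0, tolerance = 1e-9)
  solC <- solve_delta_sbm(pan, 3, cfg)
  expect_equal(solC$objective, 2, tolerance = 1e-9)
  # lexicographic tie-break maximises the input slack first: C projects
  # onto A with s- = 2, s+ = 0
  expect_equal(unname(solC$s_in), 2, tolerance = 1e-9)
  expect_equal(unname(solC$s_out), 0, tolerance = 1e-9)
  expect_equal(sum(solC$lambda), 1, tolerance = 1e-9)
  # a single-DMU technology puts the unit on its own frontier
  sol1 <- solve_delta_sbm(panel_1x1(c(3, 3), c(5, 5)), 1, cfg)
  expect_equal(sol1$objective, 0, tolerance = 1e-9)
})

test_that("targets and scores follow the projection equations exactly", {
  tg <- compute_targets(4, 2, list(s_in = 2, s_out = 0),
                        list(delta_in = 0, delta_out = 0))
  expect_equal(tg$x_star, 2)
  expect_equal(tg$y_star, 2)
  tg2 <- compute_targets(4, 2, list(s_in = 0, s_out = 2),
                         list(delta_in = 0, delta_out = 0.001))
  expect_equal(tg2$y_star, 3.999)
  # zero slacks, zero offsets: identity
  tg3 <- compute_targets(c(1, 2), c(3), list(s_in = c(0, 0), s_out = 0),
                         list(delta_in = 0, delta_out = 0))
  expect_equal(tg3$x_star, c(1, 2))

  cfg <- dea_config(delta = 0)
  expect_equal(compute_score(4, 2, list(x_star = 4, y_star = 2), cfg), 1)
  expect_equal(compute_score(4, 2, list(x_star = 2, y_star = 2), cfg), 0.5)
  expect_equal(compute_score(c(2, 2), 4, list(x_star = c(1, 1), y_star = 4),
                             cfg), 0.5)
  expect_error(compute_score(c(0, 0), 4, list(x_star = c(1, 1), y_star = 4),
                             cfg), class = "carebench_degenerate_score")
})

test_that("scores partition into the four bands at the documented cuts", {
  expect_equal(classify_score(c(0, 0.3999, 0.4, 0.7999, 0.8, 0.9999, 1)),
               c("Third level", "Third level", "Second level", "Second level",
                 "First level", "First level", "DEA Efficient"))
  # the three reference scores from the band narrative
  expect_equal(classify_score(0.8837), "First level")
  expect_equal(classify_score(0.6742), "Second level")
  expect_equal(classify_score(0.3324), "Third level")
  expect_error(classify_score(-0.1), class = "carebench_bad_score")
})

test_that("evaluate_panel composes the pieces and preserves order", {
  ev <- evaluate_panel(abc_panel(), dea_config(delta = 0))
  expect_equal(ev$results$score, c(1, 1, 0.5), tolerance = 1e-9)
  expect_equal(ev$results$band,
               c("DEA Efficient", "DEA Efficient", "Second level"))
  expect_equal(band_summary(ev)$n_dmus, c(2L, 0L, 1L, 0L))

  # identical DMUs all sit on the frontier
  same <- panel_1x1(rep(3, 4), rep(5, 4))
  ev2 <- evaluate_panel(same, dea_config(delta = 0))
  expect_true(all(abs(ev2$results$score - 1) < 1e-9))
})

test_that("strictly dominated DMUs always get positive slack", {
  set.seed(101)
  for (k in 1:25) {
    pl <- plant_dominated(n = sample(3:7, 1), m = sample(1:3, 1),
                          p = sample(1:3, 1))
    sol <- solve_delta_sbm(pl$panel, pl$bad, dea_config(delta = 0))
    expect_gt(sol$objective, 1e-6)
    ev <- evaluate_panel(pl$panel, dea_config())
    expect_false(ev$results$band[pl$bad] == "DEA Efficient")
  }
})

test_that("scores are invariant under a common rescaling of the data", {
  set.seed(102)
  pan <- random_panel(12, 2, 2)
  base <- evaluate_panel(pan, dea_config())$results$score
  for (c_ in c(1e-3, 1e3)) {
    scaled <- performance_panel(pan$perspective, pan$dmu_ids,
                                pan$X * c_, pan$Y * c_, pan$columns)
    sc <- evaluate_panel(scaled, dea_config())$results$score
    expect_lt(max(abs(sc - base)), 1e-9)
  }
})

test_that("LP objectives equal the geometric oracle on small 1x1 panels", {
  set.seed(103)
  for (k in 1:30) {
    n <- sample(2:8, 1)
    x <- round(runif(n, 1, 10), 3); y <- round(runif(n, 1, 10), 3)
    pan <- panel_1x1(x, y)
    for (l in seq_len(n))
      expect_equal(solve_delta_sbm(pan, l, dea_config(delta = 0))$objective,
                   oracle_sbm_1x1(x, y, l), tolerance = 1e-7)
  }
})

test_that("with delta = 0 scores lie in (0, 1] and hit 1 iff slacks vanish", {
  set.seed(104)
  pan <- random_panel(10, 2, 2)
  ev <- evaluate_panel(pan, dea_config(delta = 0))
  expect_true(all(ev$results$score > 0 & ev$results$score <= 1 + 1e-12))
  zero <- ev$results$objective <= 1e-7
  expect_equal(abs(ev$results$score - 1) <= 1e-7, zero)
})

test_that("re-evaluating a DMU replaced by its delta = 0 targets scores 1", {
  set.seed(105)
  pan <- random_panel(8, 2, 1)
  cfg <- dea_config(delta = 0)
  ev <- evaluate_panel(pan, cfg)
  l <- which.min(ev$results$score)
  X2 <- pan$X; Y2 <- pan$Y
  X2[l, ] <- ev$targets_x[l, ]; Y2[l, ] <- ev$targets_y[l, ]
  pan2 <- performance_panel(pan$perspective, pan$dmu_ids, X2, Y2, pan$columns)
  ev2 <- evaluate_panel(pan2, cfg)
  expect_equal(ev2$results$score[l], 1, tolerance = 1e-6)
  expect_lt(ev2$results$objective[l], 1e-6)
})

test_that("delta > 0 reports raw scores above 1 for efficient units but still
           classifies them efficient", {
  pan <- abc_panel()
  ev <- evaluate_panel(pan, dea_config(delta = 0.001))
  expect_gt(ev$results$score[1], 1)          # delta-worsened targets
  expect_equal(ev$results$band[1], "DEA Efficient")
  expect_equal(ev$results$band[3], "Second level")
})

test_that("evaluate_panel writes deterministic result files", {
  set.seed(106)
  pan <- random_panel(6, 2, 2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dea_results(evaluate_panel(pan, dea_config()), f1)
  write_dea_results(evaluate_panel(pan, dea_config()), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("dea_config validates its parameters", {
  expect_error(dea_config(delta = -1), class = "carebench_bad_config")
  expect_error(dea_config(input_weights = 0), class = "carebench_bad_config")
  expect_error(solve_delta_sbm(abc_panel(), 9), class = "carebench_bad_index")
})
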