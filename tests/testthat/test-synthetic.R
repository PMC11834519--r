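test_that("generation is reproducible: same spec and seed, identical output", {
  s <- synthetic_spec(n = 30, seed = 17)
  g1 <- generate_panel(s)
  g2 <- generate_panel(s)
  expect_identical(g1, g2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(g1$panel, f1); write_panel(g2$panel, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  sp1 <- generate_spatial(s); sp2 <- generate_spatial(s)
  expect_identical(sp1, sp2)
  # a different seed changes the draw
  expect_false(identical(generate_panel(synthetic_spec(n = 30, seed = 18)), g1))
})

test_that("generated panels have the perspective shapes and pass validation", {
  eco <- generate_panel(synthetic_spec(n = 20, perspective = "economic",
                                       seed = 2))$panel
  expect_equal(c(ncol(eco$X), ncol(eco$Y)), c(4, 5))
  soc <- generate_panel(synthetic_spec(n = 20, perspective = "social",
                                       seed = 2))$panel
  expect_equal(c(ncol(soc$X), ncol(soc$Y)), c(4, 8))
  # round-trips through file I/O and re-validation
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(soc, f)
  back <- read_panel(f, "social")
  expect_identical(unname(back$X), unname(soc$X))
  # rating columns live on the ordinal scale
  ratings <- eco$Y[, eco$columns$scale[eco$columns$role == "output"] == "rating"]
  expect_true(all(ratings %in% 1:5))
})

test_that("with zero noise the planted frontier is exactly recovered", {
  for (seed in c(3, 14, 41)) {
    gen <- generate_panel(synthetic_spec(n = 25, n_efficient = 4, noise = 0,
                                         seed = seed))
    ev <- evaluate_panel(gen$panel, dea_config(tie_break = "solver"))
    expect_setequal(ev$results$dmu_id[ev$results$band == "DEA Efficient"],
                    gen$truth$dmu_id[gen$truth$efficient])
    # and the planted units are pairwise non-dominated
    anc <- which(gen$truth$efficient)
    for (a in anc) for (b in anc) if (a != b)
      expect_false(dominates(gen$panel$X[a, ], gen$panel$Y[a, ],
                             gen$panel$X[b, ], gen$panel$Y[b, ]))
  }
})

test_that("a u-scaled copy of a single anchor scores u^2 at delta = 0", {
  for (u in c(0.9, 0.5, 0.1)) {
    pan <- panel_1x1(c(2, 2 / u), c(3, 3 * u))
    ev <- evaluate_panel(pan, dea_config(delta = 0))
    expect_equal(ev$results$score[2], u^2, tolerance = 1e-9)
    expect_equal(ev$results$score[1], 1, tolerance = 1e-9)
  }
})

test_that("the spatial generator plants a recoverable slope", {
  # noiseless: OLS recovers the slope exactly with zero residuals
  s0 <- synthetic_spec(n = 40, spatial_noise = 0, seed = 5)
  sp0 <- generate_spatial(s0)
  z <- (sp0$points$gdp_per_capita - mean(sp0$points$gdp_per_capita)) /
    sd(sp0$points$gdp_per_capita)
  f0 <- fit_ols(z, sp0$points$score)
  expect_equal(f0$beta1, -0.321, tolerance = 1e-9)
  expect_equal(max(abs(f0$residuals)), 0, tolerance = 1e-9)

  # null slope: estimate within 3 SE of zero
  sN <- synthetic_spec(n = 75, spatial_beta1 = 0, spatial_noise = 0.5, seed = 8)
  spN <- generate_spatial(sN)
  zN <- (spN$points$gdp_per_capita - mean(spN$points$gdp_per_capita)) /
    sd(spN$points$gdp_per_capita)
  fN <- fit_ols(zN, spN$points$score)
  expect_lt(abs(fN$beta1), 3 * fN$se[2])

  # supplied panel scores are passed through as the response
  sc <- runif(40)
  spP <- generate_spatial(s0, panel_scores = sc)
  expect_equal(spP$points$score, sc)
})

test_that("spec validation rejects impossible settings", {
  expect_error(synthetic_spec(n = 5, n_efficient = 9),
               class = "carebench_bad_spec")
  expect_error(synthetic_spec(noise = -1), class = "carebench_bad_spec")
  expect_error(synthetic_spec(inefficiency = c(1, -2)),
               class = "carebench_bad_spec")
})
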