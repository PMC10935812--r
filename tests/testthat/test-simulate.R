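test_that("generated cohorts satisfy the structural invariants in every setting", {
  for (s in 1:5) {
    spec <- scenario_preset(s, n = 2000)
    coh <- draw_cohort(spec, seed = 100 + s)
    expect_true(all(coh$w > 0 & coh$w < coh$t_true))
    expect_equal(coh$v, coh$w + 50)
    expect_true(all(coh$t_true[coh$r == 1] < coh$v[coh$r == 1]))
    expect_equal(coh$delta_true, as.numeric(coh$t_true < coh$v))
    expect_true(all(coh$p_match[coh$r == 0] == 0))
    expect_true(all(coh$p_match[coh$r == 1] > 0 & coh$p_match[coh$r == 1] <= 1))
    expect_true(all(is.na(coh$t_star[coh$r == 0])))
    expect_true(all(!is.na(coh$t_star[coh$r == 1])))
    # Bernoulli(0.5) margins within binomial error (4 SDs at n = 2000)
    expect_lt(abs(mean(coh$x) - 0.5), 4 * sqrt(0.25 / 2000))
    expect_lt(abs(mean(coh$z) - 0.5), 4 * sqrt(0.25 / 2000))
  }
})

test_that("the same seed reproduces a cohort bitwise", {
  spec <- scenario_preset(2, n = 500)
  a <- draw_cohort(spec, seed = 7)
  b <- draw_cohort(spec, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, draw_cohort(spec, seed = 8)))
})

test_that("weibull_median matches the closed form and a bisection oracle", {
  expect_equal(weibull_median(0, 1), log(2))
  # bisection on S(t) = 0.5 under the same parameterisation
  for (case in list(c(4.2, 6), c(4.4, 6), c(3.0, 2.5))) {
    med <- weibull_median(case[1], case[2])
    oracle <- bisect(function(t) weib_surv(t, case[1], case[2]) - 0.5,
                     1e-6, 1e4)
    expect_equal(med, oracle, tolerance = 1e-8)
  }
  grid <- seq(3, 5, by = 0.25)
  expect_true(all(diff(weibull_median(grid, 6)) > 0))
  expect_error(weibull_median(4, -1), "shape_p")
})

test_that("empirical survival at the analytic median is one half", {
  spec <- scenario_preset(1, n = 1e5)
  coh <- draw_cohort(spec, seed = 11)
  lin <- 4.4 - 0.2 * coh$x
  frac <- mean(coh$t_true > weibull_median(lin, 6))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("match-score measurement error follows the stated law", {
  # scores above the threshold leave the event age untouched
  expect_identical(apply_match_error(rep(70, 5), rep(0.95, 5)), rep(70, 5))
  # empirical SD at p_match = 0.4 matches 1.8^(1/0.4) within 3 MC SEs
  set.seed(21)
  n <- 1e5
  noise <- apply_match_error(rep(70, n), rep(0.4, n)) - 70
  target <- 1.8^(1 / 0.4)
  expect_lt(abs(sd(noise) - target), 3 * target / sqrt(2 * n))
  expect_error(apply_match_error(70, 0), "p_match")
})

test_that("the threshold splits exact from noisy matched ages at both extremes", {
  # threshold 1: no score exceeds it, so every matched age is perturbed
  spec <- scenario_preset(1, n = 5000, unequivocal_threshold = 1,
                          floor_t_star = FALSE)
  coh <- draw_cohort(spec, seed = 31)
  m <- coh$r == 1
  expect_gt(sum(m), 0)
  expect_identical(sum(coh$t_star[m] == coh$t_true[m]), 0L)
  # threshold 0: every positive score exceeds it, so every match is exact
  spec0 <- scenario_preset(1, n = 5000, unequivocal_threshold = 0)
  coh0 <- draw_cohort(spec0, seed = 31)
  m0 <- coh0$r == 1
  expect_identical(coh0$t_star[m0], coh0$t_true[m0])
})

test_that("degenerate and invalid missingness links are handled", {
  spec <- scenario_preset(1, n = 500, missing_link = function(l) 0 * l)
  coh <- draw_cohort(spec, seed = 41)
  expect_true(all(coh$r == 0))
  expect_true(all(coh$p_match == 0))
  # the exp link is only valid while the linear predictor stays negative
  bad <- scenario_preset(1, n = 500, missing_link = "exp")  # delta z = +2
  expect_error(draw_cohort(bad, seed = 42), "outside \\[0,1\\]")
  ok <- scenario_spec(alpha = c(4.4, -0.2, 0), delta = c(-1, 0, 0),
                      missing_link = "exp", n = 2000)
  coh <- draw_cohort(ok, seed = 43)
  expect_gt(mean(coh$r), 0.1)
})

test_that("scenario specs validate their fields and read from YAML", {
  expect_error(scenario_spec(c(4, 0, 0), c(0, 0, 0), shape_p = -1), "shape_p")
  expect_error(scenario_spec(c(4, 0, 0), c(0, 0, 0), score_beta = c(0, 2)),
               "score_beta")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("alpha: [4.4, -0.2, 0]", "delta: [-1, 0, 2]", "'n': 100",
               "bogus: 1"), path)
  expect_error(read_scenario(path), "bogus")
  spec5 <- scenario_preset("setting5")
  expect_true(spec5$score_z_dependent)
  expect_equal(spec5$alpha, c(4.5, -0.2, -0.2))
})

test_that("setting-5 match scores are weaker when z = 1", {
  coh <- draw_cohort(scenario_preset(5, n = 20000), seed = 51)
  m <- coh$r == 1
  expect_lt(mean(coh$p_match[m & coh$z == 1]),
            mean(coh$p_match[m & coh$z == 0]))
})
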