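test_that("weighted KM reproduces the textbook curve and is scale-invariant", {
  set <- as_set(c(1, 2, 3), c(1, 1, 1))
  km <- weighted_km(set)
  expect_equal(km$surv, c(2/3, 1/3, 0))

  set2 <- set
  set2$weight <- set2$weight * 2
  km2 <- weighted_km(set2)
  expect_equal(km2$surv, km$surv)
  expect_equal(km2$time, km$time)
})

test_that("weighted KM agrees with a hand-computed product-limit oracle", {
  # the specific fractional-weight case
  set <- as_set(c(1, 2, 3), c(1, 1, 1), weight = c(1, 1, 0.5))
  km <- weighted_km(set)
  oracle <- km_oracle(set$time, set$event, set$weight)
  expect_equal(km$time, oracle$time)
  expect_equal(km$surv, oracle$surv)

  # random weighted datasets with censoring and ties
  for (seed in 1:30) {
    set.seed(seed)
    n <- 25
    time <- sample(1:10, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    wt <- sample(c(0.5, 1, 2), n, replace = TRUE)
    s <- as_set(time, event, weight = wt)
    km <- weighted_km(s)
    oracle <- km_oracle(time, event, wt)
    expect_equal(km$time[km$n_event > 0], oracle$time)
    expect_equal(km$surv[km$n_event > 0], oracle$surv)
  }
})

test_that("the KM median uses the at-or-below-one-half rule", {
  expect_equal(km_median(list(time = c(1, 2), surv = c(2/3, 1/3))), 2)
  # curve touching 0.5 exactly at an event time: that time is the median
  expect_equal(km_median(list(time = c(1, 2), surv = c(0.5, 0.25))), 1)
  set <- as_set(c(5, 7), c(1, 1))
  expect_equal(km_median(weighted_km(set)), 5)
  # heavily censored curve never reaching 0.5: undefined, not extrapolated
  expect_true(is.na(km_median(list(time = c(1, 2), surv = c(0.9, 0.6)))))
})

test_that("Cox point estimates are invariant to half-weight row duplication", {
  set.seed(201)
  n <- 20
  s <- as_set(rexp(n, 0.1) + 1, rbinom(n, 1, 0.8),
              x = rbinom(n, 1, .5), z = rbinom(n, 1, .5))
  dup <- rbind(s, s)
  dup$weight <- 0.5
  class(dup) <- class(s)
  b1 <- fit_cox(s)$beta
  b2 <- fit_cox(dup)$beta
  expect_equal(b1, b2, tolerance = 1e-7)
})

test_that("joint AFT/Cox fits on uncensored Weibull data satisfy beta1 = -alpha1 * p", {
  coh <- uncensored_cohort(2e4, c(4.4, -0.2, 0), 6, seed = 211)
  set <- build_analysis_set(coh, "cc")
  aft <- fit_weibull_aft(set)
  cox <- fit_cox(set)
  se_a <- sqrt(diag(aft$vcov))
  expect_lt(abs(aft$alpha["x"] + 0.2), 3 * se_a["x"])
  expect_lt(abs(log(aft$shape_p) - log(6)), 3 * se_a[length(se_a)])
  # the AFT coefficient mapped through the shape matches the Cox fit
  implied <- aft_to_cox(aft$alpha[["x"]], aft$shape_p)
  se_joint <- 3 * (sqrt(cox$vcov["x", "x"]) + 6 * se_a["x"])
  expect_lt(abs(cox$beta[["x"]] - implied), se_joint)
})

test_that("degenerate analysis sets are refused", {
  s <- as_set(c(1, 2, 3, 4), c(0, 0, 0, 0), x = c(0, 1, 0, 1),
              z = c(0, 0, 1, 1))
  expect_error(fit_weibull_aft(s), "censored")
  expect_error(fit_cox(s), "events")
  s2 <- as_set(c(1, 2, 3, 4), c(1, 1, 1, 1), x = c(0, 0, 0, 0),
               z = c(0, 1, 0, 1))
  expect_error(fit_cox(s2), "vary")
})

test_that("the AFT to Cox conversion is exact and sign-correct", {
  expect_equal(aft_to_cox(-0.2, 6), 1.2, tolerance = 1e-12)
  expect_equal(aft_to_cox(0, 3.7), 0)
  expect_equal(aft_to_cox(0.1, 2), -0.2)
  expect_error(aft_to_cox(0.1, 0), "shape_p")
})

test_that("Rubin's rules match the closed form and the variance identity", {
  pooled <- rubin_pool(c(1, 2), c(0.1, 0.1))
  expect_equal(pooled$estimate, 1.5)
  expect_equal(pooled$total, 0.1 + 1.5 * 0.5)

  same <- rubin_pool(rep(3.3, 10), rep(0.2, 10))
  expect_equal(same$between, 0)
  expect_equal(same$total, 0.2)

  for (seed in 1:20) {
    set.seed(seed)
    B <- sample(2:30, 1)
    est <- rnorm(B)
    v <- runif(B, 0.1, 2)
    p <- rubin_pool(est, v)
    expect_equal(p$total, p$within + (1 + 1 / B) * p$between,
                 tolerance = 1e-12)
  }
  expect_error(rubin_pool(1, 0.1), "B >= 2")
})

test_that("pooled total variance estimates the within + inflated between components", {
  set.seed(221)
  sw2 <- 0.5; sb2 <- 0.3; B <- 50
  reps <- 300
  totals <- replicate(reps, {
    rubin_pool(rnorm(B, 0, sqrt(sb2)), rep(sw2, B))$total
  })
  target <- sw2 + (1 + 1 / B) * sb2
  mc_se <- sd(totals) / sqrt(reps)
  expect_lt(abs(mean(totals) - target), 3 * mc_se)
})

test_that("medians lacking model variance pool on between-imputation spread", {
  p <- rubin_pool(c(60, 62, 64), rep(NA_real_, 3))
  expect_false(p$within_known)
  expect_equal(p$estimate, 62)
  expect_equal(p$total, (1 + 1/3) * var(c(60, 62, 64)))
  # undefined medians drop out with a count of contributors
  p2 <- rubin_pool(c(60, NA, 64), rep(NA_real_, 3))
  expect_equal(p2$B_used, 2L)
  expect_equal(p2$estimate, 62)
})
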