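test_that("conditional-survival inversion matches a bisection oracle and is monotone", {
  fit <- make_aft(c(`(Intercept)` = 4.5, x = -0.2, z = -0.2), 6)
  # q = 0 returns the census age exactly: log(1) = 0
  expect_equal(mics_invert(0, 60, 1, 0, fit), 60, tolerance = 1e-13)
  # against a numeric root-find of the conditional CDF F(u + w | w) = q
  lin <- 4.5 - 0.2
  for (q in c(0.1, 0.5, 0.9)) {
    t_imp <- mics_invert(q, 60, 1, 0, fit)
    oracle <- bisect(function(t) {
      1 - weib_surv(t, lin, 6) / weib_surv(60, lin, 6) - q
    }, 60, 500, tol = 1e-10)
    expect_equal(t_imp, oracle, tolerance = 1e-8)
  }
  qs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(mics_invert(qs, 60, 1, 0, fit)) > 0))
  expect_error(mics_invert(1, 60, 1, 0, fit), "q")
  expect_error(mics_invert(0.5, -1, 1, 0, fit), "w")
})

test_that("inversion round-trips through the conditional CDF to 1e-10", {
  set.seed(101)
  for (i in 1:200) {
    alpha <- c(runif(1, 4, 4.6), runif(2, -0.3, 0))
    p <- runif(1, 4, 8)
    fit <- make_aft(alpha, p)
    q <- runif(1, 0.01, 0.99)
    w <- runif(1, 5, 95)
    x <- rbinom(1, 1, .5); z <- rbinom(1, 1, .5)
    t_imp <- mics_invert(q, w, x, z, fit)
    expect_gte(t_imp, w)
    expect_lt(abs(mics_conditional_cdf(t_imp, w, x, z, fit) - q), 1e-10)
  }
})

test_that("the Weibull working model recovers generative parameters", {
  coh <- uncensored_cohort(3e4, c(4.4, -0.2, 0), 6, seed = 111)
  fit <- fit_complete_case_aft(coh, threshold = 0.8)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$alpha[1] - 4.4), 3 * se[1])
  expect_lt(abs(fit$alpha[2] + 0.2), 3 * se[2])
  expect_lt(abs(fit$alpha[3] - 0), 3 * se[3])
  # delta-method SE for p = 1/sigma on the log scale
  se_logp <- se[length(se)]
  expect_lt(abs(log(fit$shape_p) - log(6)), 3 * se_logp)
  expect_error(fit_complete_case_aft(coh, threshold = 1.1), "too few")
})

test_that("MICS imputation preserves weight mass and censors at v", {
  coh <- draw_cohort(scenario_preset(1), seed = 121)
  imp <- mics_impute(coh, B = 5, seed = 1)
  for (b in 1:5) {
    set <- imp$sets[[b]]
    mass <- tapply(set$weight, set$id, sum)
    expect_true(all(abs(mass - 1) < 1e-12))
    # imputed ages never fall below the record's census age
    imp_rows <- set[set$source %in% c("equivocal_imputed", "nonmatch_imputed"), ]
    w_of <- coh$w[match(imp_rows$id, coh$id)]
    v_of <- coh$v[match(imp_rows$id, coh$id)]
    expect_true(all(imp_rows$time >= w_of - 1e-9))
    expect_true(all(imp_rows$time <= v_of + 1e-9))
    # censored-at-v rows are exactly those whose raw draw exceeded v
    raw <- imp$draws[[b]]$t_imp
    expect_equal(imp_rows$event, as.numeric(raw <= v_of))
  }
  expect_error(mics_impute(coh, B = 1), "B >= 2")
})

test_that("with nothing to impute the MI sets equal the complete-case set", {
  coh <- uncensored_cohort(300, c(4.4, -0.2, 0), 6, seed = 131)
  # all matches have p_match = 0.99: with threshold 0 nothing is equivocal
  imp <- mics_impute(coh, threshold = 0, B = 3, seed = 2)
  cc <- build_analysis_set(coh, "cc", threshold = 0)
  for (b in 1:3) {
    expect_equal(as.data.frame(imp$sets[[b]]), as.data.frame(cc),
                 ignore_attr = TRUE)
  }
})

test_that("MICS draws at a negligible census age follow the unconditional fitted Weibull", {
  big <- uncensored_cohort(2e4, c(4.4, -0.2, 0), 6, seed = 141)
  fit <- fit_complete_case_aft(big)
  n <- 1e4
  coh <- linked_cohort(data.frame(id = 1:n, x = 1, z = 0, w = 0.001,
                                  v = 1000, r = 0, p_match = 0, t_star = NA))
  imp <- mics_impute(coh, B = 2, proper = FALSE, fit = fit, seed = 3)
  t_imp <- imp$draws[[1]]$t_imp
  ks <- suppressWarnings(stats::ks.test(
    t_imp, pweibull, shape = fit$shape_p,
    scale = exp(fit$alpha[1] + fit$alpha[2])))
  expect_gt(ks$p.value, 0.01)
})

test_that("the restricted-mean model reduces to ordinary least squares when tau is inactive", {
  coh <- uncensored_cohort(500, c(4.4, -0.2, 0), 6, seed = 151)
  rm_fit <- fit_restricted_mean(coh, tau = 1e6)
  ols <- lm(log(t_star) ~ x + z, data = coh)
  expect_equal(rm_fit$coefficients, coef(ols), tolerance = 1e-12)
  expect_error(fit_restricted_mean(coh, tau = -1), "tau")

  # degenerate input: identical event ages give exact coefficients
  const <- linked_cohort(data.frame(id = 1:10, x = rep(0:1, 5),
                                    z = rep(c(0, 1), each = 5), w = 30,
                                    v = 80, r = 1, p_match = 0.9,
                                    t_star = 70))
  rm0 <- fit_restricted_mean(const, tau = 120)
  expect_equal(rm0$sigma2, 0, tolerance = 1e-20)
  expect_equal(unname(rm0$coefficients),
               c(log(70), 0, 0), tolerance = 1e-10)
})

test_that("restriction shrinks the fitted intercept", {
  coh <- uncensored_cohort(5e4, c(4.4, -0.2, 0), 6, seed = 161)
  restricted <- fit_restricted_mean(coh, tau = 80)
  unrestricted <- fit_restricted_mean(coh, tau = 1e6)
  expect_lt(restricted$coefficients[1], unrestricted$coefficients[1])
})

test_that("MIRM respects the noise-free limit, the tau cap and the mean structure", {
  coh <- four_record_cohort()
  rm_fit <- structure(list(coefficients = c(`(Intercept)` = log(70), x = 0,
                                            z = 0),
                           vcov = diag(0, 3), sigma2 = 0, tau = 65,
                           formula = ~ x + z, n = 4),
                      class = "linksurv_rm")
  imp <- mirm_impute(coh, rm_fit, B = 3, seed = 4)
  for (b in 1:3) {
    expect_equal(imp$draws[[b]]$t_imp,
                 rep(65, length(imp$draws[[b]]$t_imp)))  # exp(log 70) capped
  }

  coh <- draw_cohort(scenario_preset(1), seed = 171)
  rm_fit <- fit_restricted_mean(coh, tau = 80)
  imp <- mirm_impute(coh, rm_fit, B = 5, seed = 5)
  for (b in 1:5) {
    set <- imp$sets[[b]]
    ev <- set[set$event == 1 &
                set$source %in% c("equivocal_imputed", "nonmatch_imputed"), ]
    expect_true(all(ev$time <= 80 + 1e-9))
    mass <- tapply(set$weight, set$id, sum)
    expect_true(all(abs(mass - 1) < 1e-12))
  }

  # imputed log-times average to the fitted linear predictor
  B <- 200
  imp <- mirm_impute(coh, rm_fit, B = B, seed = 6)
  idx <- which(linksurv:::needs_imputation(coh, 0.8))
  pick <- idx[1]
  mu_hat <- sum(c(1, coh$x[pick], coh$z[pick]) * rm_fit$coefficients)
  logs <- vapply(imp$draws, function(d) d$log_t[1], numeric(1))
  mc_se <- sd(logs) / sqrt(B)
  expect_lt(abs(mean(logs) - mu_hat), 3 * mc_se +
              3 * sqrt(sum(diag(rm_fit$vcov))))
})
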