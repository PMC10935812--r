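# Independent oracles and fixture builders used across the suite. These are
# deliberately naive implementations, kept separate from the package code
# they check.

# Hand-rolled weighted product-limit estimator: explicit product over
# distinct event times of (1 - d_w / n_w) with weighted event and at-risk
# counts.
km_oracle <- function(time, event, weight = rep(1, length(time))) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(weight[time >= ts[i]])
    died <- sum(weight[time == ts[i] & event == 1])
    s <- s * (1 - died / at_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# Bisection root-find on a monotone function, independent of any closed-form
# inversion in the package.
bisect <- function(f, lower, upper, tol = 1e-12, maxit = 200) {
  fl <- f(lower)
  for (i in seq_len(maxit)) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (abs(upper - lower) < tol) return(mid)
    if (sign(fm) == sign(fl)) {
      lower <- mid
      fl <- fm
    } else {
      upper <- mid
    }
  }
  (lower + upper) / 2
}

# Weibull survival on the AFT parameterisation used throughout:
# S(t) = exp(-gamma t^p), gamma = exp(-lin)^p.
weib_surv <- function(t, lin, p) exp(-exp(-p * lin) * t^p)

# Minimal AFT working-model object for the inversion utilities, bypassing
# model fitting entirely.
make_aft <- function(alpha, shape_p, formula = ~ x + z) {
  structure(list(alpha = alpha, shape_p = shape_p,
                 scale_sigma = 1 / shape_p,
                 vcov = diag(0, length(alpha) + 1),
                 formula = formula),
            class = "linksurv_aft")
}

# A small valid cohort built by hand: one unequivocal match, one equivocal
# match, one nonmatch, one unequivocal match (the Table 1 walk-through).
four_record_cohort <- function() {
  linked_cohort(data.frame(
    id = 1:4,
    x = c(0, 1, 0, 1), z = c(0, 0, 1, 1),
    w = c(30, 40, 35, 25), v = c(80, 90, 85, 75),
    r = c(1, 1, 0, 1),
    p_match = c(0.95, 0.6, 0, 0.9),
    t_star = c(70, 65, NA, 60)))
}

# Random valid cohort for round-trip and validation property tests.
random_cohort <- function(n, seed) {
  set.seed(seed)
  w <- runif(n, 1, 80)
  r <- rbinom(n, 1, 0.5)
  p_match <- ifelse(r == 1, runif(n, 0.01, 1), 0)
  t_star <- ifelse(r == 1, w + rexp(n, 1 / 20), NA)
  linked_cohort(data.frame(id = seq_len(n), x = rbinom(n, 1, 0.5),
                           z = rbinom(n, 1, 0.5), w = w, v = w + 50,
                           r = r, p_match = p_match, t_star = t_star))
}

# Cohort of fully-observed unequivocal matches drawn from the Weibull AFT
# truth, for parameter-recovery checks: every subject matched with a perfect
# score and t_star equal to the true event age.
uncensored_cohort <- function(n, alpha, shape_p, seed) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  z <- rbinom(n, 1, 0.5)
  lin <- alpha[1] + alpha[2] * x + alpha[3] * z
  t <- rweibull(n, shape = shape_p, scale = exp(lin))
  linked_cohort(data.frame(id = seq_len(n), x = x, z = z,
                           w = pmin(t / 2, 1), v = t + 200, r = 1,
                           p_match = 0.99, t_star = t,
                           t_true = t, delta_true = 1))
}

as_set <- function(time, event, weight = rep(1, length(time)),
                   x = rep(0, length(time)), z = rep(0, length(time)),
                   id = seq_along(time)) {
  linksurv:::new_analysis_set(id, time, event, weight, x, z, "unequivocal")
}
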