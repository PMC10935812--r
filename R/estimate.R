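# Weighted survival estimators and Rubin's-rules pooling.

#' Weighted Kaplan-Meier curve
#'
#' Product-limit estimator with weighted event and at-risk counts, computed
#' through [survival::survfit()]. The curve is invariant to rescaling all
#' weights by a positive constant.
#'
#' @param data an `analysis_set` (columns `time`, `event`, `weight`, `x`,
#'   `z`).
#' @param x,z optional stratum filters; e.g. `x = 1` restricts to the exposed
#'   group, `x = 1, z = 0` to one covariate cell.
#' @return object of class `linksurv_km`: a step function description with
#'   `time` (event times), `surv` (survival after each time) and `n` rows
#'   used; `S(0) = 1` implicitly.
#' @export
weighted_km <- function(data, x = NULL, z = NULL) {
  d <- as.data.frame(data)
  if (!is.null(x)) d <- d[d$x == x, , drop = FALSE]
  if (!is.null(z)) d <- d[d$z == z, , drop = FALSE]
  d <- d[d$weight > 0, , drop = FALSE]
  if (nrow(d) == 0L) stop("empty stratum", call. = FALSE)
  fit <- survfit(Surv(time, event) ~ 1, data = d, weights = d$weight,
                 conf.type = "none")
  structure(list(time = fit$time, surv = fit$surv,
                 n_event = fit$n.event, n = nrow(d)),
            class = "linksurv_km")
}

#' Median of a survival step function
#'
#' The smallest time at which the curve falls to 50% survival or below
#' (`min t : S(t) <= 0.5`, the boundary counting as reached). Returns `NA`
#' when the curve never gets that low — an undefined median is reported as
#' missing, never extrapolated.
#'
#' @param curve a `linksurv_km` (or any list with `time` and `surv`).
#' @return years, or `NA_real_`.
#' @export
km_median <- function(curve) {
  hit <- curve$surv <= 0.5 + 1e-12
  if (!any(hit)) return(NA_real_)
  min(curve$time[hit])
}

#' @export
print.linksurv_km <- function(x, ...) {
  med <- km_median(x)
  cat(sprintf("Weighted KM curve: %d rows, %d distinct times, median %s\n",
              x$n, length(x$time),
              if (is.na(med)) "undefined" else sprintf("%.2f yrs", med)))
  invisible(x)
}

needs_robust <- function(d) {
  any(!(d$weight %in% c(0, 1))) || anyDuplicated(d$id) > 0L
}

#' Weighted Cox proportional-hazards fit
#'
#' Partial-likelihood fit of `Surv(time, event) ~ x + z` with case weights.
#' Ties are handled by the Breslow approximation: the weighting schemes here
#' routinely split one record into fractional-weight pseudo-rows (an
#' equivocal match contributes its matched and its imputed time), and the
#' weighted Breslow likelihood is exactly invariant to such splitting while
#' Efron's equal-share correction is not. Simulated event times are
#' continuous, so the approximations coincide there anyway. A robust
#' sandwich variance clustered on the record id is used whenever any weight
#' is fractional or a record contributes more than one row, since those
#' pseudo-rows are correlated.
#'
#' @param data an `analysis_set`.
#' @param ties tie-handling method passed to [survival::coxph()]; default
#'   `"breslow"` (see above).
#' @return object of class `linksurv_cox` with `beta` (log-hazard ratios for
#'   `x` and `z`), `vcov`, `robust`, `n`, `n_event` and the underlying
#'   [survival::coxph()] fit.
#' @export
fit_cox <- function(data, ties = "breslow") {
  d <- as.data.frame(data)
  d <- d[d$weight > 0, , drop = FALSE]
  if (sum(d$event * d$weight > 0) < 2) stop("need at least 2 events",
                                            call. = FALSE)
  if (length(unique(d$x)) < 2L || length(unique(d$z)) < 2L) {
    stop("x and z must both vary", call. = FALSE)
  }
  robust <- needs_robust(d)
  fit <- withCallingHandlers(
    coxph(Surv(time, event) ~ x + z, data = d, weights = d$weight,
          ties = ties, cluster = if (robust) d$id, robust = robust),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w))) {
        stop("Cox fit failed: ", conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (any(abs(coef(fit)) > 15)) {
    stop("Cox fit diverged (monotone likelihood / separation)", call. = FALSE)
  }
  structure(list(beta = coef(fit), vcov = vcov(fit), robust = robust,
                 ties = ties, n = nrow(d),
                 n_event = sum(d$event), fit = fit),
            class = "linksurv_cox")
}

#' @export
print.linksurv_cox <- function(x, ...) {
  cat("Weighted Cox PH fit (", x$ties, " ties",
      if (x$robust) ", robust clustered variance" else "", "):\n", sep = "")
  se <- sqrt(diag(x$vcov))
  print(round(cbind(beta = x$beta, se = se[seq_along(x$beta)]), 4))
  invisible(x)
}

#' Weighted Weibull accelerated failure-time fit
#'
#' Maximum-likelihood fit of `log(t) = alpha0 + alpha1*x + alpha2*z +
#' (1/p) eps` with extreme-value `eps` (Weibull lifetimes with shape `p`),
#' case weights, and right-censored rows. `exp(alpha1)` is the event-time
#' ratio for exposure; under this model the Cox log-hazard ratio is
#' `-alpha1 * p` (see [aft_to_cox()]). Robust clustered variance under the
#' same rule as [fit_cox()].
#'
#' @param data an `analysis_set`.
#' @return object of class `linksurv_aft`: `alpha` (intercept, x, z),
#'   `shape_p`, `vcov` on the (coefficients, log scale) parameterisation,
#'   `loglik`, `n_effective` (sum of weights) and the underlying
#'   [survival::survreg()] fit.
#' @export
fit_weibull_aft <- function(data) {
  d <- as.data.frame(data)
  d <- d[d$weight > 0, , drop = FALSE]
  if (all(d$event == 0)) stop("all rows censored: no information",
                              call. = FALSE)
  robust <- needs_robust(d)
  fit <- tryCatch({
    if (robust) {
      survreg(Surv(time, event) ~ x + z + cluster(id), data = d,
              weights = d$weight, dist = "weibull", robust = TRUE)
    } else {
      survreg(Surv(time, event) ~ x + z, data = d, weights = d$weight,
              dist = "weibull")
    }
  }, warning = function(w) {
    suppressWarnings(
      if (robust) {
        survreg(Surv(time, event) ~ x + z + cluster(id), data = d,
                weights = d$weight, dist = "weibull", robust = TRUE)
      } else {
        survreg(Surv(time, event) ~ x + z, data = d, weights = d$weight,
                dist = "weibull")
      })
  })
  if (is.null(fit$coefficients) || anyNA(coef(fit))) {
    stop("Weibull AFT fit did not converge", call. = FALSE)
  }
  new_linksurv_aft(fit, n_effective = sum(d$weight))
}

# Shared wrapper for survreg fits (also used by the imputation engines).
new_linksurv_aft <- function(fit, n_effective, formula = ~ x + z) {
  alpha <- coef(fit)
  structure(list(alpha = alpha, shape_p = 1 / fit$scale,
                 scale_sigma = fit$scale, vcov = vcov(fit),
                 loglik = fit$loglik[length(fit$loglik)],
                 n_effective = n_effective, formula = formula, fit = fit),
            class = "linksurv_aft")
}

#' @export
print.linksurv_aft <- function(x, ...) {
  cat("Weibull AFT fit:\n")
  se <- sqrt(diag(x$vcov))
  print(round(cbind(alpha = x$alpha, se = se[seq_along(x$alpha)]), 4))
  cat(sprintf("shape p = %.3f (log-time error scale sigma = %.4f)\n",
              x$shape_p, x$scale_sigma))
  invisible(x)
}

#' Map a Weibull AFT exposure coefficient to the Cox log-hazard ratio
#'
#' Under Weibull lifetimes the proportional-hazards and accelerated
#' failure-time parameterisations coincide, with `beta1 = -alpha1 * p`.
#'
#' @param alpha1 log event-time ratio.
#' @param shape_p Weibull shape (> 0).
#' @return the log-hazard ratio.
#' @export
aft_to_cox <- function(alpha1, shape_p) {
  if (any(shape_p <= 0)) stop("shape_p must be > 0", call. = FALSE)
  -alpha1 * shape_p
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled point estimate is the mean of the per-imputation estimates; total
#' variance is the mean within-imputation variance plus `(1 + 1/B)` times the
#' between-imputation variance. Degrees of freedom follow the standard Rubin
#' formula. Quantities without a model-based variance (KM medians here) may
#' pass `NA` variances: the pooled interval then rests on the
#' between-imputation spread alone, which understates the total uncertainty
#' and is flagged in the result.
#'
#' @param estimates numeric vector of B point estimates.
#' @param variances numeric vector of B squared standard errors (may be all
#'   `NA`).
#' @return object of class `linksurv_mi`: `estimate`, `within`, `between`,
#'   `total`, `df`, `B`, `B_used` (imputations contributing a non-missing
#'   estimate) and `within_known`.
#' @export
rubin_pool <- function(estimates, variances) {
  if (length(estimates) < 2L) stop("Rubin's rules need B >= 2", call. = FALSE)
  if (length(estimates) != length(variances)) {
    stop("estimates and variances must have equal length", call. = FALSE)
  }
  B <- length(estimates)
  ok <- !is.na(estimates)
  est <- estimates[ok]
  B_used <- length(est)
  if (B_used < 2L) {
    return(structure(list(estimate = if (B_used == 1L) est else NA_real_,
                          within = NA_real_, between = NA_real_,
                          total = NA_real_, df = NA_real_, B = B,
                          B_used = B_used, within_known = FALSE),
                     class = "linksurv_mi"))
  }
  pooled <- mean(est)
  between <- var(est)
  within_known <- !all(is.na(variances[ok]))
  within <- if (within_known) mean(variances[ok], na.rm = TRUE) else 0
  total <- within + (1 + 1 / B_used) * between
  df <- if (between > 0) {
    (B_used - 1) * (1 + within / ((1 + 1 / B_used) * between))^2
  } else {
    Inf
  }
  structure(list(estimate = pooled, within = if (within_known) within else NA_real_,
                 between = between, total = total, df = df, B = B,
                 B_used = B_used, within_known = within_known),
            class = "linksurv_mi")
}

#' @export
print.linksurv_mi <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimate over B = %d imputations (%d used):\n",
              x$B, x$B_used))
  cat(sprintf("  estimate %.4f, total variance %s (within %s, between %s)\n",
              x$estimate,
              format(x$total, digits = 4),
              if (x$within_known) format(x$within, digits = 4)
              else "unavailable",
              format(x$between, digits = 4)))
  if (!x$within_known) {
    cat("  note: no model-based within-imputation variance; total rests on\n")
    cat("  the between-imputation spread only.\n")
  }
  invisible(x)
}
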