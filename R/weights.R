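# Analysis-set construction for the non-imputation methods: complete case,
# inverse-probability weighting of all matches, censoring nonmatches at the
# census age. Also the gold-standard (fully observed) set for simulations.

new_analysis_set <- function(id, time, event, weight, x, z, source) {
  n <- length(id)
  d <- data.frame(id = id, time = unname(rep_len(time, n)),
                  event = rep_len(event, n), weight = rep_len(weight, n),
                  x = rep_len(x, n), z = rep_len(z, n),
                  source = rep_len(source, n), stringsAsFactors = FALSE)
  if (any(d$weight < 0)) stop("negative weight in analysis set", call. = FALSE)
  if (any(d$time <= 0)) stop("non-positive time in analysis set", call. = FALSE)
  class(d) <- c("analysis_set", "data.frame")
  d
}

#' Logistic propensity model for linkage success
#'
#' Fits `r ~ x + z` by maximum-likelihood logistic regression, regardless of
#' the link that actually generated the linkage indicator (the analyst never
#' knows it). Used for the IPW weights.
#'
#' @param cohort a [linked_cohort()] containing both matched and unmatched
#'   records.
#' @return object of class `linksurv_propensity` with `coefficients`,
#'   per-record `fitted` probabilities and a `converged` flag.
#' @export
fit_propensity <- function(cohort) {
  stopifnot(inherits(cohort, "linked_cohort"))
  if (length(unique(cohort$r)) < 2L) {
    stop("all records have the same match indicator; ",
         "the propensity model is not identifiable", call. = FALSE)
  }
  fit <- glm(r ~ x + z, data = cohort, family = binomial())
  fitted <- as.numeric(fit$fitted.values)
  if (!fit$converged || any(fitted < 1e-10) || any(fitted > 1 - 1e-10)) {
    stop("propensity model did not converge cleanly (possible separation); ",
         "pool sparse covariate cells or regularize", call. = FALSE)
  }
  structure(list(coefficients = coef(fit), fitted = fitted,
                 converged = fit$converged, model = fit),
            class = "linksurv_propensity")
}

#' @export
print.linksurv_propensity <- function(x, ...) {
  cat("Linkage propensity (logistic):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("fitted P(matched) range: %.3f-%.3f\n",
              min(x$fitted), max(x$fitted)))
  invisible(x)
}

#' Build the weighted analysis set for a non-imputation method
#'
#' Implements the weighting schemes of the three non-imputation strategies:
#'
#' * `"cc"` — complete case: only matches with `p_match >= threshold`, each
#'   an event at `t_star` with weight 1.
#' * `"ipw"` — all matches, each an event at `t_star`; unequivocal matches
#'   get weight `1 / P(r = 1 | x, z)`, equivocal matches
#'   `p_match / P(r = 1 | x, z)`, with the denominator taken from the fitted
#'   propensity model.
#' * `"cens"` — unequivocal matches as events with weight 1; equivocal
#'   matches as events down-weighted to `p_match`; nonmatches right-censored
#'   at the census age `w` with weight 1.
#'
#' @param cohort a [linked_cohort()].
#' @param method `"cc"`, `"ipw"` or `"cens"`.
#' @param threshold unequivocal-match score threshold (default 0.8). Set it
#'   just below 1 to treat only perfect scores as unequivocal.
#' @param propensity a [fit_propensity()] result; required for `"ipw"`.
#' @return an `analysis_set` data.frame with columns `id, time, event,
#'   weight, x, z, source`.
#' @export
build_analysis_set <- function(cohort, method, threshold = 0.8,
                               propensity = NULL) {
  stopifnot(inherits(cohort, "linked_cohort"))
  method <- match.arg(method, c("cc", "ipw", "cens"))
  matched <- cohort$r == 1
  uneq <- matched & cohort$p_match >= threshold
  eq <- matched & cohort$p_match < threshold
  if (method == "cc") {
    s <- which(uneq)
    return(new_analysis_set(cohort$id[s], cohort$t_star[s], 1, 1,
                            cohort$x[s], cohort$z[s], "unequivocal"))
  }
  if (method == "ipw") {
    if (is.null(propensity)) {
      stop("IPW requires a fitted propensity model", call. = FALSE)
    }
    s <- which(matched)
    num <- ifelse(cohort$p_match[s] >= threshold, 1, cohort$p_match[s])
    wts <- num / propensity$fitted[s]
    src <- ifelse(cohort$p_match[s] >= threshold, "unequivocal",
                  "equivocal_matched")
    return(new_analysis_set(cohort$id[s], cohort$t_star[s], 1, wts,
                            cohort$x[s], cohort$z[s], src))
  }
  # cens: keep everyone; nonmatches censored at the census age
  s_u <- which(uneq); s_e <- which(eq); s_n <- which(!matched)
  parts <- list(
    new_analysis_set(cohort$id[s_u], cohort$t_star[s_u], 1, 1,
                     cohort$x[s_u], cohort$z[s_u], "unequivocal"),
    new_analysis_set(cohort$id[s_e], cohort$t_star[s_e], 1,
                     cohort$p_match[s_e], cohort$x[s_e], cohort$z[s_e],
                     "equivocal_matched"),
    new_analysis_set(cohort$id[s_n], cohort$w[s_n], 0, 1,
                     cohort$x[s_n], cohort$z[s_n], "censored_at_w"))
  out <- do.call(rbind, parts)
  out <- out[order(match(out$id, cohort$id)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("analysis_set", "data.frame")
  out
}

#' Fully-observed gold-standard analysis set
#'
#' Only available for simulated cohorts carrying the latent truth: deaths
#' before the analysis age `v` are observed events at `t_true`, everyone else
#' is right-censored at `v`, all with weight 1. This is the benchmark every
#' missing-data method is compared against.
#'
#' @param cohort a simulated [linked_cohort()] with `t_true`.
#' @return an `analysis_set`.
#' @export
gold_standard_set <- function(cohort) {
  stopifnot(inherits(cohort, "linked_cohort"))
  if (!"t_true" %in% names(cohort) || anyNA(cohort$t_true)) {
    stop("gold standard requires the simulated truth t_true", call. = FALSE)
  }
  event <- as.numeric(cohort$t_true < cohort$v)
  time <- ifelse(event == 1, cohort$t_true, cohort$v)
  new_analysis_set(cohort$id, time, event, 1, cohort$x, cohort$z,
                   ifelse(event == 1, "unequivocal", "censored_at_v"))
}
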