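# Multiple-imputation engines for missing event times: restricted-mean
# (MIRM) and conditional-survival (MICS). Both produce B completed weighted
# analysis sets in which an equivocal match contributes its matched time with
# weight p_match and an imputed time with weight 1 - p_match, and a nonmatch
# contributes its imputed time with weight 1.

needs_imputation <- function(cohort, threshold) {
  cohort$r == 0 | (cohort$r == 1 & cohort$p_match < threshold)
}

unequivocal_rows <- function(cohort, threshold) {
  s <- which(cohort$r == 1 & cohort$p_match >= threshold)
  new_analysis_set(cohort$id[s], cohort$t_star[s], 1, 1,
                   cohort$x[s], cohort$z[s], "unequivocal")
}

#' Weibull AFT working model on the unequivocal matches
#'
#' Fits the imputation working model for conditional-survival imputation:
#' Weibull AFT maximum likelihood on the unequivocal matches only, all
#' treated as events at their matched age.
#'
#' @param cohort a [linked_cohort()].
#' @param threshold unequivocal score threshold (default 0.8).
#' @param formula imputation covariates, default `~ x + z`; `~ x` (covariate
#'   omission) and `~ x * z` (spurious interaction) reproduce the
#'   misspecification sensitivity analysis.
#' @param min_n minimum unequivocal matches required (default 20).
#' @return a `linksurv_aft` (see [fit_weibull_aft()]).
#' @export
fit_complete_case_aft <- function(cohort, threshold = 0.8,
                                  formula = ~ x + z, min_n = 20) {
  stopifnot(inherits(cohort, "linked_cohort"))
  s <- which(cohort$r == 1 & cohort$p_match >= threshold)
  if (length(s) < min_n) {
    stop("only ", length(s), " unequivocal matches (< ", min_n,
         "): too few to fit the imputation model", call. = FALSE)
  }
  d <- data.frame(time = cohort$t_star[s], x = cohort$x[s], z = cohort$z[s])
  if (any(d$time <= 0)) {
    stop("non-positive matched event ages among unequivocal matches",
         call. = FALSE)
  }
  f <- as.formula(paste("Surv(time, rep(1, nrow(d))) ~",
                        paste(deparse(formula[[2]]), collapse = "")))
  fit <- tryCatch(survreg(f, data = d, dist = "weibull"),
                  warning = function(w) {
                    stop("Weibull AFT working model did not converge: ",
                         conditionMessage(w), call. = FALSE)
                  })
  new_linksurv_aft(fit, n_effective = length(s), formula = formula)
}

aft_linpred <- function(fit, x, z, alpha = fit$alpha) {
  mm <- model.matrix(fit$formula, data.frame(x = x, z = z))
  unname(drop(mm %*% alpha))
}

#' Invert the conditional Weibull survival distribution
#'
#' Given survival to the census age `w`, the conditional CDF of the event age
#' under the Weibull working model is
#' `F(t | w) = 1 - exp(-gamma (t^p - w^p))` with
#' `gamma = exp(-(alpha'x))^p`. Probability-integral inversion at percentile
#' `q` gives `T_imp = (w^p - log(1 - q) / gamma)^(1/p)`, which is always at
#' least `w` and increases strictly in `q`; `q = 0` returns `w` exactly.
#'
#' @param q percentile(s) in \[0, 1).
#' @param w census age(s) (> 0).
#' @param x,z covariate values.
#' @param fit a `linksurv_aft` working model.
#' @param alpha,shape_p optional parameter overrides (used for proper MI
#'   draws); default to the fitted values.
#' @return imputed event age(s), in years.
#' @export
mics_invert <- function(q, w, x, z, fit, alpha = fit$alpha,
                        shape_p = fit$shape_p) {
  if (any(q < 0 | q >= 1)) {
    stop("q must lie in [0, 1): q = 1 maps to infinite time", call. = FALSE)
  }
  if (any(w <= 0)) stop("w must be > 0", call. = FALSE)
  lin <- aft_linpred(fit, x, z, alpha = alpha)
  gamma <- exp(-shape_p * lin)
  if (any(!is.finite(gamma))) stop("non-finite Weibull scale parameter",
                                   call. = FALSE)
  (w^shape_p - log1p(-q) / gamma)^(1 / shape_p)
}

# Conditional CDF corresponding to mics_invert (exported for checking and
# for users who want the density of the imputation law).
#' Conditional Weibull CDF given survival to the census age
#'
#' @inheritParams mics_invert
#' @param t event ages at which to evaluate (each `>= w`).
#' @return `F(t | survived to w)` under the working model.
#' @export
mics_conditional_cdf <- function(t, w, x, z, fit, alpha = fit$alpha,
                                 shape_p = fit$shape_p) {
  lin <- aft_linpred(fit, x, z, alpha = alpha)
  gamma <- exp(-shape_p * lin)
  -expm1(-gamma * (t^shape_p - w^shape_p))
}

draw_aft_parameters <- function(fit) {
  theta <- c(fit$alpha, log(fit$scale_sigma))
  V <- fit$vcov
  if (nrow(V) != length(theta)) {
    stop("working-model covariance does not include the scale parameter",
         call. = FALSE)
  }
  draw <- MASS::mvrnorm(1, mu = theta, Sigma = V)
  list(alpha = draw[seq_along(fit$alpha)],
       shape_p = 1 / exp(draw[length(draw)]))
}

#' Multiple imputation by conditional survival (MICS)
#'
#' For each of `B` imputations, every record needing imputation (nonmatch,
#' or match with score below the threshold) gets a percentile
#' `q ~ Uniform(0,1)` pushed through [mics_invert()], conditioning on
#' survival to its census age `w`. Imputed ages beyond the analysis age `v`
#' are stored as censored at `v`, mimicking the gold-standard analysis;
#' earlier ones are events. With `proper = TRUE` (default) the working-model
#' parameters are redrawn per imputation from their asymptotic normal
#' distribution, so Rubin's total variance is valid; `proper = FALSE` reuses
#' the point estimates.
#'
#' @param cohort a [linked_cohort()].
#' @param threshold unequivocal score threshold (default 0.8).
#' @param B number of imputations (>= 2, default 10).
#' @param proper redraw parameters per imputation (default `TRUE`).
#' @param formula imputation covariates (default `~ x + z`).
#' @param fit optional pre-fitted working model from
#'   [fit_complete_case_aft()]; fitted internally when absent.
#' @param seed optional RNG seed.
#' @return object of class `linksurv_imputed`: `sets` (list of B
#'   `analysis_set`s), `draws` (audit trail of percentiles and parameter
#'   draws), `B`, `method`, and the working `fit`.
#' @export
mics_impute <- function(cohort, threshold = 0.8, B = 10, proper = TRUE,
                        formula = ~ x + z, fit = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "linked_cohort"))
  if (B < 2) stop("Rubin's rules need B >= 2 imputations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fit)) {
    fit <- fit_complete_case_aft(cohort, threshold = threshold,
                                 formula = formula)
  }
  base <- unequivocal_rows(cohort, threshold)
  imp_idx <- which(needs_imputation(cohort, threshold))
  sets <- vector("list", B)
  draws <- vector("list", B)
  for (b in seq_len(B)) {
    par <- if (proper) draw_aft_parameters(fit) else
      list(alpha = fit$alpha, shape_p = fit$shape_p)
    if (length(imp_idx) == 0L) {
      sets[[b]] <- base
      draws[[b]] <- list(q = numeric(0), alpha = par$alpha,
                         shape_p = par$shape_p)
      next
    }
    q <- runif(length(imp_idx))
    t_imp <- mics_invert(q, cohort$w[imp_idx], cohort$x[imp_idx],
                         cohort$z[imp_idx], fit,
                         alpha = par$alpha, shape_p = par$shape_p)
    cens <- t_imp > cohort$v[imp_idx]
    time <- ifelse(cens, cohort$v[imp_idx], t_imp)
    event <- as.numeric(!cens)
    is_eq <- cohort$r[imp_idx] == 1
    wt <- ifelse(is_eq, 1 - cohort$p_match[imp_idx], 1)
    imp_rows <- new_analysis_set(cohort$id[imp_idx], time, event, wt,
                                 cohort$x[imp_idx], cohort$z[imp_idx],
                                 ifelse(is_eq, "equivocal_imputed",
                                        "nonmatch_imputed"))
    eq_idx <- imp_idx[is_eq]
    eq_rows <- new_analysis_set(cohort$id[eq_idx], cohort$t_star[eq_idx], 1,
                                cohort$p_match[eq_idx], cohort$x[eq_idx],
                                cohort$z[eq_idx], "equivocal_matched")
    set <- rbind(base, eq_rows, imp_rows)
    rownames(set) <- NULL
    class(set) <- c("analysis_set", "data.frame")
    sets[[b]] <- set
    draws[[b]] <- list(q = q, t_imp = t_imp, alpha = par$alpha,
                       shape_p = par$shape_p)
  }
  structure(list(sets = sets, draws = draws, B = B, method = "mics",
                 threshold = threshold, fit = fit, proper = proper),
            class = "linksurv_imputed")
}

#' Restricted-mean log-survival model on the unequivocal matches
#'
#' Least-squares fit of `log(min(t_star, tau))` on the imputation covariates
#' over the unequivocal matches. `tau` is the restriction age: a ceiling
#' beyond which lifetimes are not extrapolated (people are not expected to
#' live past, say, 120). Stores the residual variance and the coefficient
#' covariance for proper multiple imputation.
#'
#' @param cohort a [linked_cohort()].
#' @param threshold unequivocal score threshold (default 0.8).
#' @param tau restriction age in years (> 0). The packaged simulation
#'   presets use 80 and 120; application-style analyses 80 and 110.
#' @param formula imputation covariates (default `~ x + z`).
#' @return object of class `linksurv_rm`: `coefficients`, `vcov`, `sigma2`
#'   (residual variance), `tau`, `formula`, `n` and the `lm` fit.
#' @export
fit_restricted_mean <- function(cohort, threshold = 0.8, tau = 120,
                                formula = ~ x + z) {
  stopifnot(inherits(cohort, "linked_cohort"))
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  s <- which(cohort$r == 1 & cohort$p_match >= threshold)
  if (length(s) == 0L) stop("no unequivocal matches", call. = FALSE)
  d <- data.frame(y = log(pmin(cohort$t_star[s], tau)),
                  x = cohort$x[s], z = cohort$z[s])
  f <- as.formula(paste("y ~", paste(deparse(formula[[2]]), collapse = "")))
  fit <- lm(f, data = d)
  rdf <- fit$df.residual
  sigma2 <- if (rdf > 0) sum(fit$residuals^2) / rdf else 0
  # a zero-residual fit is a legitimate degenerate input; vcov is then 0
  V <- if (rdf > 0 && sigma2 > 0) suppressWarnings(vcov(fit)) else
    matrix(0, length(coef(fit)), length(coef(fit)))
  structure(list(coefficients = coef(fit), vcov = V, sigma2 = sigma2,
                 tau = tau, formula = formula, n = length(s), fit = fit),
            class = "linksurv_rm")
}

#' Multiple imputation from the restricted mean (MIRM)
#'
#' Per imputation, model coefficients are drawn from their sampling normal
#' distribution, predicted log restricted lifetimes are formed for every
#' record needing imputation, and log-times are drawn around them with the
#' residual variance. The exponentiated draws are capped at `tau` and, by
#' default, right-censored at the analysis age `v` when they exceed it.
#' Weights follow the same scheme as [mics_impute()].
#'
#' @param cohort a [linked_cohort()].
#' @param fit a [fit_restricted_mean()] result.
#' @param B number of imputations (>= 2, default 10).
#' @param threshold unequivocal score threshold (default 0.8).
#' @param censor_at_v right-censor imputed ages beyond `v` (default `TRUE`).
#' @param seed optional RNG seed.
#' @return a `linksurv_imputed` (see [mics_impute()]).
#' @export
mirm_impute <- function(cohort, fit, B = 10, threshold = 0.8,
                        censor_at_v = TRUE, seed = NULL) {
  stopifnot(inherits(cohort, "linked_cohort"), inherits(fit, "linksurv_rm"))
  if (B < 2) stop("Rubin's rules need B >= 2 imputations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  base <- unequivocal_rows(cohort, threshold)
  imp_idx <- which(needs_imputation(cohort, threshold))
  mm <- model.matrix(fit$formula,
                     data.frame(x = cohort$x[imp_idx],
                                z = cohort$z[imp_idx]))
  sets <- vector("list", B)
  draws <- vector("list", B)
  for (b in seq_len(B)) {
    beta_b <- if (all(fit$vcov == 0)) fit$coefficients else
      drop(MASS::mvrnorm(1, mu = fit$coefficients, Sigma = fit$vcov))
    if (length(imp_idx) == 0L) {
      sets[[b]] <- base
      draws[[b]] <- list(beta = beta_b, log_t = numeric(0))
      next
    }
    mu <- unname(drop(mm %*% beta_b))
    log_t <- if (fit$sigma2 > 0) rnorm(length(mu), mu, sqrt(fit$sigma2))
             else mu
    t_imp <- pmin(exp(log_t), fit$tau)
    cens <- censor_at_v & t_imp > cohort$v[imp_idx]
    time <- ifelse(cens, cohort$v[imp_idx], t_imp)
    event <- as.numeric(!cens)
    is_eq <- cohort$r[imp_idx] == 1
    wt <- ifelse(is_eq, 1 - cohort$p_match[imp_idx], 1)
    imp_rows <- new_analysis_set(cohort$id[imp_idx], time, event, wt,
                                 cohort$x[imp_idx], cohort$z[imp_idx],
                                 ifelse(is_eq, "equivocal_imputed",
                                        "nonmatch_imputed"))
    eq_idx <- imp_idx[is_eq]
    eq_rows <- new_analysis_set(cohort$id[eq_idx], cohort$t_star[eq_idx], 1,
                                cohort$p_match[eq_idx], cohort$x[eq_idx],
                                cohort$z[eq_idx], "equivocal_matched")
    set <- rbind(base, eq_rows, imp_rows)
    rownames(set) <- NULL
    class(set) <- c("analysis_set", "data.frame")
    sets[[b]] <- set
    draws[[b]] <- list(beta = beta_b, log_t = log_t, t_imp = t_imp)
  }
  structure(list(sets = sets, draws = draws, B = B, method = "mirm",
                 threshold = threshold, fit = fit, tau = fit$tau),
            class = "linksurv_imputed")
}

#' @export
print.linksurv_imputed <- function(x, ...) {
  cat(sprintf("%s multiple imputation: B = %d completed sets\n",
              toupper(x$method), x$B))
  s1 <- x$sets[[1]]
  cat(sprintf("  rows per set: %d (%d unequivocal, %d equivocal pairs, %d nonmatch)\n",
              nrow(s1), sum(s1$source == "unequivocal"),
              sum(s1$source == "equivocal_matched"),
              sum(s1$source == "nonmatch_imputed")))
  invisible(x)
}
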