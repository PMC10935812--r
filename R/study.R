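# Monte Carlo study harness: repeated cohorts under one scenario, every
# requested method on each cohort, bias against the same-replicate gold
# standard, empirical and mean model-based SEs.

STUDY_METHODS <- c("gold", "cc", "ipw", "cens", "mirm", "mics")

method_seed <- function(base_seed, k, arm) {
  # deterministic per (replicate, arm), independent of which arms run
  (base_seed + k) %% 100000L * 10000L + 100L * arm
}

#' Run a Monte Carlo study of the missing-data methods
#'
#' Draws `K` cohorts from a scenario (replicate `k` uses seed
#' `base_seed + k`), analyses each with the fully-observed gold standard and
#' every requested method, and summarises per (method, parameter): the mean
#' bias against the same-replicate gold-standard estimate, the empirical SE
#' across replicates, and the mean model-based SE. Method arms are re-seeded
#' deterministically per replicate so results do not depend on which other
#' arms run. A replicate on which a method fails is logged and excluded for
#' that method; more than `max_failure_rate` failures for any method is a
#' hard error.
#'
#' @param spec a [scenario_spec()].
#' @param methods subset of `c("cc", "ipw", "cens", "mirm", "mics")`.
#' @param K number of replicates.
#' @param base_seed integer seed base.
#' @param B,tau,threshold,proper,imputation_formula method options as in
#'   [linksurv()].
#' @param max_failure_rate hard-error threshold on per-method failures
#'   (default 0.2).
#' @return object of class `linksurv_study`: `summary` (data.frame of
#'   method, parameter, bias, empirical_se, mean_model_se, K_completed,
#'   failures), `estimates` (list of per-method K x parameter matrices),
#'   `spec`, `K`, `base_seed`.
#' @export
run_study <- function(spec, methods = c("cc", "ipw", "cens", "mirm", "mics"),
                      K = 500, base_seed = 1, B = 10, tau = 120,
                      threshold = spec$unequivocal_threshold, proper = TRUE,
                      imputation_formula = ~ x + z,
                      max_failure_rate = 0.2) {
  stopifnot(inherits(spec, "scenario_spec"), K >= 1)
  if (length(methods) > 0L) {
    methods <- match.arg(methods, STUDY_METHODS[-1], several.ok = TRUE)
  }
  arms <- c("gold", methods)
  est <- lapply(arms, function(a)
    matrix(NA_real_, K, length(PARAMETERS),
           dimnames = list(NULL, PARAMETERS)))
  mse <- est  # model-based SEs, same shape
  names(est) <- names(mse) <- arms
  failures <- setNames(integer(length(arms)), arms)
  for (k in seq_len(K)) {
    cohort <- draw_cohort(spec, seed = base_seed + k)
    for (a in arms) {
      res <- tryCatch({
        set.seed(method_seed(base_seed, k, match(a, STUDY_METHODS)))
        fit <- linksurv(cohort, method = a, threshold = threshold, B = B,
                        tau = tau, proper = proper,
                        imputation_formula = imputation_formula)
        fit$estimates
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[a] <- failures[a] + 1L
      } else {
        est[[a]][k, res$parameter] <- res$estimate
        mse[[a]][k, res$parameter] <- res$se
      }
    }
  }
  if (any(failures > max_failure_rate * K)) {
    bad <- names(failures)[failures > max_failure_rate * K]
    stop("method(s) failed on more than ", 100 * max_failure_rate,
         "% of replicates: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (a in arms) {
    for (p in PARAMETERS) {
      diff <- est[[a]][, p] - est[["gold"]][, p]
      rows[[length(rows) + 1L]] <- data.frame(
        method = a, parameter = p,
        bias = mean(diff, na.rm = TRUE),
        mean_estimate = mean(est[[a]][, p], na.rm = TRUE),
        empirical_se = sd(est[[a]][, p], na.rm = TRUE),
        mean_model_se = mean(mse[[a]][, p], na.rm = TRUE),
        K_completed = sum(!is.na(est[[a]][, p])),
        failures = unname(failures[a]), stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, rows), estimates = est,
                 model_se = mse, spec = spec, K = K, base_seed = base_seed,
                 methods = arms, failures = failures),
            class = "linksurv_study")
}

#' Sensitivity of the imputation methods to model misspecification
#'
#' Reruns the study with the imputation model deliberately misspecified
#' while the analysis model stays `~ x + z`: the correct `~ x + z`, covariate
#' omission `~ x`, and a spurious interaction `~ x * z`.
#'
#' @param spec a [scenario_spec()].
#' @param imputation_formulas named list of formulas (default the three
#'   above).
#' @param methods imputation methods to refit (default `c("mirm", "mics")`).
#' @param ... passed to [run_study()] (`K`, `base_seed`, `B`, `tau`, ...).
#' @return object of class `linksurv_sensitivity`: `summary` with an extra
#'   `imputation_formula` column, and the per-formula `linksurv_study`
#'   objects in `studies`.
#' @export
run_sensitivity <- function(spec,
                            imputation_formulas = list(correct = ~ x + z,
                                                       omit_z = ~ x,
                                                       interaction = ~ x * z),
                            methods = c("mirm", "mics"), ...) {
  studies <- lapply(imputation_formulas, function(f) {
    run_study(spec, methods = methods, imputation_formula = f, ...)
  })
  tabs <- Map(function(s, nm) {
    out <- s$summary
    out$imputation_formula <- nm
    out
  }, studies, names(imputation_formulas))
  structure(list(summary = do.call(rbind, tabs), studies = studies,
                 spec = spec),
            class = "linksurv_sensitivity")
}

#' @export
print.linksurv_study <- function(x, ...) {
  cat(sprintf("Monte Carlo study: %s, K = %d replicates of n = %d\n",
              if (!is.null(x$spec$label)) x$spec$label else "scenario",
              x$K, x$spec$n))
  key <- x$summary[x$summary$parameter %in% c("beta1", "alpha1", "m0", "m1"), ]
  key$bias <- round(key$bias, 4)
  key$empirical_se <- round(key$empirical_se, 4)
  key$mean_model_se <- round(key$mean_model_se, 4)
  print(key[, c("method", "parameter", "bias", "empirical_se",
                "mean_model_se", "K_completed")], row.names = FALSE)
  if (any(x$failures > 0)) {
    cat("failures:", paste(sprintf("%s=%d", names(x$failures), x$failures)
                           [x$failures > 0], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.linksurv_sensitivity <- function(x, ...) {
  cat("Imputation-model sensitivity analysis\n")
  key <- x$summary[x$summary$parameter %in% c("beta1", "alpha1", "m1"), ]
  key$bias <- round(key$bias, 4)
  print(key[, c("imputation_formula", "method", "parameter", "bias",
                "K_completed")], row.names = FALSE)
  invisible(x)
}

#' Bias dot plot for a study
#'
#' One panel per parameter: mean bias of each method against the gold
#' standard, with +/- 1 empirical SE whiskers.
#'
#' @param x a `linksurv_study`.
#' @param parameters which parameters to show.
#' @param ... ignored.
#' @export
plot.linksurv_study <- function(x, parameters = c("beta1", "alpha1",
                                                  "m0", "m1"), ...) {
  tab <- x$summary[x$summary$parameter %in% parameters &
                     x$summary$method != "gold", ]
  old <- graphics::par(mfrow = c(1, length(parameters)), mar = c(4, 6, 2, 1))
  on.exit(graphics::par(old))
  for (p in parameters) {
    d <- tab[tab$parameter == p, ]
    graphics::plot(d$bias, seq_len(nrow(d)), yaxt = "n", pch = 19,
                   xlab = "bias vs gold standard", ylab = "", main = p,
                   xlim = range(c(0, d$bias - d$empirical_se,
                                  d$bias + d$empirical_se), na.rm = TRUE))
    graphics::segments(d$bias - d$empirical_se, seq_len(nrow(d)),
                       d$bias + d$empirical_se, seq_len(nrow(d)))
    graphics::abline(v = 0, lty = 3)
    graphics::axis(2, at = seq_len(nrow(d)), labels = d$method, las = 1)
  }
  invisible(x)
}
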