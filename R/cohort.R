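# Linked-cohort container, validation and delimited-text I/O.

COHORT_COLUMNS <- c("id", "x", "z", "w", "v", "r", "p_match", "t_star")
COHORT_SIM_COLUMNS <- c("t_true", "delta_true")

#' Construct and validate a linked cohort
#'
#' A linked cohort holds one row per census record: a binary exposure `x`, a
#' binary covariate `z`, the age at census `w` (years since birth), the age at
#' the analysis date `v`, a match indicator `r` (1 = a vital record was
#' linked), the probabilistic match score `p_match` (0 when unmatched), and
#' the matched event age `t_star` (present iff `r = 1`). Simulated cohorts
#' additionally carry the latent truth `t_true` and `delta_true = I(t_true <
#' v)`.
#'
#' Validation enforces: `w > 0` and `v > w` for every record; `r = 0` implies
#' `p_match = 0` and `t_star` missing; `r = 1` implies `p_match` in (0, 1]
#' and `t_star` present; and, when the latent truth is carried, `r = 1`
#' implies `delta_true = 1` (no one alive at the analysis date is matched).
#' A matched event age below the census age is logically suspect but can
#' arise from score-dependent measurement error in the linkage, so it is
#' flagged with a message rather than rejected; downstream methods decide how
#' to treat it.
#'
#' @param data data.frame with the columns named above (simulation columns
#'   optional).
#' @param followup expected constant `v - w` in years, or `NULL` to skip the
#'   constancy check. A non-constant follow-up raises a warning, not an
#'   error.
#' @return `data` with class `linked_cohort`, invisibly checked.
#' @seealso [read_cohort()], [write_cohort()], [validate_cohort()]
#' @export
linked_cohort <- function(data, followup = NULL) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(COHORT_COLUMNS, names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)
  for (col in intersect(c("x", "z", "w", "v", "r", "p_match", "t_star",
                          COHORT_SIM_COLUMNS), names(data))) {
    data[[col]] <- as.numeric(data[[col]])
  }
  report <- validate_cohort(data)
  if (nrow(report) > 0L) {
    bad <- report[!report$warning_only, , drop = FALSE]
    if (nrow(bad) > 0L) {
      msg <- paste(sprintf("row id=%s: %s", bad$id, bad$problem),
                   collapse = "\n  ")
      stop("invalid cohort (", nrow(bad), " violation(s)):\n  ", msg,
           call. = FALSE)
    }
    flagged <- report[report$warning_only, , drop = FALSE]
    message(nrow(flagged),
            " record(s) have t_star below the census age w ",
            "(possible linkage measurement error); kept as-is.")
  }
  if (!is.null(followup) && nrow(data) > 0L) {
    if (any(abs(data$v - data$w - followup) > 1e-8)) {
      warning("follow-up v - w is not constant at ", followup, " years",
              call. = FALSE)
    }
  }
  class(data) <- c("linked_cohort", "data.frame")
  data
}

#' Per-row validation report for a cohort table
#'
#' @param data data.frame with linked-cohort columns.
#' @return data.frame with columns `id`, `problem`, `warning_only` (logical);
#'   zero rows when every record satisfies every invariant.
#' @export
validate_cohort <- function(data) {
  probs <- list()
  flag <- function(sel, problem, warning_only = FALSE) {
    sel[is.na(sel)] <- FALSE
    if (any(sel)) {
      probs[[length(probs) + 1L]] <<- data.frame(
        id = as.character(data$id[sel]), problem = problem,
        warning_only = warning_only, stringsAsFactors = FALSE)
    }
  }
  flag(!(data$x %in% c(0, 1)), "x must be 0/1")
  flag(!(data$z %in% c(0, 1)), "z must be 0/1")
  flag(!(data$r %in% c(0, 1)), "r must be 0/1")
  flag(is.na(data$w) | data$w <= 0, "w must be > 0")
  flag(is.na(data$v) | data$v <= data$w, "v must exceed w")
  flag(is.na(data$p_match) | data$p_match < 0 | data$p_match > 1,
       "p_match must lie in [0,1]")
  flag(data$r == 0 & data$p_match != 0, "r = 0 requires p_match = 0")
  flag(data$r == 0 & !is.na(data$t_star), "r = 0 requires t_star absent")
  flag(data$r == 1 & (is.na(data$p_match) | data$p_match <= 0),
       "r = 1 requires p_match in (0,1]")
  flag(data$r == 1 & is.na(data$t_star), "r = 1 requires t_star present")
  if (all(COHORT_SIM_COLUMNS %in% names(data))) {
    flag(data$r == 1 & data$delta_true != 1,
         "matched record must have delta_true = 1")
    flag(!is.na(data$t_true) & !is.na(data$delta_true) &
           (data$delta_true != as.numeric(data$t_true < data$v)),
         "delta_true must equal I(t_true < v)")
  }
  flag(data$r == 1 & !is.na(data$t_star) & data$t_star < data$w,
       "t_star below census age w", warning_only = TRUE)
  if (length(probs) == 0L) {
    return(data.frame(id = character(), problem = character(),
                      warning_only = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, probs)
}

#' Read a linked cohort from delimited text
#'
#' Expects a UTF-8 CSV with one header row, "." as the decimal separator and
#' the canonical lower-case column names (`id,x,z,w,v,r,p_match,t_star`, plus
#' `t_true,delta_true` for simulated cohorts). Files with other column names
#' are handled through `dialect`, a named character vector mapping canonical
#' names to the names used in the file.
#'
#' @param path file to read.
#' @param dialect optional named character vector, e.g.
#'   `c(p_match = "score", t_star = "death_age")`.
#' @param followup expected constant `v - w`, or `NULL` (default) to accept
#'   any positive follow-up.
#' @return a [linked_cohort()].
#' @export
read_cohort <- function(path, dialect = NULL, followup = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    for (canonical in names(dialect)) {
      file_col <- dialect[[canonical]]
      if (!file_col %in% names(raw)) {
        stop("dialect maps '", canonical, "' to missing column '",
             file_col, "'", call. = FALSE)
      }
      names(raw)[names(raw) == file_col] <- canonical
    }
  }
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  linked_cohort(raw, followup = followup)
}

# Shortest decimal string that parses back to the same double; falls back to
# 17 significant digits where the short form is lossy.
format_roundtrip <- function(x) {
  s <- as.character(x)
  needs <- !is.na(x) & (is.na(suppressWarnings(as.numeric(s))) |
                          suppressWarnings(as.numeric(s)) != x)
  s[needs] <- sprintf("%.17g", x[needs])
  s[is.na(x)] <- NA_character_
  s
}

#' Write a linked cohort to delimited text
#'
#' Numeric columns are written with enough digits that
#' `read_cohort(write_cohort(cohort))` reproduces every value exactly; the
#' output is byte-stable for identical input. An empty cohort produces a
#' header-only file.
#'
#' @param cohort a [linked_cohort()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "linked_cohort"))
  out <- as.data.frame(cohort)
  cols <- intersect(c(COHORT_COLUMNS, COHORT_SIM_COLUMNS), names(out))
  out <- out[, cols, drop = FALSE]
  for (col in setdiff(cols, "id")) {
    out[[col]] <- format_roundtrip(out[[col]])
  }
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' @export
print.linked_cohort <- function(x, ...) {
  n <- nrow(x)
  cat("Linked cohort:", n, "records\n")
  if (n > 0L) {
    cat(sprintf("  matched: %d (%.1f%%), unequivocal scores > 0.8: %d\n",
                sum(x$r == 1), 100 * mean(x$r == 1),
                sum(x$r == 1 & x$p_match > 0.8)))
    cat(sprintf("  census age w: %.1f-%.1f yrs; follow-up v - w: %.1f-%.1f yrs\n",
                min(x$w), max(x$w), min(x$v - x$w), max(x$v - x$w)))
    if (all(COHORT_SIM_COLUMNS %in% names(x))) {
      cat(sprintf("  simulated truth present; event rate before v: %.1f%%\n",
                  100 * mean(x$delta_true)))
    }
  }
  invisible(x)
}
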