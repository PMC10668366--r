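#' Sufficient statistics of a two-group study
#'
#' Collects the data for a two-group comparison in one of three modes:
#' raw outcome vectors (`x`, `y`), per-group summary statistics
#' (`n_x`, `n_y`, `mean_x`, `mean_y`, `sd_x`, `sd_y`), or group means
#' plus a confidence interval for the mean difference (`n_x`, `n_y`,
#' `mean_x`, `mean_y`, `ci_margin`, `ci_level`). Throughout the package,
#' names with an `x` refer to the control condition and names with a `y`
#' to the experimental condition.
#'
#' @param x,y Raw outcome vectors for the control and experimental
#'   groups (one observation per element; all values must be finite).
#' @param n_x,n_y Group sample sizes (each at least 2).
#' @param mean_x,mean_y Sample means.
#' @param sd_x,sd_y Sample standard deviations (computed with the
#'   \eqn{n - 1} denominator).
#' @param ci_margin Half-width of the confidence interval for the mean
#'   difference (experimental minus control), in outcome units.
#' @param ci_level Confidence level of that interval, as a fraction in
#'   (0, 1), e.g. `0.95`.
#'
#' @return An object of class `"study_summary"` with elements `n_x`,
#'   `n_y`, `mean_x`, `mean_y`, and (depending on mode) `sd_x`/`sd_y` or
#'   `ci_margin`/`ci_level`, plus `mode` (one of `"raw"`, `"means_sds"`,
#'   `"means_ci"`).
#'
#' @examples
#' study_summary(x = c(1, 2, 3), y = c(2, 3, 4))
#' study_summary(n_x = 193, n_y = 205, mean_x = 4.7, mean_y = 4.8,
#'               ci_margin = 0.19, ci_level = 0.95)
#' @export
study_summary <- function(x = NULL, y = NULL,
                          n_x = NULL, n_y = NULL,
                          mean_x = NULL, mean_y = NULL,
                          sd_x = NULL, sd_y = NULL,
                          ci_margin = NULL, ci_level = NULL) {
  raw_given <- !is.null(x) || !is.null(y)
  sds_given <- !is.null(sd_x) || !is.null(sd_y)
  ci_given <- !is.null(ci_margin) || !is.null(ci_level)

  if (raw_given) {
    if (sds_given || ci_given || !is.null(n_x) || !is.null(n_y) ||
        !is.null(mean_x) || !is.null(mean_y)) {
      stop_invalid("supply either raw data (x, y) or summary statistics, ",
                   "not both")
    }
    return(.summarize_raw(x, y))
  }
  if (sds_given && ci_given) {
    stop_invalid("supply either standard deviations (sd_x, sd_y) or a ",
                 "confidence interval (ci_margin, ci_level), not both")
  }
  if (!sds_given && !ci_given) {
    stop_invalid("no data supplied: give raw vectors (x, y), standard ",
                 "deviations (sd_x, sd_y), or a confidence interval ",
                 "(ci_margin, ci_level)")
  }
  for (nm in c("n_x", "n_y", "mean_x", "mean_y")) {
    v <- get(nm)
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_invalid("'", nm, "' must be a single finite number")
    }
  }
  .check_n(n_x, "n_x")
  .check_n(n_y, "n_y")

  if (sds_given) {
    for (nm in c("sd_x", "sd_y")) {
      v <- get(nm)
      if (is.null(v) || !is.numeric(v) || length(v) != 1L ||
          !is.finite(v) || v < 0) {
        stop_invalid("'", nm, "' must be a single nonnegative number")
      }
    }
    out <- list(n_x = n_x, n_y = n_y, mean_x = mean_x, mean_y = mean_y,
                sd_x = sd_x, sd_y = sd_y, mode = "means_sds")
  } else {
    if (is.null(ci_margin) || !is.numeric(ci_margin) ||
        length(ci_margin) != 1L || !is.finite(ci_margin) || ci_margin <= 0) {
      stop_invalid("'ci_margin' must be a single positive number")
    }
    if (is.null(ci_level) || !is.numeric(ci_level) ||
        length(ci_level) != 1L || !is.finite(ci_level) ||
        ci_level <= 0 || ci_level >= 1) {
      hint <- if (is.numeric(ci_level) && length(ci_level) == 1L &&
                  is.finite(ci_level) && ci_level > 1 && ci_level <= 100) {
        paste0(" (give the level as a fraction, e.g. ", ci_level / 100,
               " rather than ", ci_level, ")")
      } else {
        ""
      }
      stop_invalid("'ci_level' must lie strictly between 0 and 1", hint)
    }
    out <- list(n_x = n_x, n_y = n_y, mean_x = mean_x, mean_y = mean_y,
                ci_margin = ci_margin, ci_level = ci_level,
                mode = "means_ci")
  }
  structure(out, class = "study_summary")
}

.check_n <- function(n, nm) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) ||
      n != round(n) || n < 2) {
    stop_invalid("'", nm, "' must be an integer sample size of at least 2")
  }
}

# raw vectors -> moments (sample sd, n - 1 denominator)
.summarize_raw <- function(x, y) {
  for (nm in c("x", "y")) {
    v <- get(nm)
    if (is.null(v) || !is.numeric(v)) {
      stop_invalid("'", nm, "' must be a numeric vector")
    }
    if (length(v) < 2L) {
      stop_invalid("group '", nm, "' needs at least 2 observations")
    }
    if (any(!is.finite(v))) {
      stop_invalid("group '", nm, "' contains non-finite values")
    }
  }
  sd_x <- stats::sd(x)
  sd_y <- stats::sd(y)
  if (sd_x == 0 && sd_y == 0) {
    stop_invalid("both groups have zero variance")
  }
  structure(
    list(n_x = length(x), n_y = length(y),
         mean_x = mean(x), mean_y = mean(y),
         sd_x = sd_x, sd_y = sd_y,
         x = as.numeric(x), y = as.numeric(y), mode = "raw"),
    class = "study_summary"
  )
}

#' Read a single-column outcome file
#'
#' Reads one numeric value per line from a plain-text or single-column
#' CSV file. Blank lines are ignored; a single leading non-numeric line
#' is treated as a header; any other non-numeric content is an error
#' (values are never silently skipped or coerced).
#'
#' @param path Path to the file.
#' @return A numeric vector of outcomes.
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_invalid("file is empty: ", path)
  vals <- suppressWarnings(as.numeric(lines))
  if (is.na(vals[1L]) && length(lines) > 1L &&
      !anyNA(vals[-1L])) {
    # single header line
    return(vals[-1L])
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop_invalid("non-numeric value on line ", bad, " of ", path, ": '",
                 lines[bad], "'")
  }
  vals
}

#' Canonicalize a study to the high-favorable orientation
#'
#' Internally the package always works in coordinates where a larger
#' standardized effect is more favorable. When low scores on the outcome
#' are the favorable ones (`direction = "low"`), the group means (and raw
#' values, if present) are negated, which negates the mean difference;
#' after that, `direction` is `"high"` by construction. Applying the
#' function twice is the same as applying it once.
#'
#' @param summary A [study_summary()] object.
#' @param direction `"high"` if high outcome scores are favorable,
#'   `"low"` otherwise.
#' @return The canonicalized `study_summary` (with an attribute
#'   `canonical = TRUE`).
#' @export
canonicalize <- function(summary, direction = c("high", "low")) {
  direction <- match.arg(direction)
  stopifnot(inherits(summary, "study_summary"))
  if (direction == "low") {
    summary$mean_x <- -summary$mean_x
    summary$mean_y <- -summary$mean_y
    if (!is.null(summary$x)) {
      summary$x <- -summary$x
      summary$y <- -summary$y
    }
  }
  attr(summary, "canonical") <- TRUE
  summary
}

# Expand the user-facing equivalence interval argument: a single
# nonnegative value v becomes (-v, v); a pair is taken verbatim;
# 0 (or c(0, 0)) is the point null.
.expand_interval <- function(interval) {
  if (!is.numeric(interval) || anyNA(interval) || any(!is.finite(interval))) {
    stop_invalid("'interval' must be numeric and finite")
  }
  if (length(interval) == 1L) {
    if (interval < 0) {
      stop_invalid("a single 'interval' value must be nonnegative")
    }
    c(-interval, interval)
  } else if (length(interval) == 2L) {
    if (interval[1L] > interval[2L]) {
      stop_invalid("interval bounds are inverted: lower > upper")
    }
    as.numeric(interval)
  } else {
    stop_invalid("'interval' must have length 1 or 2")
  }
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Two-group study summary (mode: ", x$mode, ")\n", sep = "")
  cat(sprintf("  control (x):      n = %d, mean = %g", x$n_x, x$mean_x))
  if (!is.null(x$sd_x)) cat(sprintf(", sd = %g", x$sd_x))
  cat("\n")
  cat(sprintf("  experimental (y): n = %d, mean = %g", x$n_y, x$mean_y))
  if (!is.null(x$sd_y)) cat(sprintf(", sd = %g", x$sd_y))
  cat("\n")
  if (!is.null(x$ci_margin)) {
    cat(sprintf("  CI for difference: half-width %g at level %g\n",
                x$ci_margin, x$ci_level))
  }
  invisible(x)
}
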