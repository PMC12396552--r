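# Visual-acuity handling and the univariate structure-function regressions:
# integrity indices or areas against BCVA/LLVA, cross-sectional and
# change-on-change.

#' Convert ETDRS letter score to logMAR
#'
#' Standard chart conversion, anchored at 85 letters = 0.0 logMAR:
#' logMAR = -0.02 x letters + 1.7. Strictly decreasing (more letters,
#' better acuity, lower logMAR).
#'
#' @param letters ETDRS letter score(s) in [0, 100].
#' @return logMAR value(s).
#' @examples
#' letters_to_logmar(85)  # 0
#' letters_to_logmar(35)  # 1
#' @export
letters_to_logmar <- function(letters) {
  if (any(!is.finite(letters)) || any(letters < 0 | letters > 100))
    stop("letters must lie in [0, 100]", call. = FALSE)
  -0.02 * letters + 1.7
}

#' Convert logMAR to ETDRS letter score
#'
#' Inverse of [letters_to_logmar()]; the result is clipped to [0, 100].
#'
#' @param logmar logMAR value(s).
#' @return Letter score(s) in [0, 100] (possibly fractional).
#' @export
logmar_to_letters <- function(logmar) {
  pmin(100, pmax(0, (1.7 - logmar) / 0.02))
}

#' Univariate ordinary-least-squares regression
#'
#' Fits y = a + b x by OLS and reports the slope, intercept, coefficient of
#' determination and the two-sided p-value of the slope (t-test with n - 2
#' degrees of freedom).
#'
#' @param x Predictor values (not constant).
#' @param y Outcome values, same length as `x` (n >= 3).
#' @return An object of class `regression_result` with fields `slope`,
#'   `intercept`, `slope_se`, `r_squared`, `p_value`, `n`. A constant
#'   outcome gives slope 0, `r_squared` 0 and `p_value` 1.
#' @export
fit_univariate <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("predictor is constant", call. = FALSE)
  if (stats::sd(y) == 0) {
    return(structure(
      list(slope = 0, intercept = y[1], slope_se = 0, r_squared = 0,
           p_value = 1, n = n),
      class = "regression_result"
    ))
  }
  fit <- stats::lm(y ~ x)
  # a perfect fit is legitimate here (noiseless generators); summary.lm
  # warns about it, which is noise for this use
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  structure(
    list(
      slope = unname(co["x", "Estimate"]),
      intercept = unname(co["(Intercept)", "Estimate"]),
      slope_se = unname(co["x", "Std. Error"]),
      r_squared = sm$r.squared,
      p_value = unname(co["x", "Pr(>|t|)"]),
      n = n
    ),
    class = "regression_result"
  )
}

#' Mean and sample SD summary
#'
#' Continuous cohort variables are summarized as mean +/- SD (n - 1
#' denominator; SD is 0 for a single observation).
#'
#' @param values Numeric vector (non-empty).
#' @param variable Optional name carried in the output.
#' @return An object of class `cohort_summary` with fields `variable`,
#'   `mean`, `sd`, `n`.
#' @export
summarize_values <- function(values, variable = "value") {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) stop("no observations to summarize", call. = FALSE)
  structure(
    list(variable = variable, mean = mean(values),
         sd = if (n == 1L) 0 else stats::sd(values), n = n),
    class = "cohort_summary"
  )
}

#' Panel of univariate structure-function regressions
#'
#' Regresses each outcome column on each predictor column of a merged
#' per-eye table, one OLS fit per pair. Outcomes are typically BCVA/LLVA in
#' logMAR; predictors the integrity indices (percent) or GA areas (mm^2),
#' cross-sectional or change-on-change. Significance is flagged at
#' `alpha` with no multiple-testing correction (a Holm-adjusted column is
#' included for reference).
#'
#' @param table Data.frame with the predictor and outcome columns.
#' @param predictors Character vector of predictor column names.
#' @param outcomes Character vector of outcome column names.
#' @param alpha Significance threshold (default 0.05).
#' @return A data.frame with one row per predictor-outcome pair: `predictor`,
#'   `outcome`, `slope`, `intercept`, `r_squared`, `p_value`, `n`,
#'   `significant`, `p_holm`.
#' @export
regression_panel <- function(table, predictors, outcomes, alpha = 0.05) {
  missing <- setdiff(c(predictors, outcomes), names(table))
  if (length(missing))
    stop("table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- list()
  for (p in predictors) {
    for (o in outcomes) {
      r <- fit_univariate(table[[p]], table[[o]])
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = p, outcome = o, slope = r$slope, intercept = r$intercept,
        r_squared = r$r_squared, p_value = r$p_value, n = r$n
      )
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: slope %.4g, intercept %.4g, R^2 = %.3f, P = %.4g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%s: %.3g +/- %.3g (n = %d)\n", x$variable, x$mean, x$sd, x$n))
  invisible(x)
}
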