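#' Seasonal adjustment by classical additive decomposition
#'
#' Removes a fixed period-`period` seasonal component estimated by the
#' classical moving-average decomposition ([stats::decompose()]): a centered
#' moving-average trend, month-mean seasonal factors centered to sum to zero
#' over a period, subtracted additively. This is a deliberately simple,
#' closed-form-testable stand-in for ARIMA-model-based seasonal extraction.
#'
#' @param series Numeric monthly series, length >= `2 * period`.
#' @param period Seasonal period (default 12).
#' @return Adjusted series of the same length.
#' @export
seasonal_adjust <- function(series, period = 12L) {
  if (length(series) < 2L * period)
    stop("series must cover at least two periods", call. = FALSE)
  if (any(!is.finite(series))) stop("series must be finite", call. = FALSE)
  dec <- stats::decompose(stats::ts(series, frequency = period),
                          type = "additive")
  as.numeric(series - dec$seasonal)
}

#' Remove the ordinary least-squares linear trend
#'
#' Subtracts the OLS line fit on the time index `1..length(series)`;
#' residuals have zero mean and are uncorrelated with the index.
#'
#' @param series Numeric series, length >= 3.
#' @return Residual series.
#' @export
detrend_linear <- function(series) {
  if (length(series) < 3L) stop("series too short to detrend", call. = FALSE)
  t_idx <- seq_along(series)
  as.numeric(stats::lm.fit(cbind(1, t_idx), series)$residuals)
}

#' Augmented Dickey-Fuller stationarity check
#'
#' ADF regression with a constant (no trend term):
#' `diff(y)_t = a + g * y_{t-1} + sum_i b_i diff(y)_{t-i} + e_t`, with the
#' lag order `0..max_lag` selected by AIC. The unit-root null is rejected at
#' the 5% level against MacKinnon (2010) response-surface critical values
#' for the constant-only case.
#'
#' @param series Numeric series, length > `max_lag + 10`.
#' @param max_lag Maximum augmentation lag (default 12).
#' @return List with `statistic`, `lag`, `crit_5pct`, `reject_unit_root`.
#' @export
adf_check <- function(series, max_lag = 12L) {
  n <- length(series)
  if (n <= max_lag + 10L) stop("series too short for adf_check", call. = FALSE)
  if (stats::sd(series) == 0)
    stop("degenerate input: constant series", call. = FALSE)
  dy <- diff(series)
  ylag <- series[-n]
  best <- NULL
  for (p in 0:max_lag) {
    idx <- (p + 1L):(n - 1L)              # usable rows of the ADF regression
    X <- cbind(1, ylag[idx])
    if (p > 0L)
      X <- cbind(X, sapply(seq_len(p), function(i) dy[idx - i]))
    fit <- stats::lm.fit(X, dy[idx])
    k <- ncol(X) + 1L                     # + residual variance
    nn <- length(idx)
    aic <- nn * log(sum(fit$residuals^2) / nn) + 2 * k
    if (is.null(best) || aic < best$aic)
      best <- list(aic = aic, fit = fit, X = X, idx = idx, p = p)
  }
  fit <- best$fit
  res <- fit$residuals
  nn <- length(best$idx)
  s2 <- sum(res^2) / (nn - ncol(best$X))
  XtXinv <- chol2inv(chol(crossprod(best$X)))
  se_g <- sqrt(s2 * XtXinv[2, 2])
  stat <- fit$coefficients[2] / se_g
  # MacKinnon (2010) 5% response surface, constant, no trend
  crit <- -2.86154 - 2.8903 / nn - 4.234 / nn^2 - 40.04 / nn^3
  list(statistic = unname(stat), lag = best$p, crit_5pct = crit,
       reject_unit_root = unname(stat < crit))
}

#' Symbolize month-to-month changes
#'
#' Binary symbolization of a real-valued series: symbol `t` is 1 when the
#' value at `t + 1` strictly exceeds the value at `t`, else 0 (ties give 0).
#' The output is one element shorter than the input.
#'
#' @param series Numeric series, length >= 2.
#' @param label Optional source label carried on the result.
#' @return A `symbolic_series` (list with `symbols`, `rule`, `source_label`).
#' @export
symbolize_changes <- function(series, label = "") {
  if (length(series) < 2L) stop("series too short", call. = FALSE)
  symbolic_series(as.integer(diff(series) > 0), "change", label)
}

#' Symbolize event occurrences
#'
#' Symbol `t` is 1 when at least one event occurred in time step `t`
#' (count >= 1), else 0; length is preserved.
#'
#' @param counts Nonnegative integer event counts.
#' @param label Optional source label.
#' @return A `symbolic_series`.
#' @export
symbolize_events <- function(counts, label = "") {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  symbolic_series(as.integer(counts >= 1), "event", label)
}

symbolic_series <- function(symbols, rule, label = "") {
  stopifnot(all(symbols %in% c(0L, 1L)))
  structure(list(symbols = as.integer(symbols), rule = rule,
                 source_label = label),
            class = "symbolic_series")
}

#' @export
print.symbolic_series <- function(x, ...) {
  cat(sprintf("<symbolic_series> %s rule, length %d (%s): %d ones\n",
              x$rule, length(x$symbols),
              if (nzchar(x$source_label)) x$source_label else "unlabeled",
              sum(x$symbols)))
  invisible(x)
}

# accept a symbolic_series or a raw 0/1 vector
as_symbols <- function(x) {
  if (inherits(x, "symbolic_series")) return(x$symbols)
  x <- as.integer(x)
  if (!all(x %in% c(0L, 1L))) stop("non-binary symbols", call. = FALSE)
  x
}

#' Apply a per-series preprocessing plan
#'
#' Chains the pipeline steps a series needs before symbolization: seasonal
#' adjustment, linear detrending, then change or event symbolization.
#' Continuous monthly series (proxies, model output) typically take
#' `adjust = TRUE, detrend = TRUE, rule = "change"`; sporadic event counts
#' take `rule = "event"` with no adjustment; an already-stationary series
#' can take `rule = "change"` alone.
#'
#' @param series Numeric series.
#' @param rule `"change"` or `"event"`.
#' @param adjust Seasonally adjust first?
#' @param detrend Remove the linear trend?
#' @param period Seasonal period.
#' @param label Source label.
#' @return A `symbolic_series`.
#' @export
preprocess_series <- function(series, rule = c("change", "event"),
                              adjust = FALSE, detrend = FALSE,
                              period = 12L, label = "") {
  rule <- match.arg(rule)
  if (rule == "event") {
    if (adjust || detrend)
      stop("event counts are symbolized directly", call. = FALSE)
    return(symbolize_events(series, label))
  }
  if (adjust) series <- seasonal_adjust(series, period)
  if (detrend) series <- detrend_linear(series)
  symbolize_changes(series, label)
}
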