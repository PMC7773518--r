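#' Preprocessing configuration
#'
#' @param ma_window_ms Moving-average window in milliseconds (default 20 ms).
#'   At 50 Hz a 20-ms window spans a single sample, i.e. the filter is the
#'   identity; the knob matters for plates streaming at higher rates.
#' @param detrend_mode `"linear"` (least-squares line removed per axis,
#'   default) or `"mean"` (mean removed).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(ma_window_ms = 20,
                              detrend_mode = c("linear", "mean")) {
  detrend_mode <- match.arg(detrend_mode)
  if (!is.finite(ma_window_ms) || ma_window_ms <= 0) {
    abort("`ma_window_ms` must be > 0.", class = "sot_validation_error")
  }
  structure(list(ma_window_ms = ma_window_ms, detrend_mode = detrend_mode),
            class = "preprocess_config")
}

detrend_axis <- function(y, t, mode) {
  if (mode == "mean") return(y - mean(y))
  fit <- stats::.lm.fit(cbind(1, t), y)
  unname(fit$residuals)
}

#' Remove the trend from a COP trace
#'
#' Removes, per axis, either the least-squares linear trend or the mean.
#' Length and sampling rate are preserved and the residual mean per axis is
#' numerically zero.
#'
#' @param trace A [cop_trace()] (or coercible data frame).
#' @param mode `"linear"` (default) or `"mean"`.
#' @return A detrended [cop_trace()].
#' @export
detrend_trace <- function(trace, mode = c("linear", "mean")) {
  trace <- as_cop_trace(trace)
  mode <- match.arg(mode)
  cop_trace(time = trace$time,
            ap = detrend_axis(trace$ap, trace$time, mode),
            ml = detrend_axis(trace$ml, trace$time, mode),
            fs = sampling_rate(trace))
}

moving_average_axis <- function(y, w) {
  n <- length(y)
  if (w <= 1) return(y)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  cs <- cumsum(c(0, y))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Moving-average filter a COP trace
#'
#' Applies a centered moving average of `w = max(1, round(window_ms * fs /
#' 1000))` samples per axis.  Edges use shrunken (partial) windows so no data
#' are invented at the trial boundaries; the trace length is unchanged.  For
#' even `w` the window extends one sample further to the right.
#'
#' @param trace A [cop_trace()].
#' @param window_ms Window length in milliseconds (default 20 ms).
#' @return A filtered [cop_trace()].
#' @export
smooth_trace <- function(trace, window_ms = 20) {
  trace <- as_cop_trace(trace)
  if (!is.finite(window_ms) || window_ms <= 0) {
    abort("`window_ms` must be > 0.", class = "sot_validation_error")
  }
  w <- max(1L, as.integer(round(window_ms * sampling_rate(trace) / 1000)))
  cop_trace(time = trace$time,
            ap = moving_average_axis(trace$ap, w),
            ml = moving_average_axis(trace$ml, w),
            fs = sampling_rate(trace))
}

#' Condition a COP trace for metric computation
#'
#' Detrends each axis, then applies the moving-average filter, in that order.
#'
#' @param trace A [cop_trace()].
#' @param config A [preprocess_config()].
#' @return A preprocessed [cop_trace()].
#' @export
preprocess_trace <- function(trace, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  trace %>%
    detrend_trace(mode = config$detrend_mode) %>%
    smooth_trace(window_ms = config$ma_window_ms)
}
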