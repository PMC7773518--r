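#' @importFrom rlang abort %||% .data
#' @importFrom dplyr %>%
NULL

#' Construct a center-of-pressure trace
#'
#' A `cop_trace` is a tibble with columns `time` (s), `ap` (anterior-posterior
#' COP displacement in metres, anterior positive) and `ml` (medial-lateral
#' displacement in metres), uniformly sampled at `fs` Hz.  It is the substrate
#' of every balance metric in the package.
#'
#' @param time Sample times in seconds, strictly increasing and uniformly
#'   spaced (tolerance 1e-6 s on the step).
#' @param ap,ml COP displacement in metres along the anterior-posterior and
#'   medial-lateral axes.  All values must be finite.
#' @param fs Sampling rate in Hz.  When `NULL` (default) it is inferred as the
#'   reciprocal of the median time step.
#'
#' @return A tibble of class `cop_trace` with an `fs` attribute.
#' @examples
#' tr <- cop_trace(time = seq(0, 1.98, by = 0.02),
#'                 ap = sin(seq(0, 1.98, by = 0.02)) / 100,
#'                 ml = rep(0, 100))
#' sampling_rate(tr)
#' @export
cop_trace <- function(time, ap, ml, fs = NULL) {
  n <- length(time)
  if (length(ap) != n || length(ml) != n) {
    abort("`time`, `ap` and `ml` must have the same length.",
          class = "sot_validation_error")
  }
  if (n < 2) {
    abort("a COP trace needs at least 2 samples.",
          class = "sot_degenerate_error")
  }
  if (!all(is.finite(time)) || !all(is.finite(ap)) || !all(is.finite(ml))) {
    abort("COP samples must be finite (no NA, NaN or Inf).",
          class = "sot_validation_error")
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    abort("`time` must be strictly increasing.",
          class = "sot_sampling_error")
  }
  if (is.null(fs)) fs <- 1 / stats::median(dt)
  if (!is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive, finite sampling rate in Hz.",
          class = "sot_validation_error")
  }
  if (max(abs(dt - 1 / fs)) >= 1e-6) {
    abort(sprintf(
      "non-uniform sampling: time steps deviate from 1/fs = %.6g s by more than 1e-6 s.",
      1 / fs), class = "sot_sampling_error")
  }
  out <- tibble::tibble(time = as.double(time),
                        ap   = as.double(ap),
                        ml   = as.double(ml))
  structure(out, fs = as.double(fs),
            class = c("cop_trace", class(out)))
}

#' Coerce a data frame to a COP trace
#'
#' @param x A data frame with columns `time`, `ap`, `ml` (case-insensitive),
#'   or an existing `cop_trace`.
#' @param fs Optional sampling rate in Hz; inferred from the time stamps when
#'   absent.
#' @return A validated [cop_trace()].
#' @export
as_cop_trace <- function(x, fs = NULL) {
  if (inherits(x, "cop_trace") && is.null(fs)) return(x)
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame with columns time, ap, ml.",
          class = "sot_validation_error")
  }
  nm <- tolower(names(x))
  need <- c("time", "ap", "ml")
  if (!all(need %in% nm)) {
    abort(paste0("missing column(s): ",
                 paste(setdiff(need, nm), collapse = ", "),
                 " (expected time, ap, ml)."),
          class = "sot_format_error")
  }
  cop_trace(time = x[[which(nm == "time")[1]]],
            ap   = x[[which(nm == "ap")[1]]],
            ml   = x[[which(nm == "ml")[1]]],
            fs   = fs %||% attr(x, "fs"))
}

#' Sampling rate of a COP trace
#'
#' @param trace A [cop_trace()].
#' @return The sampling rate in Hz.
#' @export
sampling_rate <- function(trace) {
  attr(trace, "fs") %||% (1 / stats::median(diff(trace$time)))
}

#' @export
print.cop_trace <- function(x, ...) {
  cat(sprintf("<cop_trace: %d samples @ %g Hz (%.2f s)>\n",
              nrow(x), sampling_rate(x), nrow(x) / sampling_rate(x)))
  NextMethod()
}

unit_factor <- function(units) {
  switch(match.arg(units, c("m", "cm", "mm")),
         m = 1, cm = 1e-2, mm = 1e-3)
}

#' Read a COP trace from a CSV file
#'
#' The on-disk dialect is a UTF-8 CSV with a header naming (case-insensitive)
#' columns `time`, `ap`, `ml`, decimal point `.`, one file per trial.
#' Displacements are converted to metres according to `units`.
#'
#' @param path Path to the CSV file.
#' @param fs_hint Sampling rate in Hz; when `NULL` it is inferred from the
#'   median time step.
#' @param units Unit of the stored displacements: `"m"` (default), `"cm"` or
#'   `"mm"`.  Values are converted to metres on load.
#' @return A [cop_trace()].
#' @export
read_cop_trace <- function(path, fs_hint = NULL, units = "m") {
  if (!file.exists(path)) {
    abort(paste0("trace file not found: ", path), class = "sot_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(names(df))
  need <- c("time", "ap", "ml")
  if (!all(need %in% nm)) {
    abort(paste0("trace file ", path, " is missing column(s): ",
                 paste(setdiff(need, nm), collapse = ", ")),
          class = "sot_format_error")
  }
  k <- unit_factor(units)
  cop_trace(time = df[[which(nm == "time")[1]]],
            ap   = df[[which(nm == "ap")[1]]] * k,
            ml   = df[[which(nm == "ml")[1]]] * k,
            fs   = fs_hint)
}

#' Write a COP trace to a CSV file
#'
#' Values are serialized with round-trip precision so that
#' `read_cop_trace(write_cop_trace(x, path))` reproduces every sample to
#' better than 1e-9.
#'
#' @param trace A [cop_trace()] (or a data frame coercible to one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cop_trace <- function(trace, path) {
  trace <- as_cop_trace(trace)
  res <- tryCatch(
    readr::write_csv(tibble::tibble(time = trace$time,
                                    ap = trace$ap,
                                    ml = trace$ml),
                     path, progress = FALSE),
    error = function(e) {
      abort(paste0("cannot write trace to ", path, ": ", conditionMessage(e)),
            class = "sot_io_error")
    })
  invisible(path)
}
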