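#' Two-way single-measure intraclass correlation for paired devices
#'
#' Computes the ICC of an n x 2 score table (one row per subject, one column
#' per device) from its two-way ANOVA mean squares.  `"consistency"`
#' (ICC(3,1)-type) ignores a systematic device offset:
#' `(MSR - MSE) / (MSR + MSE)`.  `"agreement"` (ICC(2,1)-type, absolute
#' agreement) penalizes it:
#' `(MSR - MSE) / (MSR + MSE + (2/n) (MSC - MSE))`,
#' with `MSR`, `MSC`, `MSE` the subject, device and error mean squares.
#'
#' @param x,y Paired scores from the two devices, same length `n >= 3`.
#' @param type `"consistency"` or `"agreement"`.
#' @return The ICC (a scalar `<= 1`).
#' @export
icc_pair <- function(x, y, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    abort("ICC needs at least 3 complete pairs.",
          class = "sot_insufficient_data_error")
  }
  tab <- cbind(x, y)
  if (sum((tab - mean(tab))^2) <= 0) {
    abort("zero total variance; the ICC is undefined.",
          class = "sot_undefined_statistic_error")
  }
  k <- 2
  MSR <- k * stats::var(rowMeans(tab))
  MSC <- n * stats::var(colMeans(tab))
  SSE <- sum((tab - mean(tab))^2) - (n - 1) * MSR - (k - 1) * MSC
  MSE <- SSE / ((n - 1) * (k - 1))
  if (type == "consistency") {
    (MSR - MSE) / (MSR + (k - 1) * MSE)
  } else {
    (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  }
}

#' Pearson correlation with two-sided p-value
#'
#' Sample correlation with the p-value from the t-distribution on `n - 2`
#' degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Paired numeric vectors, `n >= 3`, both non-constant.
#' @return A one-row tibble with `r`, `p` and `n`.
#' @export
pearson_pair <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort("Pearson correlation needs at least 3 complete pairs.",
          class = "sot_insufficient_data_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("constant input; the correlation is undefined.",
          class = "sot_undefined_statistic_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bland-Altman statistics
#'
#' Differences are taken as `y - x`; the limits of agreement are
#' `mean(d) +/- k * sd(d)` with the n-1 standard deviation and `k = 1.96`
#' by default.
#'
#' @param x,y Paired numeric vectors, `n >= 2`.
#' @param k Half-width multiplier for the limits of agreement.
#' @return A one-row tibble with `mean_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(x, y, k = 1.96) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) {
    abort("Bland-Altman needs at least 2 complete pairs.",
          class = "sot_insufficient_data_error")
  }
  d <- y - x
  m <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(mean_diff = m, loa_low = m - k * s, loa_high = m + k * s)
}

#' Interpretation bands for reliability and correlation values
#'
#' `interpret_icc()` uses the Koo-Li reliability bands: poor (< 0.5),
#' moderate (0.5-0.75), good (0.75-0.9), excellent (>= 0.9).
#' `interpret_r()` bins the magnitude of the correlation: negligible
#' (< 0.3), weak (0.3-0.5), moderate (0.5-0.7), strong (0.7-0.9), very
#' strong (>= 0.9); negative correlations are labelled by `|r|`.
#'
#' @param value A numeric vector of ICCs or correlations.
#' @return A character vector of labels.
#' @export
interpret_icc <- function(value) {
  out <- as.character(cut(value, c(-Inf, 0.5, 0.75, 0.9, Inf),
                          labels = c("poor", "moderate", "good", "excellent"),
                          right = FALSE))
  out[!is.finite(value)] <- NA_character_
  out
}

#' @rdname interpret_icc
#' @export
interpret_r <- function(value) {
  out <- as.character(cut(abs(value), c(-Inf, 0.3, 0.5, 0.7, 0.9, Inf),
                          labels = c("negligible", "weak", "moderate",
                                     "strong", "very strong"),
                          right = FALSE))
  out[!is.finite(value)] <- NA_character_
  out
}

#' Full between-device agreement summary for one condition
#'
#' Bundles, for a table of paired scores, both intraclass correlations, the
#' Pearson correlation with its p-value, the Bland-Altman statistics, and the
#' interpretation labels.
#'
#' @param data A data frame of paired scores.
#' @param x,y Unquoted column names holding the reference-device and
#'   test-device scores (e.g. `ei`, `eei`).
#' @param ba_k Limits-of-agreement multiplier (default 1.96).
#' @return A one-row tibble with columns `n`, `icc_absolute`,
#'   `icc_consistency`, their labels, `pearson_r`, `pearson_p`, `r_label`,
#'   `ba_mean_diff`, `ba_loa_low`, `ba_loa_high`.
#' @examples
#' d <- data.frame(ei = c(70, 80, 90, 60), eei = c(72, 79, 88, 65))
#' agreement_stats(d, ei, eei)
#' @export
agreement_stats <- function(data, x, y, ba_k = 1.96) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  pe <- pearson_pair(xv, yv)
  ba <- bland_altman(xv, yv, k = ba_k)
  ia <- icc_pair(xv, yv, type = "agreement")
  ic <- icc_pair(xv, yv, type = "consistency")
  tibble::tibble(
    n = pe$n,
    icc_absolute = ia,
    icc_consistency = ic,
    icc_absolute_label = interpret_icc(ia),
    icc_consistency_label = interpret_icc(ic),
    pearson_r = pe$r,
    pearson_p = pe$p,
    r_label = interpret_r(pe$r),
    ba_mean_diff = ba$mean_diff,
    ba_loa_low = ba$loa_low,
    ba_loa_high = ba$loa_high)
}
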