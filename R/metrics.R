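#' Parameters of the estimated equilibrium index
#'
#' The equilibrium index scores anterior-posterior sway against a theoretical
#' stability limit: a participant with no sway scores 100, and combined
#' forward-plus-backward sway at or beyond `theta_limit_deg` scores 0.  Sway
#' angles are obtained from COP excursions via the inverse sine over an
#' estimated centre-of-gravity height, taken as `cog_height_fraction` of
#' stature.
#'
#' @param theta_limit_deg Theoretical sway limit in degrees (default 12.5).
#' @param cog_height_fraction Centre-of-gravity height as a fraction of
#'   participant height (default 0.56).
#' @return A list of class `ei_params`.
#' @export
ei_params <- function(theta_limit_deg = 12.5, cog_height_fraction = 0.56) {
  if (!is.finite(theta_limit_deg) || theta_limit_deg <= 0) {
    abort("`theta_limit_deg` must be > 0.", class = "sot_validation_error")
  }
  if (!is.finite(cog_height_fraction) ||
      cog_height_fraction <= 0 || cog_height_fraction >= 1) {
    abort("`cog_height_fraction` must be in (0, 1).",
          class = "sot_validation_error")
  }
  structure(list(theta_limit_deg = theta_limit_deg,
                 cog_height_fraction = cog_height_fraction),
            class = "ei_params")
}

#' Anterior and posterior sway angles
#'
#' Converts the peak anterior and peak posterior COP excursions of a
#' (detrended) trace into sway angles: `asin(peak / h)` in degrees, where
#' `h = cog_height_fraction * height` is the estimated centre-of-gravity
#' height.  A peak that does not cross zero in a direction contributes a
#' zero angle in that direction.
#'
#' @param trace A [cop_trace()], detrended so the AP signal is mean-zero.
#' @param height Participant height in metres.
#' @param params An [ei_params()].
#' @return A one-row tibble with `theta_ant` and `theta_post` in degrees.
#' @export
sway_angles <- function(trace, height, params = ei_params()) {
  trace <- as_cop_trace(trace)
  stopifnot(inherits(params, "ei_params"))
  if (!is.finite(height) || height <= 0) {
    abort("`height` must be a positive length in metres.",
          class = "sot_validation_error")
  }
  h <- params$cog_height_fraction * height
  if (max(abs(trace$ap)) >= h) {
    abort("AP excursion reaches the estimated COG height; the inverse-sine sway model is undefined.",
          class = "sot_domain_error")
  }
  deg <- 180 / pi
  tibble::tibble(
    theta_ant  = deg * asin(max(max(trace$ap), 0) / h),
    theta_post = deg * asin(max(-min(trace$ap), 0) / h))
}

#' Estimated equilibrium index (eEI)
#'
#' Scores a trace on the 0-100 equilibrium scale:
#' `100 * (1 - (theta_ant + theta_post) / theta_limit_deg)`, clamped to
#' `[0, 100]`.  Zero sway scores 100; combined sway at or beyond the limit
#' (12.5 degrees by default) scores 0.
#'
#' @inheritParams sway_angles
#' @return A scalar score in `[0, 100]`.
#' @export
estimated_equilibrium_index <- function(trace, height, params = ei_params()) {
  th <- sway_angles(trace, height, params)
  raw <- 100 * (1 - (th$theta_ant + th$theta_post) / params$theta_limit_deg)
  min(max(raw, 0), 100)
}

#' 95% confidence-ellipse sway area
#'
#' Area of the ellipse expected to contain a fraction `conf` of COP samples
#' under a bivariate normal model:
#' `pi * qchisq(conf, 2) * sqrt(det(S))`, with `S` the 2x2 sample covariance
#' (n-1 denominator) of the AP and ML displacements.  For `conf = 0.95` the
#' chi-square quantile is 5.991.
#'
#' @param trace A [cop_trace()] with at least 3 samples.
#' @param conf Coverage probability of the ellipse (default 0.95).
#' @return The ellipse area in square metres.
#' @export
ellipse_area_95 <- function(trace, conf = 0.95) {
  trace <- as_cop_trace(trace)
  if (nrow(trace) < 3) {
    abort("ellipse area needs at least 3 samples.",
          class = "sot_degenerate_error")
  }
  S <- stats::cov(cbind(trace$ap, trace$ml))
  pi * stats::qchisq(conf, df = 2) * sqrt(max(det(S), 0))
}

#' Sway path length
#'
#' Total length of the COP trajectory: the sum of Euclidean distances between
#' consecutive (ap, ml) samples.
#'
#' @param trace A [cop_trace()] with at least 2 samples.
#' @return Path length in metres.
#' @export
path_length <- function(trace) {
  trace <- as_cop_trace(trace)
  sum(sqrt(diff(trace$ap)^2 + diff(trace$ml)^2))
}

#' Detrended fluctuation analysis configuration
#'
#' @param min_box Smallest box size in samples (default 4); must be at least
#'   `poly_order + 2` so each box supports the polynomial fit.
#' @param max_box_fraction Largest box as a fraction of the series length
#'   (default 1/4).
#' @param n_boxes Number of log-spaced box sizes (default 12).
#' @param poly_order Order of the per-box detrending polynomial (default 1).
#' @return A list of class `dfa_config`.
#' @export
dfa_config <- function(min_box = 4, max_box_fraction = 0.25, n_boxes = 12,
                       poly_order = 1) {
  min_box <- as.integer(min_box)
  poly_order <- as.integer(poly_order)
  if (min_box < poly_order + 2) {
    abort("`min_box` must be at least `poly_order + 2`.",
          class = "sot_validation_error")
  }
  if (max_box_fraction <= 0 || max_box_fraction > 1) {
    abort("`max_box_fraction` must be in (0, 1].",
          class = "sot_validation_error")
  }
  structure(list(min_box = min_box, max_box_fraction = max_box_fraction,
                 n_boxes = as.integer(n_boxes), poly_order = poly_order),
            class = "dfa_config")
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Standard DFA: the mean-removed series is integrated; for each of
#' `n_boxes` log-spaced box sizes the profile is partitioned into
#' non-overlapping boxes (anchored at the series start), a least-squares
#' polynomial of order `poly_order` is removed per box, and `F(n)` is the RMS
#' residual over all boxed samples.  The exponent alpha is the least-squares
#' slope of `log F(n)` against `log n`.  Uncorrelated noise gives alpha near
#' 0.5 and Brownian-like signals near 1.5.
#'
#' @param x A numeric series, or a [cop_trace()] whose AP channel is used.
#' @param config A [dfa_config()].
#' @return The scaling exponent alpha.
#' @export
dfa_alpha <- function(x, config = dfa_config()) {
  if (inherits(x, "cop_trace") || is.data.frame(x)) {
    x <- as_cop_trace(x)$ap
  }
  stopifnot(inherits(config, "dfa_config"))
  N <- length(x)
  if (N < 4L * config$min_box) {
    abort("series too short for DFA at this configuration.",
          class = "sot_degenerate_error")
  }
  y <- cumsum(x - mean(x))
  max_box <- floor(N * config$max_box_fraction)
  sizes <- unique(round(exp(seq(log(config$min_box), log(max_box),
                                length.out = config$n_boxes))))
  Fn <- vapply(sizes, function(n) {
    m <- N %/% n
    Y <- matrix(y[seq_len(n * m)], nrow = n)
    X <- outer(seq_len(n), 0:config$poly_order, `^`)
    res <- Y - X %*% qr.coef(qr(X), Y)
    sqrt(mean(res^2))
  }, numeric(1))
  if (any(Fn <= 0)) {
    abort("zero fluctuation in a box; DFA is undefined for a constant series.",
          class = "sot_degenerate_error")
  }
  lx <- log(sizes)
  ly <- log(Fn)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Compute the per-trial balance metric bundle
#'
#' Applies the four trial-level measures to a preprocessed trace: estimated
#' equilibrium index, 95% ellipse area, path length, and the AP DFA scaling
#' exponent.  A trace whose AP channel is constant (no sway) has no defined
#' DFA exponent; the bundle then reports `dfa_alpha_ap = NA`.
#'
#' @param trace A preprocessed [cop_trace()].
#' @param height Participant height in metres.
#' @param ei An [ei_params()].
#' @param dfa A [dfa_config()].
#' @return A one-row tibble with columns `eei`, `ellipse_area_95`,
#'   `path_length`, `dfa_alpha_ap`.
#' @export
compute_balance_metrics <- function(trace, height, ei = ei_params(),
                                    dfa = dfa_config()) {
  trace <- as_cop_trace(trace)
  alpha <- tryCatch(dfa_alpha(trace$ap, config = dfa),
                    sot_degenerate_error = function(e) NA_real_)
  tibble::tibble(
    eei = estimated_equilibrium_index(trace, height, ei),
    ellipse_area_95 = ellipse_area_95(trace),
    path_length = path_length(trace),
    dfa_alpha_ap = alpha)
}
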