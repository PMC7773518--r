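# Build a trace from an AP vector at a given rate; ML defaults to zero.
make_trace <- function(ap, ml = rep(0, length(ap)), fs = 50) {
  cop_trace(time = (seq_along(ap) - 1) / fs, ap = ap, ml = ml, fs = fs)
}

# Palindromic zero-mean AP pattern with peaks +a and -2a (odd n only).
# Palindromic + zero-mean means a linear detrend is exactly the identity,
# so pipeline preprocessing leaves the peaks untouched.
palindrome_ap <- function(a, n = 101) {
  stopifnot(n >= 5, n %% 2 == 1)
  ap <- numeric(n)
  ap[2] <- a
  ap[n - 1] <- a
  ap[(n + 1) %/% 2] <- -2 * a
  ap
}

# Solve for the palindrome amplitude that yields a prescribed combined sway
# angle (degrees) at COG height h, independent of the package's internals.
palindrome_amplitude <- function(theta_deg, h) {
  th <- theta_deg * pi / 180
  g <- function(a) asin(a / h) + asin(2 * a / h) - th
  stats::uniroot(g, c(0, h * sin(min(th, pi / 2 - 1e-9)) / 2),
                 tol = 1e-14)$root
}

# A toy paired study: per participant and condition, the VR trace is built so
# its estimated equilibrium index exactly equals `eei`, and the Equitest
# score is `ei`.  Heights are all 1.70 m.  `scores` is a data frame with
# columns pid, condition, ei, eei and optionally trial_index rows are
# expanded to (1, 2) with trial 1 a decoy unless n_trials = 1.
toy_study <- function(scores, n_trials = 2, height = 1.70) {
  h <- 0.56 * height
  participants <- tibble::tibble(pid = unique(scores$pid), height = height)
  rows <- list()
  for (i in seq_len(nrow(scores))) {
    s <- scores[i, ]
    for (t in seq_len(n_trials)) {
      # familiarization trials carry a wrong score so selection is testable
      ei_t <- if (t < n_trials) max(0, s$ei - 10) else s$ei
      eei_t <- if (t < n_trials) max(0, s$eei - 10) else s$eei
      rows[[length(rows) + 1]] <- tibble::tibble(
        pid = s$pid, condition = s$condition, device = "equitest",
        trial_index = t, ei = ei_t, trace = list(NULL))
      theta <- (100 - eei_t) * 12.5 / 100
      a <- if (theta <= 0) 0 else palindrome_amplitude(theta, h)
      ap <- palindrome_ap(a, n = 101)
      rows[[length(rows) + 1]] <- tibble::tibble(
        pid = s$pid, condition = s$condition, device = "vr",
        trial_index = t, ei = NA_real_,
        trace = list(make_trace(ap, ml = rep(0, 101))))
    }
  }
  sot_study(participants, dplyr::bind_rows(rows))
}
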