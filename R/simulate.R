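#' Configuration of the synthetic paired-session generator
#'
#' Describes a study of `n_participants` completing the full 28-trial
#' session: six SOT conditions on the Equitest (two trials each, scalar EI),
#' the six matched VR conditions (two trials each, COP traces), and the two
#' head-tracking-only VR environments (`VRX1` stable, `VRX2` foam) that have
#' no Equitest counterpart.
#'
#' Per participant and condition a latent stability `z ~ N(0,1)` drives the
#' Equitest score, and a second latent `w = rho * z + sqrt(1 - rho^2) * z'`
#' drives the VR sway: the combined AP sway angle is
#' `theta = theta_c * exp(-latent_gain * w + e)` with trial-level log-normal
#' noise `e`, so larger latent instability (lower `w`) yields a larger angle
#' and a lower estimated equilibrium index.  `theta_c` is set from the
#' condition's sway scale `sigma[c]` via a nominal peak-to-RMS factor over a
#' reference centre-of-gravity height, so increasing `sigma[c]` lowers the
#' expected score.  `rho` is the single knob controlling between-device
#' agreement; [sim_expected_agreement()] returns the implied closed-form
#' per-condition ICCs and Pearson correlation.
#'
#' @param n_participants Number of participants (default 20).
#' @param rho Latent between-device agreement correlation in `[-1, 1]`
#'   (default 0.75, yielding moderate ICCs).
#' @param sigma Named per-condition stationary sway scale in metres
#'   (`SOT1`..`SOT6`), increasing with condition difficulty.  Defaults are
#'   chosen so expected scores span roughly 58-85.
#' @param sigma_extra Sway scales for the two unmatched VR environments.
#' @param latent_gain Log-scale gain from the latent `w` to the sway angle
#'   (default 0.25).
#' @param noise_sd_log_sway SD of the trial-level log-normal sway noise
#'   (default 0.10).
#' @param noise_sd_ei SD of the Equitest trial measurement noise in score
#'   units (default 3).
#' @param vr_bias Systematic offset of the VR score in score units
#'   (default 0); a non-zero bias lowers absolute agreement but not
#'   consistency.
#' @param trial_seconds,fs Trial duration (20 s) and COP sampling rate
#'   (50 Hz).
#' @param tau Mean-reversion time constant of the sway process in seconds
#'   (default 1), keeping 20-s traces bounded.
#' @param n_trials Trials per condition and device (default 2; the first is
#'   the familiarization run).
#' @param male_prop Proportion of male participants (default 7/20).
#' @param height_mean,height_sd Sex-specific height distributions in metres
#'   (male 1.79 (0.079), female 1.66 (0.072)).
#' @param peak_factor Nominal combined peak-to-RMS factor converting a sway
#'   scale to a combined excursion (default 5, i.e. about 2.5 SD each way).
#' @param height_ref Reference stature (m) used only to map `sigma` to a
#'   nominal condition sway angle.
#' @param cog_height_fraction Centre-of-gravity height fraction assumed by
#'   the scoring model (default 0.56).
#' @param theta_limit_deg Scoring sway limit in degrees (default 12.5).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 20,
                       rho = 0.75,
                       sigma = c(SOT1 = 0.0062, SOT2 = 0.0071,
                                 SOT3 = 0.0083, SOT4 = 0.0108,
                                 SOT5 = 0.0158, SOT6 = 0.0175),
                       sigma_extra = c(VRX1 = 0.0083, VRX2 = 0.0140),
                       latent_gain = 0.25,
                       noise_sd_log_sway = 0.10,
                       noise_sd_ei = 3,
                       vr_bias = 0,
                       trial_seconds = 20, fs = 50, tau = 1,
                       n_trials = 2,
                       male_prop = 7 / 20,
                       height_mean = c(male = 1.79, female = 1.66),
                       height_sd = c(male = 0.079, female = 0.072),
                       peak_factor = 5,
                       height_ref = 1.70,
                       cog_height_fraction = 0.56,
                       theta_limit_deg = 12.5) {
  if (abs(rho) > 1) {
    abort("`rho` must lie in [-1, 1].", class = "sot_validation_error")
  }
  if (length(sigma) != 6 || any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort("`sigma` must give a positive sway scale for each SOT condition.",
          class = "sot_validation_error")
  }
  names(sigma) <- paste0("SOT", 1:6)
  names(sigma_extra) <- c("VRX1", "VRX2")
  structure(list(n_participants = as.integer(n_participants), rho = rho,
                 sigma = sigma, sigma_extra = sigma_extra,
                 latent_gain = latent_gain,
                 noise_sd_log_sway = noise_sd_log_sway,
                 noise_sd_ei = noise_sd_ei, vr_bias = vr_bias,
                 trial_seconds = trial_seconds, fs = fs, tau = tau,
                 n_trials = as.integer(n_trials), male_prop = male_prop,
                 height_mean = height_mean, height_sd = height_sd,
                 peak_factor = peak_factor, height_ref = height_ref,
                 cog_height_fraction = cog_height_fraction,
                 theta_limit_deg = theta_limit_deg),
            class = "sim_config")
}

derive_seed <- function(seed, i) {
  as.integer(((seed %% 2147483647) * 69621 + i) %% 2147483647)
}

ar1_series <- function(n, phi, sigma) {
  innov <- stats::rnorm(n, 0, sigma * sqrt(1 - phi^2))
  x0 <- stats::rnorm(1, 0, sigma)
  as.numeric(stats::filter(innov, phi, method = "recursive", init = x0))
}

#' Simulate a mean-reverting sway trace
#'
#' AP and ML are independent first-order autoregressive processes reverting
#' toward zero with time constant `tau` and stationary standard deviation
#' `sigma`, started from the stationary distribution, so 20-s traces remain
#' bounded and the inverse-sine sway model stays defined.
#'
#' @param sigma Stationary SD of each axis in metres.
#' @param seconds Trial duration in seconds (default 20).
#' @param fs Sampling rate in Hz (default 50).
#' @param tau Mean-reversion time constant in seconds (default 1).
#' @param seed Optional integer seed; fixed seeds give identical traces.
#' @return A [cop_trace()].
#' @export
simulate_sway_trace <- function(sigma, seconds = 20, fs = 50, tau = 1,
                                seed = NULL) {
  if (!is.finite(sigma) || sigma <= 0) {
    abort("`sigma` must be > 0.", class = "sot_validation_error")
  }
  gen <- function() {
    n <- round(seconds * fs)
    phi <- exp(-1 / (tau * fs))
    cop_trace(time = (seq_len(n) - 1) / fs,
              ap = ar1_series(n, phi, sigma),
              ml = ar1_series(n, phi, sigma),
              fs = fs)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Closed-form agreement implied by a generator configuration
#'
#' Under the generator's latent model the Equitest score is linear in `z`
#' and the VR score is an affine function of the log-normal variable
#' `U = exp(-latent_gain * w + e)`, so all second moments -- and hence the
#' population two-way consistency ICC `2 cov / (var_x + var_y)`, the
#' absolute-agreement ICC `2 cov / (var_x + var_y + vr_bias^2)`, and the
#' Pearson correlation -- have closed forms.  Boundary clamping of the 0-100
#' scale is rare under the default scales and is ignored here.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per SOT condition: the expected score
#'   `score_mean`, the device variances and covariance, `icc_consistency`,
#'   `icc_absolute` and `pearson_r`, plus attribute-free summary columns.
#' @export
sim_expected_agreement <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  q <- 100 / config$theta_limit_deg
  s <- config$latent_gain
  vt <- s^2 + config$noise_sd_log_sway^2
  EU <- exp(vt / 2)
  varU <- exp(vt) * (exp(vt) - 1)
  h_ref <- config$cog_height_fraction * config$height_ref
  theta_bar <- (180 / pi) * config$peak_factor * config$sigma / h_ref
  theta_c <- theta_bar / EU
  a_c <- q * theta_c * sqrt(varU)
  cov_xy <- a_c * q * theta_c * s * config$rho * EU
  var_x <- a_c^2 + config$noise_sd_ei^2
  var_y <- (q * theta_c)^2 * varU
  tibble::tibble(
    condition = paste0("SOT", 1:6),
    sigma = unname(config$sigma),
    score_mean = 100 - q * theta_bar,
    theta_c = unname(theta_c),
    ei_subject_sd = unname(a_c),
    var_ei = unname(var_x),
    var_eei = unname(var_y),
    cov = unname(cov_xy),
    icc_consistency = unname(2 * cov_xy / (var_x + var_y)),
    icc_absolute = unname(2 * cov_xy /
                            (var_x + var_y + config$vr_bias^2)),
    pearson_r = unname(cov_xy / sqrt(var_x * var_y)))
}

solve_peak_scale <- function(dap, h, theta_deg) {
  theta <- theta_deg * pi / 180
  pmax <- max(dap)
  pmin <- -min(dap)
  pk <- max(pmax, pmin)
  upper <- h * sin(min(theta, pi / 2 - 1e-9)) / pk
  g <- function(cc) asin(cc * pmax / h) + asin(cc * pmin / h) - theta
  stats::uniroot(g, c(0, upper), tol = 1e-12)$root
}

#' Simulate a full paired-device study
#'
#' Generates a [sot_study()] with the complete 28-trial session per
#' participant under the latent-agreement model of [sim_config()], together
#' with a truth record (attribute `"truth"`, see [sim_truth()]) holding the
#' planted `rho` and the closed-form expected agreement statistics from
#' [sim_expected_agreement()], so expected values are available without
#' re-simulation.
#'
#' Each VR trace is a mean-reverting sway process whose detrended AP channel
#' is rescaled so its combined sway angle exactly realizes the trial's
#' latent sway draw; the pipeline's estimated equilibrium index therefore
#' recovers the designed score (up to the rare 0/100 boundary clamp).  One
#' seed governs the whole study; per-trial trace substreams are derived
#' deterministically from it.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for the study.
#' @return A [sot_study()] with attribute `"truth"`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  q <- 100 / config$theta_limit_deg
  s <- config$latent_gain
  truth_tab <- sim_expected_agreement(config)
  theta_c <- stats::setNames(truth_tab$theta_c, truth_tab$condition)
  a_c <- stats::setNames(truth_tab$ei_subject_sd, truth_tab$condition)
  mu_c <- stats::setNames(truth_tab$score_mean, truth_tab$condition)
  codes <- paste0("SOT", 1:6)
  nt <- config$n_trials

  draws <- withr::with_seed(derive_seed(seed, 1L), {
    n_male <- round(config$male_prop * n)
    sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
    height <- ifelse(sex == "male",
                     stats::rnorm(n, config$height_mean[["male"]],
                                  config$height_sd[["male"]]),
                     stats::rnorm(n, config$height_mean[["female"]],
                                  config$height_sd[["female"]]))
    height <- pmin(pmax(height, 0.55), 2.45)
    list(sex = sex, height = height,
         z = matrix(stats::rnorm(n * 6), n, 6, dimnames = list(NULL, codes)),
         zp = matrix(stats::rnorm(n * 6), n, 6,
                     dimnames = list(NULL, codes)),
         eps = array(stats::rnorm(n * 6 * nt, 0, config$noise_sd_ei),
                     c(n, 6, nt)),
         eta = array(stats::rnorm(n * 6 * nt, 0, config$noise_sd_log_sway),
                     c(n, 6, nt)))
  })

  pids <- sprintf("P%02d", seq_len(n))
  participants <- tibble::tibble(pid = pids, height = draws$height,
                                 mass = NA_real_, sex = draws$sex,
                                 age = NA_real_)

  n_rows <- n * (6L * 2L * nt + 2L * nt)
  col_pid <- character(n_rows)
  col_cond <- character(n_rows)
  col_dev <- character(n_rows)
  col_tidx <- integer(n_rows)
  col_ei <- rep(NA_real_, n_rows)
  col_trace <- vector("list", n_rows)
  ri <- 0L
  add_row <- function(pid, cond, dev, tidx, ei, trace) {
    ri <<- ri + 1L
    col_pid[ri] <<- pid
    col_cond[ri] <<- cond
    col_dev[ri] <<- dev
    col_tidx[ri] <<- tidx
    col_ei[ri] <<- ei
    col_trace[[ri]] <<- trace
  }
  EU <- exp((s^2 + config$noise_sd_log_sway^2) / 2)
  for (p in seq_len(n)) {
    h <- config$cog_height_fraction * draws$height[p]
    for (ci in seq_along(codes)) {
      cc <- codes[ci]
      z <- draws$z[p, ci]
      w <- config$rho * z + sqrt(1 - config$rho^2) * draws$zp[p, ci]
      for (t in seq_len(nt)) {
        ei <- min(max(mu_c[[cc]] + a_c[[cc]] * z + draws$eps[p, ci, t],
                      0), 100)
        add_row(pids[p], cc, "equitest", t, ei, NULL)

        U <- exp(-s * w + draws$eta[p, ci, t])
        eei_des <- min(max(100 - q * theta_c[[cc]] * U + config$vr_bias,
                           0), 100)
        theta_target <- max((100 - eei_des) / q, 0.01)
        base <- simulate_sway_trace(config$sigma[[cc]],
                                    seconds = config$trial_seconds,
                                    fs = config$fs, tau = config$tau,
                                    seed = derive_seed(seed,
                                                       p * 1000L + ci * 10L +
                                                         t))
        dap <- detrend_axis(base$ap, base$time, "linear")
        cc_scale <- solve_peak_scale(dap, h, theta_target)
        add_row(pids[p], cc, "vr", t, NA_real_,
                cop_trace(time = base$time,
                          ap = cc_scale * dap,
                          ml = base$ml * U / EU,
                          fs = config$fs))
      }
    }
    for (xi in seq_along(config$sigma_extra)) {
      for (t in seq_len(nt)) {
        add_row(pids[p], names(config$sigma_extra)[xi], "vr", t, NA_real_,
                simulate_sway_trace(
                  config$sigma_extra[[xi]], seconds = config$trial_seconds,
                  fs = config$fs, tau = config$tau,
                  seed = derive_seed(seed, p * 1000L + (6L + xi) * 10L + t)))
      }
    }
  }

  trials <- tibble::tibble(pid = col_pid, condition = col_cond,
                           device = col_dev, trial_index = col_tidx,
                           ei = col_ei, trace = col_trace)
  study <- sot_study(participants, trials)
  attr(study, "truth") <- list(
    rho = config$rho,
    seed = seed,
    conditions = truth_tab,
    mean_icc_consistency = mean(truth_tab$icc_consistency),
    mean_icc_absolute = mean(truth_tab$icc_absolute),
    mean_pearson_r = mean(truth_tab$pearson_r))
  study
}

#' Truth record of a simulated study
#'
#' @param study The return value of [simulate_study()].
#' @return A list with the planted `rho`, the study seed, the per-condition
#'   closed-form agreement table, and their across-condition means.
#' @export
sim_truth <- function(study) {
  attr(study, "truth")
}
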