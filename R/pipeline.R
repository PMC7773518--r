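#' The six sensory organization test conditions
#'
#' Enumerates the SOT condition taxonomy shared by the two devices: the
#' Equitest description, the matched VR environment, and the quality of each
#' sensory channel in that condition (`accurate`, `inaccurate` or `absent`).
#' Vestibular input is accurate throughout; vision is absent with eyes closed
#' (blacked-out VR), inaccurate when the surround is sway- or
#' head-referenced; somatosensation is inaccurate on a sway-referenced or
#' foam surface.
#'
#' @return A six-row tibble with columns `condition`, `equitest_desc`,
#'   `vr_desc`, `visual`, `somatosensory`, `vestibular`.
#' @export
sot_conditions <- function() {
  tibble::tibble(
    condition = paste0("SOT", 1:6),
    equitest_desc = c(
      "Eyes open on a stable surface",
      "Eyes closed on a stable surface",
      "Eyes open with a sway-referenced surround",
      "Eyes open on a sway-referenced surface",
      "Eyes closed on a sway-referenced surface",
      "Eyes open with a sway-referenced surround and surface"),
    vr_desc = c(
      "Stable virtual surround on a stable surface",
      "Blacked out environment on a stable surface",
      "Head-referenced virtual surround on a stable surface",
      "Stable virtual surround on a foam surface",
      "Blacked out environment on a foam surface",
      "Head-referenced virtual surround on a foam surface"),
    visual = c("accurate", "absent", "inaccurate",
               "accurate", "absent", "inaccurate"),
    somatosensory = c("accurate", "accurate", "accurate",
                      "inaccurate", "inaccurate", "inaccurate"),
    vestibular = rep("accurate", 6))
}

#' Select the analysis trial per (participant, condition, device)
#'
#' The first trial of each condition is a familiarization run; only the final
#' trial (highest `trial_index`) enters the analysis.  Selection is
#' independent of the input row order.
#'
#' @param study A [sot_study()], or its `trials` tibble.
#' @return A tibble with one row per (pid, condition, device).
#' @export
select_analysis_trials <- function(study) {
  trials <- if (inherits(study, "sot_study")) study$trials else
    tibble::as_tibble(study)
  trials %>%
    dplyr::group_by(.data$pid, .data$condition, .data$device) %>%
    dplyr::slice_max(.data$trial_index, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$pid, .data$condition, .data$device)
}

#' Flag and remove paired 3-SD outliers
#'
#' For each condition, each device's score vector is screened once against
#' the mean and SD of that (condition, device) vector: entries farther than
#' `k` SDs from the mean are flagged.  A flag on either device removes the
#' participant's whole pair for that condition, so the two devices stay
#' aligned.  The screen is single-pass: means and SDs come from the
#' unfiltered vectors and are not re-estimated after removal.  Conditions
#' with fewer than 3 pairs are not screened.
#'
#' @param pairs A data frame with columns `pid`, `condition` and the two
#'   score columns.
#' @param x,y Unquoted score column names (reference device, test device).
#' @param k SD multiplier (default 3).
#' @return The retained rows of `pairs`, with an `exclusions` attribute: a
#'   tibble (`pid`, `condition`, `device`, `score`, `center`, `spread`)
#'   logging every flagged entry (see [exclusion_log()]).
#' @export
exclude_outlier_pairs <- function(pairs, x, y, k = 3) {
  pairs <- tibble::as_tibble(pairs)
  xq <- rlang::as_name(rlang::enquo(x))
  yq <- rlang::as_name(rlang::enquo(y))

  flag_vec <- function(v) {
    if (sum(is.finite(v)) < 3) return(rep(FALSE, length(v)))
    m <- mean(v)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(FALSE, length(v)))
    abs(v - m) > k * s
  }

  log_rows <- list()
  flagged <- pairs %>%
    dplyr::group_by(.data$condition) %>%
    dplyr::mutate(
      .flag_x = flag_vec(.data[[xq]]),
      .flag_y = flag_vec(.data[[yq]])) %>%
    dplyr::ungroup()

  log <- dplyr::bind_rows(
    flagged %>%
      dplyr::filter(.data$.flag_x) %>%
      dplyr::transmute(.data$pid, .data$condition, device = "equitest",
                       score = .data[[xq]]),
    flagged %>%
      dplyr::filter(.data$.flag_y) %>%
      dplyr::transmute(.data$pid, .data$condition, device = "vr",
                       score = .data[[yq]])) %>%
    dplyr::arrange(.data$condition, .data$pid)

  kept <- flagged %>%
    dplyr::filter(!.data$.flag_x & !.data$.flag_y) %>%
    dplyr::select(-".flag_x", -".flag_y")

  attr(kept, "exclusions") <- log
  kept
}

#' Exclusion log of a screened pair table or pipeline result
#'
#' @param x The return value of [exclude_outlier_pairs()] or
#'   [run_sot_pipeline()].
#' @return A tibble of flagged entries.
#' @export
exclusion_log <- function(x) {
  if (inherits(x, "sot_results")) return(x$exclusions)
  attr(x, "exclusions") %||%
    tibble::tibble(pid = character(), condition = character(),
                   device = character(), score = double())
}

na_agreement_row <- function(n) {
  tibble::tibble(n = n, icc_absolute = NA_real_, icc_consistency = NA_real_,
                 icc_absolute_label = NA_character_,
                 icc_consistency_label = NA_character_,
                 pearson_r = NA_real_, pearson_p = NA_real_,
                 r_label = NA_character_, ba_mean_diff = NA_real_,
                 ba_loa_low = NA_real_, ba_loa_high = NA_real_)
}

safe_pearson <- function(x, y) {
  tryCatch(pearson_pair(x, y),
           error = function(e) tibble::tibble(r = NA_real_, p = NA_real_,
                                              n = length(x)))
}

#' Run the end-to-end SOT agreement analysis
#'
#' Orchestrates the full validation analysis on a paired-device study:
#' keep only the final trial per (participant, condition, device);
#' preprocess every VR trace (detrend, moving-average filter) and compute its
#' balance metrics; pair the VR estimated equilibrium index with the Equitest
#' equilibrium index per condition; apply the single-pass 3-SD paired outlier
#' screen to the primary scores; then compute, per condition, the agreement
#' summary (ICCs, Pearson, Bland-Altman) and the Pearson correlation of the
#' Equitest score against each retained COP metric.
#'
#' Conditions with fewer than 3 retained pairs are reported with missing
#' statistics and a warning rather than aborting the run.
#'
#' @param study A [sot_study()] containing both devices.
#' @param preprocess A [preprocess_config()].
#' @param ei An [ei_params()].
#' @param dfa A [dfa_config()].
#' @param metrics COP metrics to compute alongside `eei`: any of
#'   `"ellipse_area_95"`, `"path_length"`, `"dfa_alpha_ap"` (all by default).
#' @param outlier_k SD multiplier of the outlier screen (default 3).
#' @param ba_k Bland-Altman limits-of-agreement multiplier (default 1.96).
#' @return An object of class `sot_results`: a list with
#'   \describe{
#'     \item{conditions}{per-condition tibble of agreement statistics and
#'       metric correlations,}
#'     \item{pairs}{the retained per-participant paired scores and metrics,}
#'     \item{exclusions}{the outlier log,}
#'     \item{config}{the configuration used.}
#'   }
#'   Supports [generics::tidy()], [generics::glance()],
#'   [ggplot2::autoplot()] and [write_sot_results()].
#' @export
run_sot_pipeline <- function(study,
                             preprocess = preprocess_config(),
                             ei = ei_params(),
                             dfa = dfa_config(),
                             metrics = c("ellipse_area_95", "path_length",
                                         "dfa_alpha_ap"),
                             outlier_k = 3, ba_k = 1.96) {
  stopifnot(inherits(study, "sot_study"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  sel <- select_analysis_trials(study)
  codes <- paste0("SOT", 1:6)

  eq <- sel %>%
    dplyr::filter(.data$device == "equitest") %>%
    dplyr::select("pid", "condition", "ei")

  heights <- stats::setNames(study$participants$height,
                             study$participants$pid)
  vr <- sel %>%
    dplyr::filter(.data$device == "vr", .data$condition %in% codes)
  vr_metrics <- purrr::pmap_dfr(
    list(vr$pid, vr$condition, vr$trace),
    function(pid, condition, trace) {
      pp <- preprocess_trace(trace, preprocess)
      row <- tibble::tibble(
        pid = pid, condition = condition,
        eei = estimated_equilibrium_index(pp, heights[[pid]], ei))
      if ("ellipse_area_95" %in% metrics) {
        row$ellipse_area_95 <- ellipse_area_95(pp)
      }
      if ("path_length" %in% metrics) row$path_length <- path_length(pp)
      if ("dfa_alpha_ap" %in% metrics) {
        row$dfa_alpha_ap <- tryCatch(dfa_alpha(pp$ap, config = dfa),
                                     sot_degenerate_error = function(e)
                                       NA_real_)
      }
      row
    })

  pairs_all <- dplyr::inner_join(eq, vr_metrics, by = c("pid", "condition"))
  kept <- exclude_outlier_pairs(pairs_all, ei, eei, k = outlier_k)
  exclusions <- attr(kept, "exclusions")

  conditions <- purrr::map_dfr(codes, function(cc) {
    sub <- dplyr::filter(kept, .data$condition == cc)
    n_pairs <- sum(pairs_all$condition == cc)
    agr <- if (nrow(sub) >= 3) {
      tryCatch(agreement_stats(sub, ei, eei, ba_k = ba_k),
               error = function(e) na_agreement_row(nrow(sub)))
    } else {
      if (n_pairs > 0) {
        rlang::warn(paste0(cc, ": fewer than 3 retained pairs; ",
                           "statistics reported as missing."))
      }
      na_agreement_row(nrow(sub))
    }
    out <- tibble::tibble(condition = cc, n_pairs = n_pairs,
                          n_retained = nrow(sub))
    out <- dplyr::bind_cols(out, agr %>% dplyr::select(-"n"))
    for (m in metrics) {
      short <- c(ellipse_area_95 = "ellipse", path_length = "path",
                 dfa_alpha_ap = "dfa")[[m]]
      pe <- if (nrow(sub) >= 3) safe_pearson(sub$ei, sub[[m]]) else
        tibble::tibble(r = NA_real_, p = NA_real_)
      out[[paste0("r_", short)]] <- pe$r
      out[[paste0("p_", short)]] <- pe$p
    }
    out
  })

  structure(list(conditions = conditions,
                 pairs = kept %>% dplyr::select(-dplyr::any_of(character())),
                 exclusions = exclusions,
                 config = list(preprocess = preprocess, ei = ei, dfa = dfa,
                               metrics = metrics, outlier_k = outlier_k,
                               ba_k = ba_k)),
            class = "sot_results")
}

#' @export
print.sot_results <- function(x, digits = 3, ...) {
  cat("SOT between-device agreement analysis\n")
  cat(sprintf("  %d condition(s); %d retained pair rows; %d excluded entr%s\n",
              nrow(x$conditions), nrow(x$pairs), nrow(x$exclusions),
              if (nrow(x$exclusions) == 1) "y" else "ies"))
  show <- x$conditions %>%
    dplyr::select("condition", "n_retained", "icc_absolute",
                  "icc_consistency", "pearson_r", "pearson_p")
  print(show, digits = digits)
  invisible(x)
}

#' Tidy the per-condition correlation table of a pipeline result
#'
#' Returns the per-condition Pearson correlations between the Equitest
#' equilibrium index and each COP-derived measure in long form, one row per
#' (condition, metric), with interpretation labels.
#'
#' @param x A `sot_results` object.
#' @param ... Unused.
#' @return A tibble with columns `condition`, `metric`, `r`, `p`, `label`.
#' @method tidy sot_results
#' @export
tidy.sot_results <- function(x, ...) {
  base <- x$conditions %>%
    dplyr::transmute(.data$condition, metric = "eei",
                     r = .data$pearson_r, p = .data$pearson_p)
  short <- c(ellipse_area_95 = "ellipse", path_length = "path",
             dfa_alpha_ap = "dfa")
  extra <- purrr::map_dfr(x$config$metrics, function(m) {
    s <- short[[m]]
    x$conditions %>%
      dplyr::transmute(.data$condition, metric = m,
                       r = .data[[paste0("r_", s)]],
                       p = .data[[paste0("p_", s)]])
  })
  dplyr::bind_rows(base, extra) %>%
    dplyr::mutate(label = interpret_r(.data$r)) %>%
    dplyr::arrange(.data$condition)
}

#' One-row summary of a pipeline result
#'
#' @param x A `sot_results` object.
#' @param ... Unused.
#' @return A one-row tibble with pair counts, exclusion count, and the
#'   median ICCs across conditions.
#' @method glance sot_results
#' @export
glance.sot_results <- function(x, ...) {
  tibble::tibble(
    n_conditions = nrow(x$conditions),
    n_pairs = sum(x$conditions$n_pairs),
    n_retained = sum(x$conditions$n_retained),
    n_excluded_entries = nrow(x$exclusions),
    median_icc_absolute = stats::median(x$conditions$icc_absolute,
                                        na.rm = TRUE),
    median_icc_consistency = stats::median(x$conditions$icc_consistency,
                                           na.rm = TRUE))
}

#' Plot a pipeline result
#'
#' `type = "bland_altman"` draws, per condition, the device difference
#' (eEI - EI) against the pair mean with the mean difference (solid) and
#' limits of agreement (dashed).  `type = "boxplot"` draws the score
#' distributions per condition and device.
#'
#' @param object A `sot_results` object.
#' @param type `"bland_altman"` or `"boxplot"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sot_results
#' @export
autoplot.sot_results <- function(object, type = c("bland_altman", "boxplot"),
                                 ...) {
  type <- match.arg(type)
  pairs <- object$pairs
  if (type == "bland_altman") {
    lines <- object$conditions %>%
      dplyr::select("condition", "ba_mean_diff", "ba_loa_low", "ba_loa_high")
    ggplot2::ggplot(pairs,
                    ggplot2::aes(x = (.data$ei + .data$eei) / 2,
                                 y = .data$eei - .data$ei)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_hline(data = lines,
                          ggplot2::aes(yintercept = .data$ba_mean_diff)) +
      ggplot2::geom_hline(data = lines,
                          ggplot2::aes(yintercept = .data$ba_loa_low),
                          linetype = "dashed") +
      ggplot2::geom_hline(data = lines,
                          ggplot2::aes(yintercept = .data$ba_loa_high),
                          linetype = "dashed") +
      ggplot2::facet_wrap(~condition) +
      ggplot2::labs(x = "Mean of EI and eEI (score)",
                    y = "eEI - EI (score)",
                    title = "Bland-Altman agreement per SOT condition")
  } else {
    long <- pairs %>%
      dplyr::select("pid", "condition", "ei", "eei") %>%
      tidyr::pivot_longer(c("ei", "eei"), names_to = "device",
                          values_to = "score") %>%
      dplyr::mutate(device = dplyr::recode(.data$device,
                                           ei = "Equitest EI",
                                           eei = "VR eEI"))
    ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$score,
                                       fill = .data$device)) +
      ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
      ggplot2::labs(x = "Condition", y = "Equilibrium score",
                    fill = NULL,
                    title = "Score distributions per condition and device")
  }
}

#' Write pipeline outputs to a directory
#'
#' Emits `results.csv` (the per-condition statistics table),
#' `exclusions.log` (one line per flagged entry) and, when `plots = TRUE`,
#' a `figures/` directory with the Bland-Altman and boxplot figures.
#'
#' @param results A `sot_results` object.
#' @param dir Output directory (created if needed).
#' @param plots Also write figures (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_sot_results <- function(results, dir, plots = FALSE) {
  stopifnot(inherits(results, "sot_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(results$conditions, file.path(dir, "results.csv"),
                   progress = FALSE)
  log <- results$exclusions
  lines <- if (nrow(log) == 0) "no exclusions" else
    sprintf("%s %s %s score=%.3f flagged beyond %g SD",
            log$condition, log$pid, log$device, log$score,
            results$config$outlier_k)
  writeLines(lines, file.path(dir, "exclusions.log"))
  if (plots) {
    dir.create(file.path(dir, "figures"), showWarnings = FALSE)
    ggplot2::ggsave(file.path(dir, "figures", "bland_altman.png"),
                    autoplot(results, "bland_altman"),
                    width = 8, height = 6, dpi = 150)
    ggplot2::ggsave(file.path(dir, "figures", "boxplot.png"),
                    autoplot(results, "boxplot"),
                    width = 8, height = 5, dpi = 150)
  }
  invisible(dir)
}
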