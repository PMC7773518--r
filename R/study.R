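#' Condition codes accepted in a study
#'
#' `SOT1`..`SOT6` are the six sensory organization test conditions shared by
#' both devices.  `VRX1` and `VRX2` are the two head-tracking-only VR
#' environments (stable and foam surface) that complete the 28-trial session
#' but have no Equitest counterpart; they are carried in the study container
#' and ignored by the agreement pipeline.
#' @keywords internal
sot_condition_codes <- function() {
  c(paste0("SOT", 1:6), "VRX1", "VRX2")
}

trial_key <- function(trials) {
  paste(trials$pid, trials$condition, trials$device, trials$trial_index,
        sep = "\r")
}

#' Assemble a posturography study
#'
#' Bundles participant metadata with trial records.  Equitest trials carry a
#' scalar equilibrium index (EI, 0-100); VR trials carry a [cop_trace()].
#'
#' @param participants Data frame with columns `pid` (unique id) and `height`
#'   (metres, in (0.5, 2.5)); optional `mass` (kg), `sex`, `age` (years).
#' @param trials Data frame with columns `pid`, `condition`
#'   (see [sot_condition_codes()]), `device` (`"equitest"` or `"vr"`),
#'   `trial_index` (1-based integer), `ei` (score, `NA` for VR trials) and
#'   `trace` (list column of [cop_trace()], `NULL` for Equitest trials).
#' @return An object of class `sot_study`: a list with tibbles `participants`
#'   and `trials`, trials in canonical (pid, condition, device, trial_index)
#'   order.
#' @export
sot_study <- function(participants, trials) {
  participants <- tibble::as_tibble(participants)
  trials <- tibble::as_tibble(trials)

  for (col in c("mass", "sex", "age")) {
    if (!col %in% names(participants)) participants[[col]] <- NA
  }
  participants <- participants[, c("pid", "height", "mass", "sex", "age")]
  participants$pid <- as.character(participants$pid)

  if (anyDuplicated(participants$pid)) {
    abort("duplicate participant ids.", class = "sot_study_error")
  }
  bad_h <- !is.finite(participants$height) |
    participants$height <= 0.5 | participants$height >= 2.5
  if (nrow(participants) > 0 && any(bad_h)) {
    abort("participant heights must be finite and in (0.5, 2.5) m.",
          class = "sot_study_error")
  }

  if (nrow(trials) > 0) {
    if (!"ei" %in% names(trials)) trials$ei <- NA_real_
    if (!"trace" %in% names(trials)) trials$trace <- list(NULL)
    trials$pid <- as.character(trials$pid)
    trials$condition <- as.character(trials$condition)
    trials$device <- as.character(trials$device)
    trials$trial_index <- as.integer(trials$trial_index)
    trials$ei <- as.double(trials$ei)

    if (!all(trials$device %in% c("equitest", "vr"))) {
      abort("device must be 'equitest' or 'vr'.", class = "sot_study_error")
    }
    if (!all(trials$condition %in% sot_condition_codes())) {
      abort(paste0("unknown condition code(s): ",
                   paste(setdiff(trials$condition, sot_condition_codes()),
                         collapse = ", ")),
            class = "sot_study_error")
    }
    eq <- trials$device == "equitest"
    if (any(eq & !trials$condition %in% paste0("SOT", 1:6))) {
      abort("equitest trials must use conditions SOT1..SOT6.",
            class = "sot_study_error")
    }
    if (any(eq & (!is.finite(trials$ei) | trials$ei < 0 | trials$ei > 100))) {
      abort("equitest trials need an equilibrium index in [0, 100].",
            class = "sot_study_error")
    }
    ok_trace <- vapply(trials$trace, inherits, logical(1), what = "cop_trace")
    if (any(!eq & !ok_trace)) {
      abort("vr trials need a valid cop_trace payload.",
            class = "sot_study_error")
    }
    orphan <- setdiff(trials$pid, participants$pid)
    if (length(orphan)) {
      abort(paste0("trial(s) reference unknown participant(s): ",
                   paste(unique(orphan), collapse = ", ")),
            class = "sot_study_error")
    }
    if (anyDuplicated(trial_key(trials))) {
      abort("duplicate (pid, condition, device, trial_index) trial key.",
            class = "sot_study_error")
    }
    trials <- dplyr::arrange(trials, .data$pid, .data$condition,
                             .data$device, .data$trial_index)
  } else {
    trials <- tibble::tibble(pid = character(), condition = character(),
                             device = character(), trial_index = integer(),
                             ei = double(), trace = list())
  }

  structure(list(participants = dplyr::arrange(participants, .data$pid),
                 trials = trials),
            class = "sot_study")
}

#' @export
print.sot_study <- function(x, ...) {
  cat(sprintf("<sot_study: %d participants, %d trials (%d equitest, %d vr)>\n",
              nrow(x$participants), nrow(x$trials),
              sum(x$trials$device == "equitest"),
              sum(x$trials$device == "vr")))
  invisible(x)
}

#' Load a study from a manifest
#'
#' The manifest is a YAML file with optional scalar fields `units`
#' (`m`/`cm`/`mm`, default `m`) and `fs` (Hz), a `participants` list
#' (`pid`, `height`, optional `mass`, `sex`, `age`) and a `trials` list.
#' Equitest trial entries carry `ei`; VR entries carry `path` to a trace CSV,
#' resolved relative to the manifest location.
#'
#' Loading is order-independent: permuting manifest entries yields an
#' identical study.
#'
#' @param manifest Path to the manifest YAML file.
#' @return A [sot_study()].
#' @export
load_study <- function(manifest) {
  if (!file.exists(manifest)) {
    abort(paste0("manifest not found: ", manifest), class = "sot_io_error")
  }
  m <- yaml::read_yaml(manifest)
  units <- m$units %||% "m"
  fs <- m$fs
  base <- dirname(manifest)

  participants <- purrr::map_dfr(m$participants, function(p) {
    if (is.null(p$pid) || is.null(p$height)) {
      abort("each participant needs `pid` and `height`.",
            class = "sot_manifest_error")
    }
    tibble::tibble(pid = as.character(p$pid),
                   height = as.double(p$height),
                   mass = as.double(p$mass %||% NA_real_),
                   sex = as.character(p$sex %||% NA_character_),
                   age = as.double(p$age %||% NA_real_))
  })
  if (is.null(m$participants)) {
    participants <- tibble::tibble(pid = character(), height = double(),
                                   mass = double(), sex = character(),
                                   age = double())
  }

  trials <- purrr::map_dfr(m$trials, function(tr) {
    need <- c("pid", "condition", "device", "trial_index")
    if (!all(need %in% names(tr))) {
      abort(paste0("trial entry is missing field(s): ",
                   paste(setdiff(need, names(tr)), collapse = ", ")),
            class = "sot_manifest_error")
    }
    if (identical(tr$device, "equitest")) {
      if (is.null(tr$ei)) {
        abort("equitest trial entries need an `ei` score.",
              class = "sot_manifest_error")
      }
      tibble::tibble(pid = as.character(tr$pid),
                     condition = as.character(tr$condition),
                     device = "equitest",
                     trial_index = as.integer(tr$trial_index),
                     ei = as.double(tr$ei), trace = list(NULL))
    } else {
      if (is.null(tr$path)) {
        abort("vr trial entries need a `path` to a trace CSV.",
              class = "sot_manifest_error")
      }
      trace <- read_cop_trace(file.path(base, tr$path),
                              fs_hint = tr$fs %||% fs, units = units)
      tibble::tibble(pid = as.character(tr$pid),
                     condition = as.character(tr$condition),
                     device = as.character(tr$device),
                     trial_index = as.integer(tr$trial_index),
                     ei = NA_real_, trace = list(trace))
    }
  })
  if (is.null(m$trials)) {
    trials <- tibble::tibble(pid = character(), condition = character(),
                             device = character(), trial_index = integer(),
                             ei = double(), trace = list())
  }

  sot_study(participants, trials)
}

#' Write a study to a manifest plus trace CSVs
#'
#' Produces a directory holding `manifest.yaml`, one trace CSV per VR trial
#' under `traces/`, and -- when the study carries a simulation truth record
#' (see [simulate_study()]) -- a `truth.json`.  The result can be read back
#' with [load_study()].
#'
#' @param study A [sot_study()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sot_study"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)

  part_list <- purrr::pmap(study$participants, function(pid, height, mass,
                                                        sex, age) {
    p <- list(pid = pid, height = height)
    if (!is.na(mass)) p$mass <- mass
    if (!is.na(sex)) p$sex <- sex
    if (!is.na(age)) p$age <- age
    p
  })

  trial_list <- purrr::pmap(study$trials, function(pid, condition, device,
                                                   trial_index, ei, trace) {
    if (device == "equitest") {
      list(pid = pid, condition = condition, device = device,
           trial_index = trial_index, ei = ei)
    } else {
      rel <- file.path("traces", sprintf("%s_%s_%s_%d.csv", pid, condition,
                                         device, trial_index))
      write_cop_trace(trace, file.path(dir, rel))
      list(pid = pid, condition = condition, device = device,
           trial_index = trial_index, path = rel,
           fs = sampling_rate(trace))
    }
  })

  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(units = "m", participants = part_list,
                        trials = trial_list), manifest)

  truth <- attr(study, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest)
}
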