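#' Experimental condition labels
#'
#' The four within-session conditions: a rest control and three remote
#' handgrip contractions defined by \%-of-peak-force and hold duration.
#' `40%30s` and `80%15s` are impulse matched; `40%15s` carries half their
#' impulse.
#'
#' @return Character vector of condition labels in canonical order.
#' @export
pic_conditions <- function() c("Control", "40%15s", "40%30s", "80%15s")

#' Phase labels (before/after the interspersed condition)
#' @return Character vector `c("before", "after")`.
#' @export
pic_phases <- function() c("before", "after")

# slugs used in fixture file names (no "%" on disk)
condition_slug <- function(condition) {
  slugs <- c("Control" = "control", "40%15s" = "c40p15s",
             "40%30s" = "c40p30s", "80%15s" = "c80p15s")
  unname(slugs[condition])
}

#' Construct a ramp trial
#'
#' One triangular dorsiflexion contraction: the performed torque trace, the
#' requested (target) triangular path and the participant's peak torque from
#' the maximal voluntary contraction.
#'
#' @param participant_id Participant identifier.
#' @param condition One of [pic_conditions()].
#' @param phase `"before"` or `"after"`.
#' @param torque_raw Numeric vector of performed torque samples (N·m).
#' @param fs Sampling frequency (Hz).
#' @param peak_torque Peak voluntary torque (N·m), the normalisation base.
#' @param target_path Numeric vector of requested torque samples (N·m),
#'   same length as `torque_raw`.
#' @return An object of class `ramp_trial`.
#' @export
ramp_trial <- function(participant_id, condition, phase,
                       torque_raw, fs, peak_torque, target_path) {
  condition <- match.arg(condition, pic_conditions())
  phase <- match.arg(phase, pic_phases())
  if (length(torque_raw) != length(target_path)) {
    stop("torque_raw and target_path must have the same length", call. = FALSE)
  }
  if (!isTRUE(fs > 0)) stop("fs must be > 0", call. = FALSE)
  if (!isTRUE(peak_torque > 0)) stop("peak_torque must be > 0", call. = FALSE)
  structure(
    list(participant_id = as.character(participant_id), condition = condition,
         phase = phase, torque_raw = as.numeric(torque_raw), fs = fs,
         peak_torque = peak_torque, target_path = as.numeric(target_path),
         qc = NULL),
    class = "ramp_trial")
}

#' @method print ramp_trial
#' @export
print.ramp_trial <- function(x, ...) {
  cat(sprintf("<ramp_trial> %s / %s / %s: %d samples @ %g Hz, peak %.1f N·m\n",
              x$participant_id, x$condition, x$phase,
              length(x$torque_raw), x$fs, x$peak_torque))
  invisible(x)
}

#' Trial duration in seconds
#' @param trial A `ramp_trial`.
#' @return Duration (s).
#' @export
trial_duration <- function(trial) (length(trial$torque_raw) - 1) / trial$fs

#' Time axis of a trial (t = 0 at ramp onset)
#' @param trial A `ramp_trial`.
#' @return Numeric vector of sample times (s).
#' @export
trial_time <- function(trial) seq(0, by = 1 / trial$fs,
                                  length.out = length(trial$torque_raw))

#' Build a table of motor-unit spike trains
#'
#' One row per unit; `firing_times` is a list-column of strictly increasing
#' firing times (s, from ramp onset). `unit_id` is stable across the
#' before/after phases of a condition so units can be matched.
#'
#' @param unit_id,participant_id,condition,phase,pnr_db Per-unit metadata;
#'   `pnr_db` is the decomposition pulse-to-noise ratio in dB.
#' @param firing_times List of numeric vectors of firing times (s).
#' @param duration Optional trial duration (s) used to validate that all
#'   firing times fall inside the ramp window.
#' @return A tibble with class `mu_trains`.
#' @export
mu_trains <- function(unit_id, participant_id, condition, phase,
                      firing_times, pnr_db, duration = NULL) {
  tr <- tibble::tibble(
    unit_id = as.character(unit_id),
    participant_id = as.character(participant_id),
    condition = condition, phase = phase,
    pnr_db = as.numeric(pnr_db),
    firing_times = lapply(firing_times, as.numeric))
  validate_trains(tr, duration = duration)
  tr
}

validate_trains <- function(trains, duration = NULL) {
  for (i in seq_len(nrow(trains))) {
    ft <- trains$firing_times[[i]]
    id <- trains$unit_id[i]
    if (length(ft) && any(diff(ft) <= 0)) {
      stop(sprintf("firing times of unit '%s' are not strictly increasing", id),
           call. = FALSE)
    }
    if (!is.null(duration) && length(ft) &&
        (min(ft) < 0 || max(ft) > duration + 1e-9)) {
      stop(sprintf("unit '%s' has firing times outside [0, %g] s", id, duration),
           call. = FALSE)
    }
  }
  invisible(trains)
}

#' Apply the pulse-to-noise-ratio retention gate
#'
#' Units decomposed with a pulse-to-noise ratio below `min_pnr_db` (default
#' 30 dB, the standard reliability cut-off) are removed.
#'
#' @param trains A `mu_trains` tibble.
#' @param min_pnr_db Retention threshold (dB).
#' @return The retained rows; the number excluded is attached as
#'   attribute `"n_excluded_pnr"`.
#' @export
apply_pnr_gate <- function(trains, min_pnr_db = 30) {
  keep <- trains$pnr_db >= min_pnr_db
  out <- trains[keep, , drop = FALSE]
  attr(out, "n_excluded_pnr") <- sum(!keep)
  out
}

# mark units not present in both phases of their participant x condition cell
flag_unmatched <- function(trains) {
  key <- paste(trains$participant_id, trains$condition, trains$unit_id)
  phases_per_unit <- tapply(trains$phase, key, function(p) length(unique(p)))
  trains$matched <- phases_per_unit[key] == 2L
  trains
}

#' Read a simulated or recorded study from its on-disk fixture dialect
#'
#' The dialect is plain text: a JSON manifest naming, per trial, a torque
#' file (`time_s,torque_Nm,target_Nm`) and a spike file
#' (`unit_id,firing_time_s`), plus per-unit pulse-to-noise ratios.
#' Units with PNR < 30 dB are excluded (count reported); units present in
#' only one phase are retained but flagged `matched = FALSE`.
#'
#' @param manifest_path Path to the manifest JSON (file paths inside are
#'   resolved relative to its directory).
#' @param min_pnr_db PNR retention threshold (dB).
#' @return A list with elements `trials` (list of bundles, each
#'   `list(trial = ramp_trial, trains = mu_trains)`) and
#'   `n_excluded_pnr`.
#' @export
read_study_inputs <- function(manifest_path, min_pnr_db = 30) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest not found: %s", manifest_path), call. = FALSE)
  }
  root <- dirname(manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  n_excluded <- 0L
  all_trains <- list()
  bundles <- list()
  for (tr in man$trials) {
    tq_path <- file.path(root, tr$torque_file)
    sp_path <- file.path(root, tr$spikes_file)
    for (p in c(tq_path, sp_path)) {
      if (!file.exists(p)) stop(sprintf("missing file: %s", p), call. = FALSE)
    }
    tq <- readr::read_csv(tq_path, show_col_types = FALSE, progress = FALSE)
    trial <- ramp_trial(tr$participant_id, tr$condition, tr$phase,
                        torque_raw = tq$torque_Nm, fs = tr$fs,
                        peak_torque = tr$peak_torque,
                        target_path = tq$target_Nm)
    sp <- readr::read_csv(sp_path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(unit_id = readr::col_character()))
    ids <- unique(sp$unit_id)
    pnr <- unlist(tr$pnr_db)
    if (!all(ids %in% names(pnr))) {
      stop(sprintf("missing pnr_db for unit(s): %s",
                   paste(setdiff(ids, names(pnr)), collapse = ", ")),
           call. = FALSE)
    }
    trains <- mu_trains(
      unit_id = ids, participant_id = tr$participant_id,
      condition = tr$condition, phase = tr$phase,
      firing_times = lapply(ids, function(id) sp$firing_time_s[sp$unit_id == id]),
      pnr_db = pnr[ids], duration = trial_duration(trial))
    trains <- apply_pnr_gate(trains, min_pnr_db)
    n_excluded <- n_excluded + attr(trains, "n_excluded_pnr")
    bundles[[length(bundles) + 1L]] <- list(trial = trial, trains = trains)
  }
  # matching is within participant x condition, across the two bundles
  pooled <- dplyr::bind_rows(lapply(bundles, function(b)
    b$trains[, c("unit_id", "participant_id", "condition", "phase")]))
  if (nrow(pooled)) {
    pooled <- flag_unmatched(pooled)
    for (i in seq_along(bundles)) {
      b <- bundles[[i]]
      key <- paste(b$trains$participant_id, b$trains$condition, b$trains$unit_id)
      pkey <- paste(pooled$participant_id, pooled$condition, pooled$unit_id)
      bundles[[i]]$trains$matched <- pooled$matched[match(key, pkey)]
    }
  }
  if (n_excluded > 0) {
    message(sprintf("read_study_inputs: excluded %d unit(s) with PNR < %g dB",
                    n_excluded, min_pnr_db))
  }
  list(trials = bundles, n_excluded_pnr = n_excluded)
}

outcome_columns <- function() {
  c("unit_id", "participant_id", "condition", "phase", "delta_f",
    "brace_height", "attenuation_slope", "peak_discharge_rate",
    "recruitment_threshold", "derecruitment_threshold", "n_control_units")
}

#' Write the per-test-unit outcome table
#'
#' Rows are written in a deterministic order (participant, condition in
#' canonical order, phase before/after, unit) so identical analyses yield
#' byte-identical files.
#'
#' @param rows Tibble of per-unit outcomes (columns as produced by
#'   [analyze_study()]).
#' @param dest Destination path (CSV, "." decimal, UTF-8).
#' @return `dest`, invisibly.
#' @export
write_outcomes <- function(rows, dest) {
  stopifnot(nrow(rows) > 0)
  rows <- rows[, outcome_columns()]
  ord <- order(rows$participant_id,
               match(rows$condition, pic_conditions()),
               match(rows$phase, pic_phases()),
               rows$unit_id)
  readr::write_csv(rows[ord, ], dest, progress = FALSE)
  invisible(dest)
}

#' Read an outcome table written by [write_outcomes()]
#' @param path CSV path.
#' @return Tibble of per-unit outcomes.
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing file: %s", path), call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(unit_id = readr::col_character(),
                                          participant_id = readr::col_character()))
}

#' Write a simulated study to the fixture dialect
#'
#' Emits the manifest JSON, per-trial torque and spike CSVs and (when
#' present) the simulator's ground-truth table, in the format
#' [read_study_inputs()] consumes. Deterministic: the same study object
#' produces byte-identical files.
#'
#' @param study A study as returned by [simulate_study()], or any list with
#'   `trials` bundles.
#' @param dir Output directory (created if absent).
#' @return Path to the manifest, invisibly.
#' @export
write_study_fixtures <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(trials = list())
  for (b in study$trials) {
    trial <- b$trial; trains <- b$trains
    stem <- sprintf("%s_%s_%s", trial$participant_id,
                    condition_slug(trial$condition), trial$phase)
    tq_file <- paste0(stem, "_torque.csv")
    sp_file <- paste0(stem, "_spikes.csv")
    readr::write_csv(tibble::tibble(
      time_s = trial_time(trial),
      torque_Nm = trial$torque_raw,
      target_Nm = trial$target_path), file.path(dir, tq_file), progress = FALSE)
    sp <- tibble::tibble(
      unit_id = rep(trains$unit_id, lengths(trains$firing_times)),
      firing_time_s = unlist(trains$firing_times))
    readr::write_csv(sp, file.path(dir, sp_file), progress = FALSE)
    man$trials[[length(man$trials) + 1L]] <- list(
      participant_id = trial$participant_id, condition = trial$condition,
      phase = trial$phase, fs = trial$fs, peak_torque = trial$peak_torque,
      torque_file = tq_file, spikes_file = sp_file,
      pnr_db = as.list(setNames(trains$pnr_db, trains$unit_id)))
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(study$ground_truth)) {
    readr::write_csv(study$ground_truth, file.path(dir, "ground_truth.csv"),
                     progress = FALSE)
  }
  invisible(path)
}
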