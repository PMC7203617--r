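#' Code a session's world-gaze stream frame by frame
#'
#' Attributes each frame to its stimulus window, applies the epoch
#' assignment (frames in segments with no assigned model are marked
#' dropped), and codes the remaining frames to F/L/R/N against the screen
#' geometry. Dot-event frames never belong to a stimulus window.
#'
#' @param gaze Tibble with `frame`, `x`, `y` (world-gaze coordinates).
#' @param schedule A [make_schedule()] object.
#' @param epochs An `epoch_assignment` (e.g. [assign_epochs()] or
#'   [identity_epochs()]).
#' @param geometry A [screen_geometry()].
#' @return A tibble of class `coded_frames`: `frame`, `trial`,
#'   `stimulus_id`, `true_emotion`, `code` (factor F/L/R/N), `dropped`.
#'   Only stimulus-window frames are returned.
#' @export
code_frames_session <- function(gaze, schedule, epochs,
                                geometry = screen_geometry()) {
  if (max(gaze$frame) > schedule$n_frames || min(gaze$frame) < 1) {
    stop("gaze stream frame range does not match the schedule", call. = FALSE)
  }
  att <- frame_attribution(schedule)
  st <- schedule$stimuli
  is_stim <- !is.na(att$stim[gaze$frame])
  g <- gaze[is_stim, ]
  si <- att$stim[g$frame]
  # epoch lookup: NA epoch_id -> dropped
  ep_idx <- findInterval(g$frame, epochs$start_frame)
  ep_idx[ep_idx < 1] <- NA
  dropped <- is.na(ep_idx) | is.na(epochs$epoch_id[ep_idx]) |
    g$frame > epochs$end_frame[pmax(ep_idx, 1)]
  out <- tibble::tibble(
    frame = g$frame,
    trial = st$trial[si],
    stimulus_id = st$stimulus_id[si],
    true_emotion = st$true_emotion[si],
    code = code_frame(g$x, g$y, geometry),
    dropped = dropped
  )
  class(out) <- c("coded_frames", class(out))
  out
}

#' Per-stimulus F/L/R/N frame counts
#'
#' Tallies coded frames into per-stimulus `(nF, nL, nR, nN)` count tuples.
#' Dropped frames (no applicable calibration model) are excluded from the
#' counts but reflected in `n_window` vs `nF + nL + nR + nN`. Every
#' scheduled stimulus gets a row, all-zero when every frame was dropped.
#'
#' @param coded A `coded_frames` tibble from [code_frames_session()].
#' @param schedule The session's [make_schedule()] object.
#' @return A tibble: `trial`, `stimulus_id`, `true_emotion`, `nF`, `nL`,
#'   `nR`, `nN`, `n_window`.
#' @export
stimulus_counts <- function(coded, schedule) {
  st <- schedule$stimuli
  kept <- coded[!coded$dropped, ]
  tab <- table(factor(kept$stimulus_id, levels = st$stimulus_id), kept$code)
  counts <- tibble::tibble(
    trial = st$trial,
    stimulus_id = st$stimulus_id,
    true_emotion = st$true_emotion,
    nF = as.integer(tab[, "F"]),
    nL = as.integer(tab[, "L"]),
    nR = as.integer(tab[, "R"]),
    nN = as.integer(tab[, "N"]),
    n_window = st$duration_frames
  )
  counts
}

#' Code a session end to end
#'
#' Convenience wrapper: [code_frames_session()] then [stimulus_counts()].
#'
#' @inheritParams code_frames_session
#' @return Per-stimulus counts tibble (see [stimulus_counts()]).
#' @export
code_session <- function(gaze, schedule, epochs,
                         geometry = screen_geometry()) {
  stimulus_counts(code_frames_session(gaze, schedule, epochs, geometry),
                  schedule)
}

#' Exclude unusable participant-trials
#'
#' Automated surrogate for the discard-on-inspection rule: a trial is
#' dropped outright when its trackable-frame fraction (frames retained by
#' epoch assignment divided by total stimulus-window frames) falls below
#' `min_fraction`.
#'
#' @param counts Counts tibble (optionally with a `participant_id` column
#'   when several sessions are stacked).
#' @param min_fraction Minimum trackable fraction (default 0.5).
#' @return List with `counts` (filtered) and `report` (tibble of dropped
#'   trials: participant, trial, fraction, reason).
#' @export
exclude_outliers <- function(counts, min_fraction = 0.5) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  has_p <- "participant_id" %in% names(counts)
  grp <- if (has_p) c("participant_id", "trial") else "trial"
  quality <- counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      fraction = sum(.data$nF + .data$nL + .data$nR + .data$nN) /
        sum(.data$n_window),
      .groups = "drop"
    )
  bad <- quality[quality$fraction < min_fraction, ]
  if (nrow(bad) > 0) {
    bad$reason <- sprintf("trackable fraction %.2f below %.2f",
                          bad$fraction, min_fraction)
    keep <- !do.call(paste, counts[grp]) %in% do.call(paste, bad[grp])
    counts <- counts[keep, ]
  } else {
    bad$reason <- character(0)
  }
  list(counts = counts, report = bad)
}
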