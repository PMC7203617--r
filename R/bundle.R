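#' Write a synthetic session bundle to disk
#'
#' Serializes a study's tables in plain formats: `participants.csv`,
#' `schedule.json`, `responses.csv`, per-participant
#' `gaze_<id>.csv` / `pupil_<id>.csv` streams, and (optionally, for
#' testing) `truth/` with latent codes and calibration coefficients.
#'
#' @param dir Output directory (created if needed).
#' @param participants Cohort tibble.
#' @param schedule A `stim_schedule`.
#' @param responses Response tibble (optional).
#' @param gaze,pupil Named lists (by participant id) of stream tibbles
#'   (optional).
#' @param truth A `calibration_truth` (optional; written under `truth/`).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(dir, participants, schedule,
                                 responses = NULL, gaze = NULL,
                                 pupil = NULL, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pt <- participants[, setdiff(names(participants), "confusion_profile")]
  utils::write.csv(pt, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(stimuli = schedule$stimuli, dot_events = schedule$dot_events,
         frame_rate = schedule$frame_rate, n_frames = schedule$n_frames,
         trial_sizes = schedule$trial_sizes),
    file.path(dir, "schedule.json"), dataframe = "columns", digits = NA
  )
  if (!is.null(responses)) {
    utils::write.csv(responses, file.path(dir, "responses.csv"),
                     row.names = FALSE)
  }
  for (nm in names(gaze)) {
    utils::write.csv(gaze[[nm]], file.path(dir, sprintf("gaze_%s.csv", nm)),
                     row.names = FALSE)
  }
  for (nm in names(pupil)) {
    utils::write.csv(pupil[[nm]],
                     file.path(dir, sprintf("pupil_%s.csv", nm)),
                     row.names = FALSE)
  }
  if (!is.null(truth)) {
    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
    utils::write.csv(as.data.frame(truth),
                     file.path(dir, "truth", "calibration.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a session bundle written by [write_session_bundle()]
#'
#' @param dir Bundle directory.
#' @return List with `participants`, `schedule` (a `stim_schedule`),
#'   `responses` (or `NULL`), and named lists `gaze`, `pupil`.
#' @export
read_session_bundle <- function(dir) {
  participants <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "participants.csv"))
  )
  sj <- jsonlite::read_json(file.path(dir, "schedule.json"),
                            simplifyVector = TRUE)
  schedule <- list(
    stimuli = tibble::as_tibble(sj$stimuli),
    dot_events = tibble::as_tibble(sj$dot_events),
    frame_rate = sj$frame_rate, n_frames = sj$n_frames,
    trial_sizes = sj$trial_sizes
  )
  class(schedule) <- "stim_schedule"
  rp <- file.path(dir, "responses.csv")
  responses <- if (file.exists(rp)) tibble::as_tibble(utils::read.csv(rp))
  read_streams <- function(prefix) {
    fs <- list.files(dir, pattern = sprintf("^%s_.*\\.csv$", prefix),
                     full.names = TRUE)
    out <- lapply(fs, function(f) tibble::as_tibble(utils::read.csv(f)))
    names(out) <- sub(sprintf("^%s_(.*)\\.csv$", prefix), "\\1",
                      basename(fs))
    out
  }
  list(participants = participants, schedule = schedule,
       responses = responses, gaze = read_streams("gaze"),
       pupil = read_streams("pupil"))
}
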