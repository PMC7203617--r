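#' Build a stimulus schedule
#'
#' Constructs the frame-level timeline of an emotion-recognition session:
#' successive trials of facial stimuli (each shown for `stim_secs` seconds
#' with one distractor image on either side), with a central validation dot
#' (`dot_secs` seconds) inserted after every block of eight stimuli within a
#' trial. Emotions are balanced across the seven-emotion set within each
#' trial up to the division remainder; presentation order is shuffled by
#' `seed`. Trial 2 is the feedback trial by default (the session in which
#' the correct emotion is announced after 3 s).
#'
#' @param trial_sizes Stimuli per trial; default `c(41, 42, 41)`.
#' @param frame_rate Frames per second (default 30).
#' @param seed Integer seed for emotion assignment and order.
#' @param stim_secs,dot_secs Stimulus and dot durations in seconds.
#' @param feedback_trial Index of the feedback trial (`NA` for none).
#' @return An object of class `stim_schedule`: a list with
#'   `stimuli` (tibble: `trial`, `stimulus_index`, `stimulus_id`,
#'   `true_emotion`, `onset_frame`, `duration_frames`, `feedback`,
#'   `left_distractor`, `right_distractor`), `dot_events` (tibble:
#'   `trial`, `start_frame`, `duration_frames`), `frame_rate`, `n_frames`,
#'   `trial_sizes`.
#' @examples
#' sched <- make_schedule(seed = 7)
#' nrow(sched$stimuli)          # 124
#' sched$stimuli$duration_frames[1]  # 180 at 30 fps
#' @export
make_schedule <- function(trial_sizes = c(41, 42, 41), frame_rate = 30,
                          seed = 1, stim_secs = 6, dot_secs = 5,
                          feedback_trial = 2) {
  stopifnot(length(trial_sizes) >= 1, all(trial_sizes >= 1), frame_rate >= 1)
  stim_frames <- round(frame_rate * stim_secs)
  dot_frames <- round(frame_rate * dot_secs)
  emo <- emotion_levels()
  distractors <- c("lego", "train", "car")

  with_seed(seed, {
    frame <- 1L
    stim_rows <- list()
    dot_rows <- list()
    for (t in seq_along(trial_sizes)) {
      s_n <- trial_sizes[t]
      # balanced emotion multiset, remainder assigned at random
      base <- rep(emo, s_n %/% length(emo))
      rem <- s_n %% length(emo)
      if (rem > 0) base <- c(base, sample(emo, rem))
      emotions <- sample(base) # shuffle presentation order
      pair <- t(replicate(s_n, sample(distractors, 2)))
      onset <- integer(s_n)
      for (s in seq_len(s_n)) {
        onset[s] <- frame
        frame <- frame + stim_frames
        if (s %% 8 == 0) { # dot after every complete block of eight
          dot_rows[[length(dot_rows) + 1]] <- tibble::tibble(
            trial = t, start_frame = frame, duration_frames = dot_frames
          )
          frame <- frame + dot_frames
        }
      }
      stim_rows[[t]] <- tibble::tibble(
        trial = t,
        stimulus_index = seq_len(s_n),
        stimulus_id = sprintf("t%d_s%02d", t, seq_len(s_n)),
        true_emotion = emotions,
        onset_frame = onset,
        duration_frames = stim_frames,
        feedback = isTRUE(t == feedback_trial),
        left_distractor = pair[, 1],
        right_distractor = pair[, 2]
      )
    }
    out <- list(
      stimuli = dplyr::bind_rows(stim_rows),
      dot_events = dplyr::bind_rows(dot_rows),
      frame_rate = frame_rate,
      n_frames = frame - 1L,
      trial_sizes = trial_sizes
    )
    class(out) <- "stim_schedule"
    out
  })
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf(
    "<stim_schedule> %d trials (%s stimuli), %d dot events, %d frames @ %g fps\n",
    length(x$trial_sizes), paste(x$trial_sizes, collapse = "/"),
    nrow(x$dot_events), x$n_frames, x$frame_rate
  ))
  invisible(x)
}

# per-frame stimulus attribution; cached on the schedule's environment would
# be overkill -- this is one allocation of n_frames integers.
# Returns list(stim = integer index into schedule$stimuli or NA,
#              dot = logical)
frame_attribution <- function(schedule) {
  n <- schedule$n_frames
  stim <- rep(NA_integer_, n)
  st <- schedule$stimuli
  for (i in seq_len(nrow(st))) {
    stim[st$onset_frame[i]:(st$onset_frame[i] + st$duration_frames[i] - 1L)] <- i
  }
  dot <- rep(FALSE, n)
  de <- schedule$dot_events
  for (i in seq_len(nrow(de))) {
    dot[de$start_frame[i]:(de$start_frame[i] + de$duration_frames[i] - 1L)] <- TRUE
  }
  list(stim = stim, dot = dot)
}
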