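#' Simulate emotion responses for a cohort
#'
#' Each participant answers every stimulus with an emotion drawn from the
#' row of their confusion profile corresponding to the true emotion. On the
#' feedback trial (where the correct label is announced mid-stimulus) the
#' row is interpolated toward the correct answer:
#' `row' = (1 - boost) * row + boost * e_true`, i.e. the diagonal is
#' boosted and the row renormalized; `boost = 1` makes every feedback-trial
#' response correct.
#'
#' @param participants Cohort tibble from [make_cohort()].
#' @param schedule A [make_schedule()] object.
#' @param feedback_boost Probability shift toward the correct answer on
#'   feedback trials (default 0.3).
#' @param seed Integer seed.
#' @return Tibble `participant_id`, `trial`, `stimulus_id`,
#'   `true_emotion`, `response`.
#' @export
simulate_responses <- function(participants, schedule, feedback_boost = 0.3,
                               seed = 1) {
  stopifnot(feedback_boost >= 0, feedback_boost <= 1)
  emo <- emotion_levels()
  st <- schedule$stimuli
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(participants)), function(i) {
      prof <- participants$confusion_profile[[i]]
      if (any(abs(rowSums(prof) - 1) > 1e-9)) {
        stop("confusion profile rows must sum to 1", call. = FALSE)
      }
      resp <- character(nrow(st))
      for (s in seq_len(nrow(st))) {
        row <- prof[st$true_emotion[s], ]
        if (st$feedback[s]) {
          e <- as.numeric(emo == st$true_emotion[s])
          row <- (1 - feedback_boost) * row + feedback_boost * e
        }
        resp[s] <- sample(emo, 1, prob = row)
      }
      tibble::tibble(
        participant_id = participants$participant_id[i],
        trial = st$trial, stimulus_id = st$stimulus_id,
        true_emotion = st$true_emotion, response = resp
      )
    })
  })
}
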