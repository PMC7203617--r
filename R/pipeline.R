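#' Simulate and code a whole cohort's gaze sessions
#'
#' Runs the generator-to-coding path for every participant: simulate the
#' world-gaze stream, code frames against the geometry (single identity
#' calibration epoch; use the explicit calibration functions to exercise
#' the pupil/calibration stages), tally per-stimulus counts, and compute
#' distraction ratios. Per-participant seeds derive from `seed`.
#'
#' @param participants Cohort tibble from [make_cohort()].
#' @param schedule A [make_schedule()] object.
#' @param geometry A [screen_geometry()].
#' @param noise_sd Gaze angular noise SD.
#' @param dwell Markov stickiness.
#' @param seed Integer master seed.
#' @param keep_frames Also return the per-participant coded frame tibbles
#'   (needed for gaze features; default `TRUE`).
#' @return List with `records` (stacked [distraction_ratios()] tibble with
#'   `participant_id`) and `coded` (named list of `coded_frames`, or
#'   `NULL`).
#' @export
simulate_coded_cohort <- function(participants, schedule,
                                  geometry = screen_geometry(),
                                  noise_sd = 0.01, dwell = 0.9, seed = 1,
                                  keep_frames = TRUE) {
  eps <- identity_epochs(schedule)
  coded_list <- list()
  records <- purrr::map_dfr(seq_len(nrow(participants)), function(i) {
    pid <- participants$participant_id[i]
    gs <- simulate_gaze(participants[i, ], schedule, geometry,
                        noise_sd = noise_sd, dwell = dwell,
                        seed = derive_seed(seed, i))
    coded <- code_frames_session(gs, schedule, eps, geometry)
    if (keep_frames) coded_list[[pid]] <<- coded
    counts <- stimulus_counts(coded, schedule)
    counts$participant_id <- pid
    distraction_ratios(counts)
  })
  list(records = records, coded = if (keep_frames) coded_list else NULL)
}

#' Run the full synthetic study once
#'
#' Generates a cohort, schedule, gaze and response data, and produces the
#' distraction-hypothesis report and the feature table for classification.
#'
#' @param n_asd,n_nc Group sizes.
#' @param seed Integer master seed.
#' @param trial_sizes,frame_rate Passed to [make_schedule()].
#' @param noise_sd,dwell Passed to [simulate_coded_cohort()].
#' @param feedback_boost Passed to [simulate_responses()].
#' @param params Cohort parameters, see [cohort_defaults()].
#' @return List with `participants`, `schedule`, `records`, `h1`,
#'   `features`, `responses`.
#' @export
run_synthetic_study <- function(n_asd = 16, n_nc = 17, seed = 1,
                                trial_sizes = c(41, 42, 41),
                                frame_rate = 30, noise_sd = 0.01,
                                dwell = 0.9, feedback_boost = 0.3,
                                params = cohort_defaults()) {
  participants <- make_cohort(n_asd, n_nc, seed = derive_seed(seed, 1),
                              params = params)
  schedule <- make_schedule(trial_sizes, frame_rate,
                            seed = derive_seed(seed, 2))
  sim <- simulate_coded_cohort(participants, schedule, noise_sd = noise_sd,
                               dwell = dwell, seed = derive_seed(seed, 3))
  responses <- simulate_responses(participants, schedule,
                                  feedback_boost = feedback_boost,
                                  seed = derive_seed(seed, 4))
  h1 <- h1_report(sim$records, participants)
  features <- build_features(participants, responses, sim$coded, schedule)
  list(participants = participants, schedule = schedule,
       records = sim$records, h1 = h1, features = features,
       responses = responses)
}
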