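# shared fixtures, all generated in code

# a small schedule: one trial of 8 stimuli -> exactly one dot event
small_schedule <- function(seed = 11, frame_rate = 30) {
  make_schedule(trial_sizes = 8, frame_rate = frame_rate, seed = seed,
                feedback_trial = NA)
}

# a participant row with given latent propensities
fake_participant <- function(ld = 0.1, lo = 0.05, acc = 0.8,
                             id = "P01", group = "ASD") {
  tibble::tibble(
    participant_id = id, group = group, age = 10L, gender = "male",
    latent_distraction = ld, latent_offtask = lo, accuracy = acc,
    confusion_profile = list(phenogaze:::confusion_profile(acc))
  )
}

# counts row builder
counts_row <- function(nF, nL, nR, nN, trial = 1, id = "s1",
                       emotion = "happy", participant = "P01") {
  tibble::tibble(participant_id = participant, trial = trial,
                 stimulus_id = id, true_emotion = emotion,
                 nF = nF, nL = nL, nR = nR, nN = nN,
                 n_window = nF + nL + nR + nN)
}

# separable two-cluster feature table
separable_features <- function(n_per = 15, p = 4, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * p), n_per),
               matrix(rnorm(n_per * p, mean = gap), n_per))
    f <- tibble::as_tibble(X, .name_repair = ~ paste0("f", seq_len(p)))
    dplyr::bind_cols(
      tibble::tibble(
        participant_id = sprintf("P%02d", seq_len(2 * n_per)),
        group = rep(c("ASD", "NC"), each = n_per)
      ),
      f
    )
  })
}

# cohort parameters with both groups identical (null generator)
null_params <- function() {
  p <- cohort_defaults()
  p$distraction_mean <- mean(p$distraction_mean[1:2]) # same propensities
  p$distraction_sd <- 0.03
  p$accuracy_mean <- 0.8
  p$accuracy_sd <- 0.05
  p$offtask_mean <- 0.09
  p$male_prop <- 0.6
  p
}
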