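resp_tbl <- function(true, resp, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("t1_s%02d", seq_along(true))
  tibble::tibble(stimulus_id = ids, true_emotion = true, response = resp)
}

test_that("confusion matrix features normalize rows and flag empty ones", {
  emo <- emotion_levels()
  all_correct <- resp_tbl(emo, emo)
  v <- confusion_matrix_features(all_correct)
  expect_length(v, 49)
  m <- matrix(v, 7, 7, byrow = TRUE)
  expect_equal(m, diag(7), ignore_attr = TRUE)
  # 3 happy stimuli answered happy, happy, calm
  r <- resp_tbl(rep("happy", 3), c("happy", "happy", "calm"))
  v2 <- confusion_matrix_features(r)
  expect_equal(unname(v2["cm_happy_happy"]), 2 / 3)
  expect_equal(unname(v2["cm_happy_calm"]), 1 / 3)
  expect_true("sad" %in% attr(v2, "zero_rows"))
  expect_equal(sum(v2[paste0("cm_sad_", emo)]), 0)
  expect_error(confusion_matrix_features(resp_tbl("happy", "bored")),
               "bored")
})

test_that("confusion details are ordered binaries, one per stimulus", {
  true <- rep(c("happy", "sad"), 4)
  resp <- ifelse(seq_along(true) %% 2 == 1, true, "calm")
  v <- confusion_detail_features(resp_tbl(true, resp))
  expect_equal(unname(v), rep(c(1, 0), 4))
  expect_length(v, 8)
  expect_error(
    confusion_detail_features(resp_tbl("happy", NA_character_)),
    "missing"
  )
})

test_that("the three gaze quantities match a hand trace", {
  # sequence L, L, F, F, R, F
  v <- phenogaze:::gaze_stim_features(c("L", "L", "F", "F", "R", "F"), 6)
  expect_equal(unname(v["face_frac"]), 0.5)        # 3 F of 6 on-region
  expect_equal(unname(v["toward_face"]), 2 / 3)    # L>F, F>R, R>F
  expect_equal(unname(v["latency"]), 2)            # first F at index 2
  # all F: no distinct transition, zero latency
  v2 <- phenogaze:::gaze_stim_features(rep("F", 10), 10)
  expect_equal(unname(v2["face_frac"]), 1)
  expect_true(is.na(v2["toward_face"]))
  expect_equal(unname(v2["latency"]), 0)
  # never F: latency is the window length
  v3 <- phenogaze:::gaze_stim_features(rep(c("L", "N"), 90), 180)
  expect_equal(unname(v3["latency"]), 180)
  # empty window: everything undefined
  v4 <- phenogaze:::gaze_stim_features(character(0), 180)
  expect_true(all(is.na(v4)))
})

test_that("metadata features code age and gender as stated", {
  p <- tibble::tibble(participant_id = c("A", "B"), age = c(12L, 8L),
                      gender = c("male", "female"))
  m <- metadata_features(p)
  expect_equal(m$pat_age, c(12, 8))
  expect_equal(m$pat_gender, c(0, 1))
  p$age[1] <- NA
  expect_error(metadata_features(p), "metadata")
})

test_that("per-trial feature dimensionality identities hold", {
  co <- make_cohort(3, 3, seed = 5)
  sched <- make_schedule(c(41, 42, 41), seed = 5)
  sim <- simulate_coded_cohort(co, sched, seed = 6)
  resp <- simulate_responses(co, sched, seed = 7)
  # S = 42 trial: 49 + 42 + 126 + 2 = 219
  f2 <- build_features(co, resp, sim$coded, sched, trials = 2)
  expect_equal(ncol(f2) - 2, 219)
  # S = 41 trial: 49 + 41 + 123 + 2 = 215
  f1 <- build_features(co, resp, sim$coded, sched, trials = 1)
  expect_equal(ncol(f1) - 2, 215)
  # all trials concatenated, pat once
  fa <- build_features(co, resp, sim$coded, sched)
  expect_equal(ncol(fa) - 2, 3 * 49 + 124 + 3 * 124 + 2)
  expect_equal(sum(grepl("^pat_", names(fa))), 2)
  # pat-only: 2 columns whatever the trial subset
  fp <- build_features(co, resp, sim$coded, sched, families = "pat",
                       trials = 2)
  expect_equal(ncol(fp) - 2, 2)
  # dimension identity 4S + 51 for another generator-configured S
  sched_s <- make_schedule(14, seed = 3)
  sim_s <- simulate_coded_cohort(co, sched_s, seed = 8)
  resp_s <- simulate_responses(co, sched_s, seed = 9)
  fs <- build_features(co, resp_s, sim_s$coded, sched_s)
  expect_equal(ncol(fs) - 2, 4 * 14 + 51)
})

test_that("assembly is deterministic and order-stable", {
  co <- make_cohort(3, 3, seed = 5)
  sched <- make_schedule(14, seed = 3)
  sim <- simulate_coded_cohort(co, sched, seed = 6)
  resp <- simulate_responses(co, sched, seed = 7)
  a <- build_features(co, resp, sim$coded, sched)
  b <- build_features(co, resp, sim$coded, sched)
  expect_identical(a, b)
  # value invariants
  man <- attr(a, "manifest")
  conf_cols <- man$column[man$family == "conf"]
  expect_true(all(as.matrix(a[conf_cols]) %in% c(0, 1)))
  ff <- man$column[man$family == "gaze" & grepl("face_frac", man$column)]
  vals <- as.matrix(a[ff])
  expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
})

test_that("family/trial selection follows the manifest", {
  co <- make_cohort(2, 2, seed = 1)
  sched <- make_schedule(c(9, 9), seed = 2)
  sim <- simulate_coded_cohort(co, sched, seed = 3)
  resp <- simulate_responses(co, sched, seed = 4)
  f <- build_features(co, resp, sim$coded, sched)
  g1 <- select_features(f, c("gaze", "pat"), trials = 1)
  man <- attr(g1, "manifest")
  expect_setequal(unique(man$family), c("gaze", "pat"))
  expect_true(all(man$trial[man$family == "gaze"] == 1))
  expect_equal(ncol(g1) - 2, 3 * 9 + 2)
})
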