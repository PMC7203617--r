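test_that("the two distraction ratios evaluate as defined", {
  r <- distraction_ratios(counts_row(3, 1, 1, 5))
  expect_equal(r$d, 0.2)
  expect_equal(r$d_flr, 0.4)
  r2 <- distraction_ratios(counts_row(10, 0, 0, 0))
  expect_equal(r2$d, 0)
  expect_equal(r2$d_flr, 0)
  # all frames N: d = 0, the N-excluding variant is undefined
  r3 <- distraction_ratios(counts_row(0, 0, 0, 7))
  expect_equal(r3$d, 0)
  expect_true(is.na(r3$d_flr))
  expect_false(r3$flr_defined)
  # all counts zero: invalid
  r4 <- distraction_ratios(counts_row(0, 0, 0, 0))
  expect_false(r4$valid)
})

test_that("d never exceeds d_flr and both stay in the unit interval", {
  withr::with_seed(42, {
    counts <- tibble::tibble(
      nF = rpois(500, 30), nL = rpois(500, 3), nR = rpois(500, 3),
      nN = rpois(500, 10)
    )
  })
  r <- distraction_ratios(counts)
  ok <- r$flr_defined
  expect_true(all(r$d[ok] <= r$d_flr[ok] + 1e-12))
  expect_true(all(r$d >= 0 & r$d <= 1, na.rm = TRUE))
  expect_true(all(r$d_flr >= 0 & r$d_flr <= 1, na.rm = TRUE))
  expect_true(all((r$d == 0) == (counts$nL + counts$nR == 0)))
})

test_that("participant aggregation averages valid records and ignores invalid ones", {
  rec <- distraction_ratios(dplyr::bind_rows(
    counts_row(10, 0, 0, 0, id = "s1"),   # d = 0
    counts_row(8, 1, 1, 0, id = "s2"),    # d = 0.2
    counts_row(6, 2, 2, 0, id = "s3"),    # d = 0.4
    counts_row(0, 0, 0, 0, id = "s4")     # invalid
  ))
  agg <- aggregate_participants(rec)
  expect_equal(agg$d, 0.2)
  expect_equal(agg$n_records, 3L)
  # single record passes through
  expect_equal(aggregate_participants(
    distraction_ratios(counts_row(7, 3, 0, 0))
  )$d, 0.3)
  # participant with zero valid records is omitted with a warning
  rec2 <- distraction_ratios(dplyr::bind_rows(
    counts_row(5, 0, 0, 0, participant = "A"),
    counts_row(0, 0, 0, 0, participant = "B")
  ))
  expect_warning(out <- aggregate_participants(rec2), "B")
  expect_equal(out$participant_id, "A")
})

test_that("aggregation is invariant to stimulus order", {
  rec <- distraction_ratios(dplyr::bind_rows(
    counts_row(10, 2, 0, 3, id = "s1"),
    counts_row(4, 0, 1, 0, id = "s2"),
    counts_row(9, 9, 9, 9, id = "s3")
  ))
  expect_equal(aggregate_participants(rec)$d,
               aggregate_participants(rec[c(3, 1, 2), ])$d)
})

test_that("per-emotion N-excluding means use only defined cells", {
  rec <- distraction_ratios(dplyr::bind_rows(
    counts_row(9, 1, 0, 0, id = "s1", emotion = "happy"),   # d_flr = 0.1
    counts_row(18, 2, 0, 0, id = "s2", emotion = "happy"),  # d_flr = 0.1
    counts_row(0, 0, 0, 5, id = "s3", emotion = "sad"),     # undefined
    counts_row(1, 1, 0, 0, id = "s4", emotion = "sad")      # d_flr = 0.5
  ))
  pe <- per_emotion_flr(rec)
  expect_equal(pe$d_flr[pe$true_emotion == "happy"], 0.1)
  expect_equal(pe$d_flr[pe$true_emotion == "sad"], 0.5)
  expect_equal(pe$n[pe$true_emotion == "sad"], 1L)
})

test_that("group test matches a hand-coded Welch oracle", {
  withr::with_seed(7, {
    a <- rbeta(16, 0.5, 8)
    b <- rbeta(17, 0.3, 12)
  })
  res <- group_ttest(a, b)
  # independent closed-form Welch computation
  s1 <- var(a) / length(a); s2 <- var(b) / length(b)
  t_or <- (mean(a) - mean(b)) / sqrt(s1 + s2)
  df_or <- (s1 + s2)^2 / (s1^2 / (length(a) - 1) + s2^2 / (length(b) - 1))
  p_or <- pt(t_or, df_or, lower.tail = FALSE)
  expect_equal(res$t, t_or, tolerance = 1e-10)
  expect_equal(res$df, df_or, tolerance = 1e-10)
  expect_equal(res$p, p_or, tolerance = 1e-10)
})

test_that("group test handles symmetry, separation, and degeneracy", {
  same <- c(0.1, 0.2, 0.3)
  res <- group_ttest(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p, 0.5)
  withr::with_seed(1, {
    hi <- 1 + rnorm(3, 0, 1e-6)
    lo <- 0 + rnorm(3, 0, 1e-6)
  })
  expect_lt(group_ttest(hi, lo)$p, 0.001)
  deg <- group_ttest(c(0.2, 0.2, 0.2), c(0.2, 0.2))
  expect_equal(deg$p, 0.5)
  expect_true(deg$degenerate)
})

test_that("h1 report produces both tests and tidies cleanly", {
  co <- make_cohort(5, 5, seed = 2)
  sched <- small_schedule()
  sim <- simulate_coded_cohort(co, sched, seed = 3, keep_frames = FALSE)
  rep <- h1_report(sim$records, co)
  expect_s3_class(rep$participant_test, "h1_test")
  expect_true(rep$stimulus_test$independence_caveat)
  td <- tidy(rep$participant_test)
  expect_equal(td$p.value, rep$participant_test$p)
  expect_equal(nrow(rep$d_participant), 10)
})
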