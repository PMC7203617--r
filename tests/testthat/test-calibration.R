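affine_pairs <- function(n = 25, sx = 0.9, sy = 1.1, ox = 0.05, oy = -0.02,
                         seed = 1) {
  withr::with_seed(seed, {
    px <- runif(n); py <- runif(n)
    tibble::tibble(pupil_x = px, pupil_y = py,
                   world_x = sx * px + ox, world_y = sy * py + oy)
  })
}

test_that("affine maps are recovered exactly by degree-1 least squares", {
  p <- affine_pairs()
  m <- fit_calibration(p, degree = 1)
  expect_lt(m$residual, 1e-10)
  expect_equal(unname(m$coef["x1y0", "x"]), 0.9, tolerance = 1e-9)
  expect_equal(unname(m$coef["x0y0", "x"]), 0.05, tolerance = 1e-9)
  # held-out prediction matches the true map
  held <- predict_world(m, c(0.3, 0.7))
  expect_equal(held$x, 0.9 * 0.3 + 0.05, tolerance = 1e-9)
  expect_equal(held$y, 1.1 * 0.7 - 0.02, tolerance = 1e-9)
})

test_that("quadratic maps are recovered by degree-2 least squares", {
  withr::with_seed(2, {
    px <- runif(40); py <- runif(40)
    p <- tibble::tibble(
      pupil_x = px, pupil_y = py,
      world_x = 0.1 + 0.8 * px + 0.2 * px^2 - 0.1 * px * py,
      world_y = -0.05 + 1.2 * py + 0.15 * py^2 + 0.05 * px
    )
  })
  m <- fit_calibration(p, degree = 2)
  expect_lt(m$residual, 1e-8)
})

test_that("fit residual never increases with polynomial degree", {
  withr::with_seed(3, {
    p <- affine_pairs(30)
    p$world_x <- p$world_x + rnorm(30, 0, 0.02)
    p$world_y <- p$world_y + rnorm(30, 0, 0.02)
  })
  res <- vapply(1:3, function(d) fit_calibration(p, degree = d)$residual,
                numeric(1))
  expect_true(all(diff(res) <= 1e-12))
})

test_that("degenerate designs are rejected with informative errors", {
  p3 <- affine_pairs(3)
  expect_error(fit_calibration(p3, degree = 2), "insufficient")
  coll <- tibble::tibble(pupil_x = seq(0, 1, length.out = 10),
                         pupil_y = seq(0, 1, length.out = 10),
                         world_x = runif(10), world_y = runif(10))
  expect_error(fit_calibration(coll, degree = 1), "rank-deficient")
  p <- affine_pairs()
  p$world_x[1] <- Inf
  expect_error(fit_calibration(p, degree = 1), "finite")
  m <- fit_calibration(affine_pairs(), degree = 1)
  expect_error(predict_world(m, c(NA, 0.5)), "finite")
})

test_that("identity-fitted model reproduces its input", {
  p <- affine_pairs(sx = 1, sy = 1, ox = 0, oy = 0)
  m <- fit_calibration(p, degree = 1)
  out <- predict_world(m, tibble::tibble(x = c(0.2, 0.8), y = c(0.4, 0.6)))
  expect_equal(out$x, c(0.2, 0.8), tolerance = 1e-9)
  expect_equal(out$y, c(0.4, 0.6), tolerance = 1e-9)
})

test_that("dot residuals report the planted offset", {
  sched <- small_schedule()
  p <- fake_participant(ld = 0, lo = 0)
  g <- simulate_gaze(p, sched, noise_sd = 0, seed = 1)
  pu <- simulate_pupil(g, identity_truth(sched), pupil_noise = 0, seed = 1)
  m <- fit_calibration(affine_pairs(sx = 1, sy = 1, ox = 0, oy = 0),
                       degree = 1)
  r0 <- dot_residuals(m, pu, sched$dot_events)
  expect_lt(r0$median, 1e-9)
  # constant offset delta on one axis -> median error |delta|
  m_off <- m
  m_off$coef["x0y0", "x"] <- m_off$coef["x0y0", "x"] + 0.1
  r1 <- dot_residuals(m_off, pu, sched$dot_events)
  expect_equal(r1$median, 0.1, tolerance = 1e-9)
})

test_that("epoch assignment finds a planted mapping switch at the dot boundary", {
  sched <- make_schedule(24, seed = 6, feedback_trial = NA) # dots after 8, 16, 24
  p <- fake_participant(ld = 0.05, lo = 0.02)
  g <- simulate_gaze(p, sched, noise_sd = 0, seed = 2)
  switch_frame <- sched$dot_events$start_frame[2]
  truth <- tibble::tibble(
    epoch = 1:2,
    start_frame = c(1L, switch_frame),
    end_frame = c(switch_frame - 1L, sched$n_frames),
    sx = c(1, 0.85), sy = c(1, 1.1), ox = c(0, 0.06), oy = c(0, -0.05)
  )
  class(truth) <- c("calibration_truth", class(truth))
  pu <- simulate_pupil(g, truth, pupil_noise = 0, seed = 3)
  cal <- simulate_calibration_pairs(truth, pupil_noise = 0, seed = 4)
  models <- fit_session_calibration(cal, degree = 2)
  asg <- assign_epochs(pu, models, sched$dot_events)
  # boundary between model 1 and model 2 sits at the switch dot onset
  expect_equal(asg$epoch_id[asg$start_frame < switch_frame],
               rep(1L, sum(asg$start_frame < switch_frame)))
  expect_equal(asg$epoch_id[asg$start_frame >= switch_frame],
               rep(2L, sum(asg$start_frame >= switch_frame)))
  expect_true(switch_frame %in% asg$start_frame)
})

test_that("one correct model wins every segment; hopeless models assign none", {
  sched <- small_schedule()
  p <- fake_participant(ld = 0, lo = 0)
  g <- simulate_gaze(p, sched, noise_sd = 0, seed = 5)
  pu <- simulate_pupil(g, identity_truth(sched), pupil_noise = 0, seed = 1)
  good <- fit_calibration(affine_pairs(sx = 1, sy = 1, ox = 0, oy = 0),
                          degree = 1)
  asg <- assign_epochs(pu, list(good), sched$dot_events)
  expect_true(all(asg$epoch_id == 1))
  bad <- good
  bad$coef["x0y0", ] <- bad$coef["x0y0", ] + 0.5
  asg2 <- assign_epochs(pu, list(bad), sched$dot_events)
  expect_true(all(is.na(asg2$epoch_id)))
})

test_that("noiseless single-epoch pipeline reproduces latent codes end to end", {
  # generator -> pupil -> calibration -> coding joint round trip
  sched <- small_schedule()
  p <- fake_participant(ld = 0.35, lo = 0.15)
  g <- simulate_gaze(p, sched, noise_sd = 0, seed = 12)
  truth <- calibration_truth(sched, n_epochs = 1, seed = 2)
  pu <- simulate_pupil(g, truth, pupil_noise = 0, seed = 1)
  cal <- simulate_calibration_pairs(truth, pupil_noise = 0, seed = 3)
  models <- fit_session_calibration(cal, degree = 2)
  asg <- assign_epochs(pu, models, sched$dot_events)
  world <- phenogaze:::predict_world_na(models[[1]], pu$x, pu$y)
  gaze_hat <- tibble::tibble(frame = pu$frame, x = world[, 1], y = world[, 2])
  coded <- code_frames_session(gaze_hat, sched, asg)
  stim <- g[g$phase %in% "stimulus", ]
  expect_identical(as.character(coded$code), as.character(stim$code))
})
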