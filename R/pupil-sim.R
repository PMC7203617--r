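#' Ground-truth calibration epochs for a synthetic session
#'
#' Partitions the session into `n_epochs` contiguous frame intervals and
#' attaches to each an affine pupil-to-world mapping
#' `world = scale * pupil + offset` (per axis), emulating slow drift of a
#' head-mounted eye camera between recalibrations. Affine truth keeps the
#' inverse mapping (needed to synthesize pupil coordinates from world
#' coordinates) available in closed form; the fitting side supports higher
#' polynomial degrees regardless.
#'
#' @param schedule A [make_schedule()] object (for the frame count), or an
#'   integer frame count.
#' @param n_epochs Number of calibration epochs (default 4).
#' @param scale_range,offset_range Ranges for the per-axis scale and drift
#'   offset draws.
#' @param seed Integer seed.
#' @return An object of class `calibration_truth`: tibble with `epoch`,
#'   `start_frame`, `end_frame`, `sx`, `sy`, `ox`, `oy`.
#' @export
calibration_truth <- function(schedule, n_epochs = 4,
                              scale_range = c(0.9, 1.1),
                              offset_range = c(-0.04, 0.04), seed = 1) {
  n <- if (inherits(schedule, "stim_schedule")) schedule$n_frames else schedule
  stopifnot(n_epochs >= 1, n >= n_epochs)
  bounds <- floor(seq(0, n, length.out = n_epochs + 1))
  with_seed(seed, {
    out <- tibble::tibble(
      epoch = seq_len(n_epochs),
      start_frame = bounds[-length(bounds)] + 1L,
      end_frame = bounds[-1],
      sx = runif(n_epochs, scale_range[1], scale_range[2]),
      sy = runif(n_epochs, scale_range[1], scale_range[2]),
      ox = runif(n_epochs, offset_range[1], offset_range[2]),
      oy = runif(n_epochs, offset_range[1], offset_range[2])
    )
    class(out) <- c("calibration_truth", class(out))
    out
  })
}

#' Identity calibration truth (one epoch, world = pupil)
#' @param schedule Schedule or frame count as in [calibration_truth()].
#' @return A `calibration_truth` with a single identity epoch.
#' @export
identity_truth <- function(schedule) {
  n <- if (inherits(schedule, "stim_schedule")) schedule$n_frames else schedule
  out <- tibble::tibble(epoch = 1L, start_frame = 1L, end_frame = as.integer(n),
                        sx = 1, sy = 1, ox = 0, oy = 0)
  class(out) <- c("calibration_truth", class(out))
  out
}

truth_epoch_of <- function(truth, frame) {
  findInterval(frame, truth$start_frame)
}

# forward: world = s * pupil + o; inverse: pupil = (world - o) / s
truth_world_to_pupil <- function(truth, epoch, wx, wy) {
  e <- truth[epoch, ]
  if (any(abs(c(e$sx, e$sy)) < 1e-8)) {
    stop("epoch mapping is not invertible on the screen domain", call. = FALSE)
  }
  cbind((wx - e$ox) / e$sx, (wy - e$oy) / e$sy)
}

#' Synthesize an eye-camera pupil stream from a world-gaze stream
#'
#' Applies, frame by frame, the inverse of the epoch's ground-truth
#' pupil-to-world mapping to the world coordinate and adds isotropic
#' Gaussian measurement noise. Frames with missing gaze emit missing pupil
#' values.
#'
#' @param gaze Tibble with `frame`, `x`, `y` (world coordinates; `NA`
#'   allowed), e.g. from [simulate_gaze()].
#' @param truth A [calibration_truth()].
#' @param pupil_noise Noise SD in pupil (normalized) units.
#' @param seed Integer seed.
#' @return A tibble `frame`, `x`, `y`, `epoch` in eye-camera coordinates.
#' @export
simulate_pupil <- function(gaze, truth, pupil_noise = 0.005, seed = 1) {
  ep <- truth_epoch_of(truth, gaze$frame)
  if (any(ep < 1 | ep > nrow(truth)) ||
      any(gaze$frame > truth$end_frame[nrow(truth)])) {
    stop("every gaze frame must fall in exactly one epoch of the truth",
         call. = FALSE)
  }
  with_seed(seed, {
    n <- nrow(gaze)
    px <- rep(NA_real_, n); py <- rep(NA_real_, n)
    ok <- !is.na(gaze$x) & !is.na(gaze$y)
    for (e in unique(ep[ok])) {
      sel <- ok & ep == e
      pc <- truth_world_to_pupil(truth, e, gaze$x[sel], gaze$y[sel])
      px[sel] <- pc[, 1]; py[sel] <- pc[, 2]
    }
    if (pupil_noise > 0) {
      px[ok] <- px[ok] + rnorm(sum(ok), 0, pupil_noise)
      py[ok] <- py[ok] + rnorm(sum(ok), 0, pupil_noise)
    }
    tibble::tibble(frame = gaze$frame, x = px, y = py, epoch = ep)
  })
}

#' Synthesize calibration-pass pupil/world pairs
#'
#' Emulates the explicit calibration procedures (one per epoch) in which
#' the participant fixates a sequence of known on-screen targets: for each
#' epoch, world targets on a regular grid are mapped to pupil coordinates
#' through the inverse of that epoch's ground-truth mapping, plus Gaussian
#' measurement noise. These pairs are what per-epoch polynomial calibration
#' is fitted on.
#'
#' @param truth A [calibration_truth()].
#' @param n_grid Targets per axis (default 3, i.e. a 9-point grid).
#' @param reps Fixation samples per target (default 5).
#' @param pupil_noise Noise SD in pupil units.
#' @param seed Integer seed.
#' @return Tibble `epoch`, `world_x`, `world_y`, `pupil_x`, `pupil_y`.
#' @export
simulate_calibration_pairs <- function(truth, n_grid = 3, reps = 5,
                                       pupil_noise = 0.005, seed = 1) {
  g <- seq(0.15, 0.85, length.out = n_grid)
  grid <- expand.grid(wx = g, wy = g)
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(truth)), function(e) {
      wx <- rep(grid$wx, each = reps)
      wy <- rep(grid$wy, each = reps)
      pc <- truth_world_to_pupil(truth, e, wx, wy)
      tibble::tibble(
        epoch = truth$epoch[e],
        world_x = wx, world_y = wy,
        pupil_x = pc[, 1] + rnorm(length(wx), 0, pupil_noise),
        pupil_y = pc[, 2] + rnorm(length(wx), 0, pupil_noise)
      )
    })
  })
}

#' Render synthetic eye-camera frames
#'
#' Draws each pupil position as a dark anti-aliased disk on a bright iris
#' field, plus optional additive Gaussian noise. Normalized pupil
#' coordinates are scaled so the disk always lies fully inside the image.
#' Ground-truth pixel centers are returned alongside for detector
#' validation.
#'
#' @param pupil Tibble with `x`, `y` in `[0,1]` (rows with `NA` are
#'   rendered as blank frames).
#' @param image_size `c(width, height)` in pixels.
#' @param pupil_radius Disk radius in pixels.
#' @param noise_sd Additive noise SD (image dynamic range is 1).
#' @param seed Integer seed for the noise.
#' @return A list of class `eye_frames`: `frames` (list of height x width
#'   matrices in `[0,1]`-ish range) and `truth` (tibble `frame`, `cx`, `cy`
#'   in pixel coordinates, 1-based).
#' @export
render_eye_frames <- function(pupil, image_size = c(80, 60), pupil_radius = 8,
                              noise_sd = 0, seed = 1) {
  w <- image_size[1]; h <- image_size[2]
  if (pupil_radius >= min(w, h) / 2) {
    stop("pupil_radius must be smaller than half the image side", call. = FALSE)
  }
  pad <- pupil_radius + 3
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  bg <- 0.85; dark <- 0.12; edge <- 1.2
  with_seed(seed, {
    n <- nrow(pupil)
    frames <- vector("list", n)
    cx <- rep(NA_real_, n); cy <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      img <- matrix(bg, h, w)
      if (!is.na(pupil$x[i]) && !is.na(pupil$y[i])) {
        cx[i] <- pad + pupil$x[i] * (w - 2 * pad)
        cy[i] <- pad + pupil$y[i] * (h - 2 * pad)
        d <- sqrt((xs - cx[i])^2 + (ys - cy[i])^2)
        # smooth edge profile: dark inside, bg outside
        img <- dark + (bg - dark) / (1 + exp(-(d - pupil_radius) / edge * 4))
      }
      if (noise_sd > 0) img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
      frames[[i]] <- img
    }
    out <- list(frames = frames,
                truth = tibble::tibble(frame = seq_len(n), cx = cx, cy = cy))
    class(out) <- "eye_frames"
    out
  })
}
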