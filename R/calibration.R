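#' Bivariate monomial basis
#'
#' Columns `x^i * y^j` for all `i + j <= degree`, constant first.
#' @param x,y Coordinate vectors.
#' @param degree Polynomial degree (1-3 supported downstream).
#' @return Design matrix with named columns.
#' @keywords internal
poly_basis <- function(x, y, degree) {
  stopifnot(degree >= 0)
  cols <- list()
  nms <- character()
  for (d in 0:degree) {
    for (i in d:0) {
      j <- d - i
      cols[[length(cols) + 1]] <- x^i * y^j
      nms <- c(nms, paste0("x", i, "y", j))
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nms
  m
}

n_poly_coef <- function(degree) (degree + 1) * (degree + 2) / 2

#' Fit a polynomial gaze-calibration model
#'
#' Least-squares regression from pupil coordinates to world-gaze
#' coordinates over the full bivariate monomial basis up to `degree`, one
#' coefficient set per output axis. The world-coordinate targets are the
#' assumed true gaze directions (on-screen stimulus or dot positions).
#'
#' @param pairs Tibble/data frame with columns `pupil_x`, `pupil_y`,
#'   `world_x`, `world_y` (all finite).
#' @param degree Polynomial degree (default 2).
#' @param epoch_id Optional epoch label carried on the model.
#' @return An object of class `calibration_model`: list with `degree`,
#'   `coef` (coefficients x 2 matrix, columns `x` and `y`), `residual`
#'   (RMS prediction error in normalized screen units), `n_points`,
#'   `epoch_id`.
#' @examples
#' p <- tibble::tibble(pupil_x = runif(20), pupil_y = runif(20))
#' p$world_x <- 0.9 * p$pupil_x + 0.05
#' p$world_y <- 1.1 * p$pupil_y - 0.02
#' fit_calibration(p, degree = 1)$residual  # ~0
#' @export
fit_calibration <- function(pairs, degree = 2, epoch_id = NA_integer_) {
  stopifnot(all(c("pupil_x", "pupil_y", "world_x", "world_y") %in%
                  names(pairs)))
  if (!all(is.finite(pairs$pupil_x)) || !all(is.finite(pairs$pupil_y)) ||
      !all(is.finite(pairs$world_x)) || !all(is.finite(pairs$world_y))) {
    stop("calibration pairs must be finite", call. = FALSE)
  }
  k <- n_poly_coef(degree)
  if (nrow(pairs) < k) {
    stop(sprintf(
      "insufficient calibration points: %d pairs for %d coefficients per axis",
      nrow(pairs), k
    ), call. = FALSE)
  }
  X <- poly_basis(pairs$pupil_x, pairs$pupil_y, degree)
  qrx <- qr(X)
  if (qrx$rank < k) {
    stop(sprintf(
      "rank-deficient calibration design (rank %d < %d coefficients); pupil points are degenerate (e.g. collinear)",
      qrx$rank, k
    ), call. = FALSE)
  }
  bx <- qr.coef(qrx, pairs$world_x)
  by <- qr.coef(qrx, pairs$world_y)
  pred <- cbind(X %*% bx, X %*% by)
  res <- sqrt(mean((pred[, 1] - pairs$world_x)^2 +
                     (pred[, 2] - pairs$world_y)^2))
  out <- list(degree = degree,
              coef = cbind(x = bx, y = by),
              residual = res, n_points = nrow(pairs), epoch_id = epoch_id)
  class(out) <- "calibration_model"
  out
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> degree %d, %d points, RMS residual %.3g\n",
              x$degree, x$n_points, x$residual))
  invisible(x)
}

#' Predict world-gaze coordinates from pupil coordinates
#'
#' Evaluates both axis polynomials. Output may lie outside the unit screen;
#' downstream coding assigns such frames `N`.
#'
#' @param model A [fit_calibration()] model.
#' @param pupil Tibble with `x`, `y` (or `pupil_x`, `pupil_y`) columns, or a
#'   numeric length-2 vector.
#' @return A tibble with predicted `x`, `y`.
#' @export
predict_world <- function(model, pupil) {
  if (is.numeric(pupil) && length(pupil) == 2) {
    pupil <- tibble::tibble(x = pupil[1], y = pupil[2])
  }
  px <- if ("pupil_x" %in% names(pupil)) pupil$pupil_x else pupil$x
  py <- if ("pupil_y" %in% names(pupil)) pupil$pupil_y else pupil$y
  if (anyNA(px) || anyNA(py) || !all(is.finite(px)) || !all(is.finite(py))) {
    stop("pupil coordinates must be finite", call. = FALSE)
  }
  X <- poly_basis(px, py, model$degree)
  tibble::tibble(x = as.numeric(X %*% model$coef[, "x"]),
                 y = as.numeric(X %*% model$coef[, "y"]))
}

# world prediction allowing missing pupil frames (NA in -> NA out)
predict_world_na <- function(model, px, py) {
  ok <- !is.na(px) & !is.na(py)
  out <- matrix(NA_real_, length(px), 2)
  if (any(ok)) {
    X <- poly_basis(px[ok], py[ok], model$degree)
    out[ok, 1] <- X %*% model$coef[, "x"]
    out[ok, 2] <- X %*% model$coef[, "y"]
  }
  out
}

#' Validation-dot residuals of a calibration model
#'
#' Prediction error of a model against the central validation-dot target
#' over the frames of each dot event.
#'
#' @param model A [fit_calibration()] model.
#' @param pupil Tibble with `frame`, `x`, `y` (pupil coordinates).
#' @param dot_events Tibble with `start_frame`, `duration_frames`.
#' @param dot_target Screen location of the dot (default center).
#' @return A list with `per_dot` (tibble: `dot`, `n`, `median_error`) and
#'   overall `median` and `mean` error.
#' @export
dot_residuals <- function(model, pupil, dot_events,
                          dot_target = c(0.5, 0.5)) {
  stopifnot(nrow(dot_events) >= 1)
  per <- purrr::map_dfr(seq_len(nrow(dot_events)), function(i) {
    idx <- pupil$frame >= dot_events$start_frame[i] &
      pupil$frame < dot_events$start_frame[i] + dot_events$duration_frames[i]
    pw <- predict_world_na(model, pupil$x[idx], pupil$y[idx])
    err <- sqrt((pw[, 1] - dot_target[1])^2 + (pw[, 2] - dot_target[2])^2)
    tibble::tibble(dot = i, n = sum(!is.na(err)),
                   median_error = median(err, na.rm = TRUE))
  })
  all_err <- unlist(purrr::map(seq_len(nrow(dot_events)), function(i) {
    idx <- pupil$frame >= dot_events$start_frame[i] &
      pupil$frame < dot_events$start_frame[i] + dot_events$duration_frames[i]
    pw <- predict_world_na(model, pupil$x[idx], pupil$y[idx])
    sqrt((pw[, 1] - dot_target[1])^2 + (pw[, 2] - dot_target[2])^2)
  }))
  list(per_dot = per,
       median = median(all_err, na.rm = TRUE),
       mean = mean(all_err, na.rm = TRUE))
}

#' Assign calibration models to inter-dot segments
#'
#' Automated surrogate for the manual inspection step: the session is cut
#' into segments at validation-dot onsets, and each segment receives the
#' candidate model whose best adjacent-dot median error is smallest. A
#' segment whose best error still exceeds `threshold` (default: half the
#' face region's half-width, below which face/distractor discrimination is
#' impossible anyway) is assigned no model and its frames are dropped from
#' coding.
#'
#' @param pupil Tibble `frame`, `x`, `y`.
#' @param models List of [fit_calibration()] models (candidates).
#' @param dot_events Tibble with `start_frame`, `duration_frames`. With no
#'   dot events the whole session is assigned the model with the lowest fit
#'   residual (with a warning).
#' @param dot_target Dot location on screen.
#' @param threshold Maximum acceptable median dot error; `NULL` for the
#'   geometry-derived default.
#' @param geometry Geometry used for the default threshold.
#' @return A tibble of class `epoch_assignment`: `start_frame`,
#'   `end_frame`, `epoch_id` (index into `models`, `NA` for none), `score`.
#' @export
assign_epochs <- function(pupil, models, dot_events,
                          dot_target = c(0.5, 0.5), threshold = NULL,
                          geometry = screen_geometry()) {
  stopifnot(length(models) >= 1)
  if (is.null(threshold)) {
    threshold <- geometry$width[geometry$region == "F"] / 4
  }
  n_frames <- max(pupil$frame)
  if (is.null(dot_events) || nrow(dot_events) == 0) {
    warning("no dot events; assigning the lowest-fit-residual model to the whole session")
    best <- which.min(purrr::map_dbl(models, "residual"))
    out <- tibble::tibble(start_frame = 1L, end_frame = n_frames,
                          epoch_id = best, score = models[[best]]$residual)
    class(out) <- c("epoch_assignment", class(out))
    return(out)
  }
  dot_events <- dot_events[order(dot_events$start_frame), ]
  nd <- nrow(dot_events)
  # median error of each model at each dot
  err <- matrix(NA_real_, length(models), nd)
  for (m in seq_along(models)) {
    err[m, ] <- dot_residuals(models[[m]], pupil, dot_events,
                              dot_target)$per_dot$median_error
  }
  # segment boundaries at dot onsets
  starts <- c(1L, dot_events$start_frame)
  ends <- c(dot_events$start_frame - 1L, n_frames)
  keep <- ends >= starts
  starts <- starts[keep]; ends <- ends[keep]
  seg_dots <- purrr::map(seq_along(starts), function(s) {
    adj <- which(dot_events$start_frame >= starts[s] - 1L &
                   dot_events$start_frame <= ends[s] + 1L)
    if (length(adj) == 0) {
      # interior segment: nearest dots on either side
      before <- which(dot_events$start_frame < starts[s])
      after <- which(dot_events$start_frame > ends[s])
      adj <- c(tail(before, 1), head(after, 1))
    }
    adj
  })
  rows <- purrr::map_dfr(seq_along(starts), function(s) {
    sc <- apply(err[, seg_dots[[s]], drop = FALSE], 1, min, na.rm = TRUE)
    best <- which.min(sc)
    tibble::tibble(
      start_frame = starts[s], end_frame = ends[s],
      epoch_id = if (sc[best] <= threshold) best else NA_integer_,
      score = sc[best]
    )
  })
  class(rows) <- c("epoch_assignment", class(rows))
  rows
}

#' Single-epoch assignment covering a whole session
#'
#' Convenience for pipelines that bypass calibration (e.g. when coding the
#' generator's world-gaze stream directly): one segment, model 1.
#'
#' @param schedule Schedule or frame count.
#' @return An `epoch_assignment` tibble.
#' @export
identity_epochs <- function(schedule) {
  n <- if (inherits(schedule, "stim_schedule")) schedule$n_frames else schedule
  out <- tibble::tibble(start_frame = 1L, end_frame = as.integer(n),
                        epoch_id = 1L, score = 0)
  class(out) <- c("epoch_assignment", class(out))
  out
}

#' Extract pupil/world calibration pairs from a session
#'
#' Builds fitting pairs under the protocol's stated assumption that the
#' true gaze direction is the on-screen target: dot frames pair with the
#' dot location, stimulus frames with the face center.
#'
#' @param pupil Tibble `frame`, `x`, `y`.
#' @param schedule A [make_schedule()] object.
#' @param frames Optional frame range (two integers) restricting the pairs,
#'   e.g. one calibration epoch.
#' @param source `"dots"` (default), `"stimuli"`, or `"both"`.
#' @param dot_target,geometry Targets for the two sources.
#' @return Tibble `pupil_x`, `pupil_y`, `world_x`, `world_y`, `frame`.
#' @export
calibration_pairs <- function(pupil, schedule, frames = NULL,
                              source = c("dots", "stimuli", "both"),
                              dot_target = c(0.5, 0.5),
                              geometry = screen_geometry()) {
  source <- match.arg(source)
  att <- frame_attribution(schedule)
  sel_dot <- att$dot[pupil$frame]
  sel_stim <- !is.na(att$stim[pupil$frame])
  use <- switch(source, dots = sel_dot, stimuli = sel_stim,
                both = sel_dot | sel_stim)
  use <- use & !is.na(pupil$x) & !is.na(pupil$y)
  if (!is.null(frames)) {
    use <- use & pupil$frame >= frames[1] & pupil$frame <= frames[2]
  }
  fc <- region_center(geometry, "F")
  tibble::tibble(
    pupil_x = pupil$x[use], pupil_y = pupil$y[use],
    world_x = ifelse(sel_dot[use], dot_target[1], fc[1]),
    world_y = ifelse(sel_dot[use], dot_target[2], fc[2]),
    frame = pupil$frame[use]
  )
}

#' Fit the candidate calibration models from calibration-pass pairs
#'
#' One polynomial model per calibration pass, fitted on that pass's
#' pupil/world pairs (e.g. from [simulate_calibration_pairs()] or a real
#' calibration procedure's point sequence).
#'
#' @param pairs Tibble with `epoch`, `pupil_x`, `pupil_y`, `world_x`,
#'   `world_y`.
#' @param degree Polynomial degree (default 2).
#' @return List of `calibration_model`s, one per epoch, in epoch order.
#' @export
fit_session_calibration <- function(pairs, degree = 2) {
  stopifnot("epoch" %in% names(pairs))
  eps <- sort(unique(pairs$epoch))
  purrr::map(eps, function(e) {
    fit_calibration(pairs[pairs$epoch == e, ], degree = degree, epoch_id = e)
  })
}
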