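pupil_estimate <- function(x = NA_real_, y = NA_real_, confidence = 0,
                           method = "none") {
  tibble::tibble(x = x, y = y, confidence = confidence, method = method)
}

check_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a 2-D numeric matrix", call. = FALSE)
  }
  invisible(image)
}

# 3x3 box smoothing, edge-replicated
smooth3 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  pad <- img[c(1, 1:h, h), c(1, 1:w, w)]
  out <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    out <- out + pad[dy + 1:h, dx + 1:w]
  }
  out / 9
}

# central-difference gradients; list(gx, gy) with image convention
# x = column, y = row
image_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  list(gx = gx, gy = gy)
}

#' Detect dark pupil candidates with a stable-extremal-region sweep
#'
#' Sweeps intensity thresholds, labels the connected components of each
#' below-threshold mask, and scores each component chain's stability (the
#' relative area growth across neighboring thresholds, smaller = stabler).
#' Components passing area and eccentricity gates are returned as
#' candidate pupil centers, ranked by a confidence combining stability and
#' darkness.
#'
#' @param image 2-D numeric matrix (rows = y, columns = x), dark pupil on
#'   bright background.
#' @param thresholds Intensity levels swept (defaults to 19 levels spanning
#'   the image range).
#' @param min_area,max_area Component area gates as fractions of the image
#'   area (defaults 0.5% and 20%).
#' @param max_eccentricity Maximum major/minor axis ratio (default 2.5).
#' @return Tibble of candidates (`x`, `y`, `confidence`, `method`,
#'   `area`, `stability`), best first; zero rows when nothing passes.
#' @export
detect_mser <- function(image, thresholds = NULL, min_area = 0.005,
                        max_area = 0.2, max_eccentricity = 2.5) {
  check_image(image)
  h <- nrow(image); w <- ncol(image)
  npx <- h * w
  rng <- range(image)
  if (diff(rng) < 1e-9) {
    return(pupil_estimate()[0, ])
  }
  if (is.null(thresholds)) {
    thresholds <- seq(rng[1] + 0.05 * diff(rng), rng[2] - 0.05 * diff(rng),
                      length.out = 19)
  }
  nt <- length(thresholds)
  labels <- lapply(thresholds, function(t) {
    EBImage::bwlabel(image <= t)
  })
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  cand <- list()
  for (k in seq(2, nt - 1)) {
    lab <- labels[[k]]
    nlab <- max(lab)
    if (nlab == 0) next
    for (cc in seq_len(nlab)) {
      sel <- lab == cc
      area <- sum(sel)
      if (area < min_area * npx || area > max_area * npx) next
      # representative pixel: first of the component
      rep_i <- which(sel)[1]
      a_lo <- {
        l2 <- labels[[k - 1]][rep_i]
        if (l2 == 0) 0 else sum(labels[[k - 1]] == l2)
      }
      a_hi <- {
        l2 <- labels[[k + 1]][rep_i]
        if (l2 == 0) area else sum(labels[[k + 1]] == l2)
      }
      stab <- (a_hi - a_lo) / area
      cx <- mean(xs[sel]); cy <- mean(ys[sel])
      vx <- mean((xs[sel] - cx)^2); vy <- mean((ys[sel] - cy)^2)
      vxy <- mean((xs[sel] - cx) * (ys[sel] - cy))
      tr <- vx + vy; det <- vx * vy - vxy^2
      disc <- sqrt(max(tr^2 / 4 - det, 0))
      ecc <- sqrt(max(tr / 2 + disc, 1e-12) / max(tr / 2 - disc, 1e-12))
      if (ecc > max_eccentricity) next
      cand[[length(cand) + 1]] <- tibble::tibble(
        x = cx, y = cy, area = area, stability = stab,
        darkness = 1 - (image[rep_i] - rng[1]) / diff(rng)
      )
    }
  }
  if (length(cand) == 0) return(pupil_estimate()[0, ])
  cand <- dplyr::bind_rows(cand)
  # merge candidates within a small radius, keeping the stablest
  cand <- cand[order(cand$stability), ]
  kept <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) == 0 ||
        all((kept$x - cand$x[i])^2 + (kept$y - cand$y[i])^2 > 9)) {
      kept <- rbind(kept, cand[i, ])
    }
  }
  kept$confidence <- pmax(0, pmin(1, 1 / (1 + pmax(kept$stability, 0)))) *
    kept$darkness
  kept <- kept[order(-kept$confidence), ]
  tibble::tibble(x = kept$x, y = kept$y, confidence = kept$confidence,
                 method = "mser", area = kept$area,
                 stability = kept$stability)
}

#' Locate the pupil center with a means-of-gradients objective
#'
#' Finds the point maximizing the mean squared alignment between the unit
#' displacement vectors to strong-gradient pixels and the image gradient
#' directions there, weighted toward dark centers (inverted smoothed
#' intensity). The objective is evaluated on a stride-`stride` grid and
#' then refined at unit resolution around the best cell.
#'
#' @param image 2-D numeric matrix.
#' @param search_region Optional `c(xmin, xmax, ymin, ymax)` restriction of
#'   the candidate grid.
#' @param stride Coarse grid stride in pixels (default 2).
#' @param grad_quantile Quantile of gradient magnitude defining "strong"
#'   pixels (default 0.9).
#' @return One-row tibble `x`, `y`, `confidence`, `method`; confidence 0
#'   (and `NA` center) for a gradient-free image.
#' @export
detect_gradient <- function(image, search_region = NULL, stride = 2,
                            grad_quantile = 0.9) {
  check_image(image)
  h <- nrow(image); w <- ncol(image)
  g <- image_gradients(image)
  mag <- sqrt(g$gx^2 + g$gy^2)
  thr <- max(quantile(mag, grad_quantile), 1e-6)
  strong <- which(mag >= thr & mag > 0)
  if (length(strong) < 8) {
    return(pupil_estimate(method = "gradient"))
  }
  px <- ((strong - 1) %/% h) + 1 # column
  py <- ((strong - 1) %% h) + 1  # row
  gx <- g$gx[strong] / mag[strong]
  gy <- g$gy[strong] / mag[strong]
  sm <- smooth3(image)
  rngs <- range(sm)
  dark <- if (diff(rngs) > 1e-9) (rngs[2] - sm) / diff(rngs) else sm * 0 + 1
  lim <- if (is.null(search_region)) c(2, w - 1, 2, h - 1) else search_region
  cx <- seq(max(2, lim[1]), min(w - 1, lim[2]), by = stride)
  cy <- seq(max(2, lim[3]), min(h - 1, lim[4]), by = stride)
  grid <- expand.grid(x = cx, y = cy)
  wc <- dark[cbind(grid$y, grid$x)]
  obj <- .grad_objective(grid$x, grid$y, px, py, gx, gy, wc)
  best <- grid[which.max(obj), ]
  # unit-resolution refinement around the coarse optimum
  rx <- seq(max(2, best$x - stride), min(w - 1, best$x + stride))
  ry <- seq(max(2, best$y - stride), min(h - 1, best$y + stride))
  grid2 <- expand.grid(x = rx, y = ry)
  wc2 <- dark[cbind(grid2$y, grid2$x)]
  obj2 <- .grad_objective(grid2$x, grid2$y, px, py, gx, gy, wc2)
  b2 <- which.max(obj2)
  conf <- max(0, min(1, obj2[b2]))
  pupil_estimate(grid2$x[b2], grid2$y[b2], conf, "gradient")
}

# bilinear sample of img at (x, y) vectors (x = column, y = row)
bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 1), w); y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1); y0 <- pmin(floor(y), h - 1)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' Propagate a pupil center by local optical flow
#'
#' Iterative Lucas-Kanade estimation of the translation of an image window
#' centered on the previous pupil estimate; the center is shifted by the
#' estimated flow. Confidence decays with the post-warp residual.
#'
#' @param prev_image,image Consecutive 2-D numeric frames.
#' @param prev_center One-row estimate tibble (confidence must be > 0).
#' @param window Half-width of the flow window in pixels (default 12).
#' @param iterations Lucas-Kanade refinement iterations.
#' @return One-row estimate tibble with `method = "flow"`.
#' @export
propagate_flow <- function(prev_image, prev_center, image, window = 12,
                           iterations = 5) {
  check_image(prev_image); check_image(image)
  if (nrow(prev_center) != 1 || prev_center$confidence <= 0) {
    stop("prev_center must be a single estimate with confidence > 0",
         call. = FALSE)
  }
  h <- nrow(image); w <- ncol(image)
  cx <- prev_center$x; cy <- prev_center$y
  xs <- seq(max(2, round(cx) - window), min(w - 1, round(cx) + window))
  ys <- seq(max(2, round(cy) - window), min(h - 1, round(cy) + window))
  grid <- expand.grid(x = xs, y = ys)
  g <- image_gradients(prev_image)
  Ix <- g$gx[cbind(grid$y, grid$x)]
  Iy <- g$gy[cbind(grid$y, grid$x)]
  A <- cbind(Ix, Iy)
  AtA <- crossprod(A)
  if (abs(det(AtA)) < 1e-12) {
    return(pupil_estimate(method = "flow"))
  }
  I0 <- prev_image[cbind(grid$y, grid$x)]
  u <- c(0, 0)
  for (it in seq_len(iterations)) {
    I1 <- bilinear(image, grid$x + u[1], grid$y + u[2])
    It <- I1 - I0
    du <- -solve(AtA, crossprod(A, It))
    u <- u + as.numeric(du)
    if (sqrt(sum(du^2)) < 0.01) break
  }
  I1 <- bilinear(image, grid$x + u[1], grid$y + u[2])
  resid <- mean(abs(I1 - I0))
  conf <- prev_center$confidence * exp(-8 * resid)
  nx <- cx + u[1]; ny <- cy + u[2]
  if (nx < 1 || nx > w || ny < 1 || ny > h) {
    return(pupil_estimate(method = "flow"))
  }
  pupil_estimate(nx, ny, conf, "flow")
}

#' Fuse pupil estimates from the three detectors
#'
#' Gate-and-validate rule: when the means-of-gradients estimate
#' corroborates a stable extremal-region candidate within `gate` pixels,
#' the fused center is that candidate's centroid (region centroids
#' localize with subpixel precision; the gradient objective acts as the
#' validator) and the confidence is boosted by the agreement. Otherwise
#' the highest-confidence single estimate wins; otherwise the flow
#' propagation is passed through. With no usable input the frame is
#' marked untrackable (confidence 0).
#'
#' @param mser_candidates Candidate tibble from [detect_mser()] (may be
#'   empty).
#' @param gradient_est One-row tibble from [detect_gradient()] or `NULL`.
#' @param flow_est One-row tibble from [propagate_flow()] or `NULL`.
#' @param gate Agreement gate radius in pixels (default 3).
#' @return One-row estimate tibble.
#' @export
fuse_estimates <- function(mser_candidates = NULL, gradient_est = NULL,
                           flow_est = NULL, gate = 3) {
  has_grad <- !is.null(gradient_est) && nrow(gradient_est) == 1 &&
    gradient_est$confidence > 0
  has_mser <- !is.null(mser_candidates) && nrow(mser_candidates) > 0
  has_flow <- !is.null(flow_est) && nrow(flow_est) == 1 &&
    flow_est$confidence > 0
  if (has_grad && has_mser) {
    # the gradient estimate corroborates the top stable-region candidate
    dd <- sqrt((mser_candidates$x[1] - gradient_est$x)^2 +
                 (mser_candidates$y[1] - gradient_est$y)^2)
    if (dd <= gate) {
      agree <- 1 - dd / (2 * gate)
      return(pupil_estimate(
        mser_candidates$x[1], mser_candidates$y[1],
        min(1, agree * max(gradient_est$confidence,
                           mser_candidates$confidence[1]) + 0.1),
        "fused"
      ))
    }
  }
  singles <- dplyr::bind_rows(
    if (has_grad) gradient_est,
    if (has_mser) mser_candidates[1, c("x", "y", "confidence", "method")]
  )
  if (!is.null(singles) && nrow(singles) > 0 &&
      max(singles$confidence) > 0) {
    return(singles[which.max(singles$confidence), ])
  }
  if (has_flow) return(flow_est)
  pupil_estimate(method = "fused")
}

#' Track pupil centers across a frame sequence
#'
#' Runs the chosen detector (or the fused hybrid) on every frame,
#' propagating the previous estimate by optical flow for the fusion rule.
#'
#' @param frames An `eye_frames` object from [render_eye_frames()] or a
#'   list of 2-D numeric matrices.
#' @param method `"fused"` (default), `"gradient"`, `"mser"`, or `"flow"`.
#' @param gate Fusion gate radius.
#' @return Tibble `frame`, `x`, `y`, `confidence`, `method`.
#' @export
track_pupils <- function(frames, method = c("fused", "gradient", "mser",
                                            "flow"), gate = 3) {
  method <- match.arg(method)
  if (inherits(frames, "eye_frames")) frames <- frames$frames
  prev_est <- NULL
  prev_img <- NULL
  out <- purrr::map_dfr(seq_along(frames), function(i) {
    img <- frames[[i]]
    flow <- NULL
    if (!is.null(prev_est) && prev_est$confidence > 0 &&
        method %in% c("fused", "flow")) {
      flow <- propagate_flow(prev_img, prev_est, img)
    }
    est <- switch(
      method,
      gradient = detect_gradient(img),
      mser = {
        cand <- detect_mser(img)
        if (nrow(cand) > 0) cand[1, c("x", "y", "confidence", "method")]
        else pupil_estimate(method = "mser")
      },
      flow = {
        if (!is.null(flow)) flow
        else { # bootstrap the first frame with the gradient detector
          detect_gradient(img)
        }
      },
      fused = fuse_estimates(detect_mser(img), detect_gradient(img), flow,
                             gate = gate)
    )
    prev_est <<- est
    prev_img <<- img
    dplyr::bind_cols(tibble::tibble(frame = i), est)
  })
  out
}
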