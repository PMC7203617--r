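# deterministic frame with a disk at a chosen pixel center
disk_frame <- function(cx, cy, w = 80, h = 60, r = 8, dark = 0.12,
                       bg = 0.85) {
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  dark + (bg - dark) / (1 + exp(-(d - r) / 1.2 * 4))
}

test_that("rendering is deterministic and puts the darkest pixel in the disk", {
  pup <- tibble::tibble(x = c(0.2, 0.8), y = c(0.3, 0.6))
  a <- render_eye_frames(pup, noise_sd = 0.05, seed = 4)
  b <- render_eye_frames(pup, noise_sd = 0.05, seed = 4)
  expect_identical(a$frames, b$frames)
  clean <- render_eye_frames(pup, noise_sd = 0, seed = 1)
  for (i in 1:2) {
    img <- clean$frames[[i]]
    dk <- which(img == min(img), arr.ind = TRUE)[1, ]
    dist <- sqrt((dk["col"] - clean$truth$cx[i])^2 +
                   (dk["row"] - clean$truth$cy[i])^2)
    expect_lt(dist, 8) # inside the rendered pupil disk
  }
  expect_error(render_eye_frames(pup, image_size = c(40, 40),
                                 pupil_radius = 20), "radius")
})

test_that("gradient detector localizes a clean disk to within a pixel", {
  img <- disk_frame(40, 25)
  est <- detect_gradient(img)
  expect_lt(sqrt((est$x - 40)^2 + (est$y - 25)^2), 1)
  expect_gt(est$confidence, 0)
})

test_that("gradient detector is mirror-symmetric and rejects flat images", {
  img <- disk_frame(31, 22)
  est <- detect_gradient(img)
  mir <- img[, ncol(img):1]
  est_m <- detect_gradient(mir)
  expect_lt(abs((ncol(img) + 1 - est_m$x) - est$x), 1.01)
  expect_lt(abs(est_m$y - est$y), 1.01)
  flat <- matrix(0.5, 60, 80)
  est_f <- detect_gradient(flat)
  expect_equal(est_f$confidence, 0)
  expect_true(is.na(est_f$x))
  expect_error(detect_gradient(1:10), "matrix")
})

test_that("stable-region detector finds disks and ranks the darker one first", {
  img <- disk_frame(50, 30)
  cand <- detect_mser(img)
  expect_gte(nrow(cand), 1)
  expect_lt(sqrt((cand$x[1] - 50)^2 + (cand$y[1] - 30)^2), 1)
  # uniform image: nothing to detect
  expect_equal(nrow(detect_mser(matrix(0.5, 60, 80))), 0)
  # two disks, one darker: darker ranked first
  two <- pmin(disk_frame(20, 30, dark = 0.08), disk_frame(60, 30, dark = 0.45))
  cand2 <- detect_mser(two)
  expect_gte(nrow(cand2), 2)
  expect_lt(abs(cand2$x[1] - 20), 2)
})

test_that("flow propagation tracks translations and honors preconditions", {
  a <- disk_frame(40, 30)
  prev <- detect_gradient(a)
  # identical frames: no displacement
  same <- propagate_flow(a, prev, a)
  expect_equal(same$x, prev$x)
  expect_equal(same$y, prev$y)
  # pure 3 px horizontal shift
  b <- disk_frame(43, 30)
  fl <- propagate_flow(a, prev, b)
  expect_lt(abs(fl$x - prev$x - 3), 0.5)
  expect_lt(abs(fl$y - prev$y), 0.5)
  # zero-confidence previous estimate is rejected
  dead <- prev
  dead$confidence <- 0
  expect_error(propagate_flow(a, dead, b), "confidence")
})

test_that("fusion picks corroborated regions and falls back gracefully", {
  img <- disk_frame(35, 28)
  grad <- detect_gradient(img)
  cand <- detect_mser(img)
  fused <- fuse_estimates(cand, grad, NULL)
  expect_equal(fused$method, "fused")
  # corroborated: fused center is the validated region centroid
  expect_equal(fused$x, cand$x[1])
  expect_equal(fused$y, cand$y[1])
  expect_gt(fused$confidence, max(grad$confidence, cand$confidence[1]) - 1)
  # only flow available: passed through
  fl <- tibble::tibble(x = 10, y = 10, confidence = 0.4, method = "flow")
  expect_identical(fuse_estimates(NULL, NULL, fl), fl)
  # nothing usable: untrackable frame
  none <- fuse_estimates(NULL, NULL, NULL)
  expect_equal(none$confidence, 0)
})

test_that("detections are translation-equivariant", {
  base <- disk_frame(30, 25, w = 100, h = 80)
  shifted <- disk_frame(30 + 7, 25 + 5, w = 100, h = 80)
  for (fn in list(detect_gradient,
                  function(i) detect_mser(i)[1, c("x", "y")])) {
    e1 <- fn(base)
    e2 <- fn(shifted)
    expect_lt(abs(e2$x - e1$x - 7), 0.5)
    expect_lt(abs(e2$y - e1$y - 5), 0.5)
  }
})

test_that("tracking error degrades monotonically with rendering noise", {
  withr::with_seed(31, {
    pup <- tibble::tibble(x = runif(15, 0.15, 0.85),
                          y = runif(15, 0.15, 0.85))
  })
  err_for <- function(method) {
    vapply(c(0, 0.05, 0.1, 0.2), function(ns) {
      ef <- render_eye_frames(pup, noise_sd = ns, seed = 17)
      tr <- track_pupils(ef, method = method)
      mean(sqrt((tr$x - ef$truth$cx)^2 + (tr$y - ef$truth$cy)^2),
           na.rm = TRUE)
    }, numeric(1))
  }
  expect_true(all(diff(err_for("gradient")) >= 0))
  # fused errors are subpixel until heavy noise; allow subpixel dither
  expect_true(all(diff(err_for("fused")) >= -0.02))
  # and no detection ever lands outside the image bounds
  efn <- render_eye_frames(pup, noise_sd = 0.2, seed = 17)
  tr <- track_pupils(efn, method = "fused")
  ok <- tr$confidence > 0
  expect_true(all(tr$x[ok] >= 1 & tr$x[ok] <= 80))
  expect_true(all(tr$y[ok] >= 1 & tr$y[ok] <= 60))
})
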