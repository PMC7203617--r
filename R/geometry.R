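#' Screen geometry of the emotion-recognition task
#'
#' Describes the three on-screen areas of interest as axis-aligned rectangles
#' in normalized screen units (`[0,1] x [0,1]`, origin top-left, x rightward,
#' y downward): the central facial stimulus and the two nonsocial distractor
#' images flanking it. Defaults follow the study layout: the face covers 49%
#' of screen width and 87% of height; each distractor covers 17% x 31%. The
#' face is centered; distractors are centered within the vertical strips to
#' its left and right.
#'
#' @param face_width,face_height Face rectangle size in normalized units.
#' @param distractor_width,distractor_height Distractor rectangle size.
#' @return A tibble of class `screen_geometry` with columns `region`
#'   (`"F"`, `"L"`, `"R"`), `cx`, `cy`, `width`, `height`.
#' @examples
#' geom <- screen_geometry()
#' code_frame(0.5, 0.5, geom)  # face center -> "F"
#' @export
screen_geometry <- function(face_width = 0.49, face_height = 0.87,
                            distractor_width = 0.17,
                            distractor_height = 0.31) {
  strip <- (1 - face_width) / 2 # width of each flanking strip
  if (distractor_width > strip) {
    stop("distractor_width exceeds the strip beside the face; regions would overlap",
         call. = FALSE)
  }
  geom <- tibble::tibble(
    region = c("F", "L", "R"),
    cx = c(0.5, strip / 2, 1 - strip / 2),
    cy = 0.5,
    width = c(face_width, distractor_width, distractor_width),
    height = c(face_height, distractor_height, distractor_height)
  )
  bad <- geom$cx - geom$width / 2 < 0 | geom$cx + geom$width / 2 > 1 |
    geom$cy - geom$height / 2 < 0 | geom$cy + geom$height / 2 > 1
  if (any(bad)) stop("a region extends outside the unit screen", call. = FALSE)
  class(geom) <- c("screen_geometry", class(geom))
  geom
}

#' Center of a named region
#' @param geometry A [screen_geometry()].
#' @param region One of `"F"`, `"L"`, `"R"`.
#' @return Numeric length-2 vector `(x, y)`.
#' @export
region_center <- function(geometry, region) {
  i <- match(region, geometry$region)
  if (is.na(i)) stop("unknown region: ", region, call. = FALSE)
  c(geometry$cx[i], geometry$cy[i])
}

#' Code world-gaze coordinates to F/L/R/N
#'
#' Codes each gaze point to one of four categories: on the facial stimulus
#' (`F`), on the left (`L`) or right (`R`) distractor, or nowhere in
#' particular (`N`). Boundary points count as inside; missing and off-screen
#' coordinates code as `N`.
#'
#' @param x,y Numeric vectors of world-gaze coordinates (normalized units);
#'   `NA` allowed.
#' @param geometry A [screen_geometry()].
#' @return A factor with levels `F`, `L`, `R`, `N`.
#' @export
code_frame <- function(x, y, geometry = screen_geometry()) {
  n <- length(x)
  stopifnot(length(y) == n)
  out <- rep("N", n)
  for (i in seq_len(nrow(geometry))) {
    # boundary-inclusive, with a guard for floating-point representation
    inside <- !is.na(x) & !is.na(y) &
      abs(x - geometry$cx[i]) <= geometry$width[i] / 2 + 1e-12 &
      abs(y - geometry$cy[i]) <= geometry$height[i] / 2 + 1e-12
    out[inside] <- geometry$region[i]
  }
  factor(out, levels = code_levels())
}
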