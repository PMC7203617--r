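#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing so that independent pipeline stages (one per
#' participant, permutation, or replicate) can each receive their own seed
#' from a single master seed, independently of execution order.
#'
#' @param seed Master seed (integer).
#' @param ... One or more integer indices identifying the stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + (as.double(i) + 1) * 30269 + 11) %% 2147483647
  }
  as.integer(s)
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' The canonical seven-emotion response set
#'
#' The fixed emotion vocabulary used for stimuli and responses:
#' happy, sad, angry, scared, disgust, surprised, calm.
#'
#' @return Character vector of length 7.
#' @export
emotion_levels <- function() {
  c("happy", "sad", "angry", "scared", "disgust", "surprised", "calm")
}

# gaze code levels, fixed order
code_levels <- function() c("F", "L", "R", "N")

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
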