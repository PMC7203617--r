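#' Gaze transition kernel over F/L/R/N
#'
#' First-order Markov kernel whose stationary distribution places
#' `latent_distraction` mass on the two distractors (split evenly),
#' `latent_offtask` on `N`, and the remainder on the face. The kernel is
#' `dwell * I + (1 - dwell) * 1 pi'`, so rows are stochastic and the
#' stationary distribution equals `pi` exactly for any dwell in `[0, 1)`;
#' `dwell` controls fixation run lengths without changing frame fractions.
#'
#' @param latent_distraction,latent_offtask Probabilities with sum <= 1.
#' @param dwell Self-transition stickiness (default 0.9).
#' @return A 4x4 row-stochastic matrix with dimnames `F`, `L`, `R`, `N`.
#' @export
gaze_transition_matrix <- function(latent_distraction, latent_offtask,
                                   dwell = 0.9) {
  stopifnot(latent_distraction >= 0, latent_offtask >= 0,
            latent_distraction + latent_offtask <= 1,
            dwell >= 0, dwell < 1)
  pi <- c(F = 1 - latent_distraction - latent_offtask,
          L = latent_distraction / 2, R = latent_distraction / 2,
          N = latent_offtask)
  P <- dwell * diag(4) + (1 - dwell) * matrix(pi, 4, 4, byrow = TRUE)
  dimnames(P) <- list(code_levels(), code_levels())
  P
}

gaze_stationary <- function(latent_distraction, latent_offtask) {
  c(F = 1 - latent_distraction - latent_offtask,
    L = latent_distraction / 2, R = latent_distraction / 2,
    N = latent_offtask)
}

#' Simulate a per-frame gaze stream for one participant
#'
#' Latent gaze codes follow the participant's Markov chain independently
#' within each stimulus window (initial state drawn from the stationary
#' distribution, modeling a persistent attention state). The emitted
#' world-gaze coordinate is the latent target region's center plus isotropic
#' Gaussian noise; `N` frames emit either a uniform point outside all
#' regions (default) or a missing value. During dot events the latent target
#' is the screen center.
#'
#' @param participant One cohort row (tibble or list) with
#'   `latent_distraction` and `latent_offtask`.
#' @param schedule A [make_schedule()] object.
#' @param geometry A [screen_geometry()].
#' @param noise_sd Angular noise SD in normalized screen units
#'   (default 0.01).
#' @param dwell Markov self-transition stickiness.
#' @param n_policy `"outside"` (default) or `"missing"`: how `N` frames emit.
#' @param seed Integer seed.
#' @return A tibble with one row per session frame: `frame`, `trial`,
#'   `phase` (`"stimulus"`/`"dot"`), `stimulus_id`, `code` (latent
#'   F/L/R/N; `NA` during dots), `x`, `y`.
#' @export
simulate_gaze <- function(participant, schedule, geometry = screen_geometry(),
                          noise_sd = 0.01, dwell = 0.9,
                          n_policy = c("outside", "missing"), seed = 1) {
  n_policy <- match.arg(n_policy)
  ld <- participant$latent_distraction[[1]]
  lo <- participant$latent_offtask[[1]]
  P <- gaze_transition_matrix(ld, lo, dwell)
  pi0 <- gaze_stationary(ld, lo)
  att <- frame_attribution(schedule)
  n <- schedule$n_frames
  st <- schedule$stimuli

  with_seed(seed, {
    code_int <- rep(NA_integer_, n)
    for (i in seq_len(nrow(st))) {
      idx <- st$onset_frame[i]:(st$onset_frame[i] + st$duration_frames[i] - 1L)
      code_int[idx] <- .sim_markov_chain(length(idx), P, pi0)
    }
    lev <- code_levels()
    centers <- rbind(
      vapply(lev[1:3], function(r) region_center(geometry, r), numeric(2)),
      deparse.level = 0
    ) # 2 x 3: columns F, L, R

    x <- rep(NA_real_, n); y <- rep(NA_real_, n)
    is_stim <- !is.na(att$stim)
    cc <- code_int[is_stim]
    on_target <- cc <= 3L
    tx <- centers[1, cc[on_target]]; ty <- centers[2, cc[on_target]]
    m <- length(tx)
    x[is_stim][on_target] <- tx + rnorm(m, 0, noise_sd)
    y[is_stim][on_target] <- ty + rnorm(m, 0, noise_sd)
    # N frames
    n_idx <- which(is_stim)[!on_target]
    if (length(n_idx) > 0) {
      if (n_policy == "missing") {
        # leave NA
      } else {
        pts <- sample_outside_regions(length(n_idx), geometry)
        x[n_idx] <- pts[, 1]; y[n_idx] <- pts[, 2]
      }
    }
    # dot frames: target is the screen center
    if (any(att$dot)) {
      nd <- sum(att$dot)
      x[att$dot] <- 0.5 + rnorm(nd, 0, noise_sd)
      y[att$dot] <- 0.5 + rnorm(nd, 0, noise_sd)
    }
    trial <- rep(NA_integer_, n)
    trial[is_stim] <- st$trial[att$stim[is_stim]]
    if (any(att$dot)) trial[att$dot] <- dot_trial(schedule, att)[att$dot]
    phase <- rep(NA_character_, n)
    phase[is_stim] <- "stimulus"
    phase[att$dot] <- "dot"
    stim_id <- rep(NA_character_, n)
    stim_id[is_stim] <- st$stimulus_id[att$stim[is_stim]]
    code_chr <- rep(NA_character_, n)
    code_chr[is_stim] <- lev[code_int[is_stim]]
    tibble::tibble(
      frame = seq_len(n),
      trial = trial,
      phase = phase,
      stimulus_id = stim_id,
      code = factor(code_chr, levels = lev),
      x = x, y = y
    )
  })
}

# trial index for dot frames
dot_trial <- function(schedule, att) {
  de <- schedule$dot_events
  tr <- rep(NA_integer_, schedule$n_frames)
  for (i in seq_len(nrow(de))) {
    tr[de$start_frame[i]:(de$start_frame[i] + de$duration_frames[i] - 1L)] <-
      de$trial[i]
  }
  tr
}

# rejection-sample uniform screen points lying outside all regions
sample_outside_regions <- function(n, geometry) {
  out <- matrix(NA_real_, n, 2)
  need <- n
  filled <- 0
  while (need > 0) {
    m <- max(need * 3, 16)
    px <- runif(m); py <- runif(m)
    keep <- code_frame(px, py, geometry) == "N"
    k <- min(sum(keep), need)
    if (k > 0) {
      sel <- which(keep)[seq_len(k)]
      out[(filled + 1):(filled + k), ] <- cbind(px[sel], py[sel])
      filled <- filled + k
      need <- need - k
    }
  }
  out
}
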