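#' Default group parameters for the synthetic cohort
#'
#' Per-group distraction propensity moments follow the distraction-ratio
#' means and standard deviations reported for the two cohorts
#' (ASD: 0.0433, SD 0.0911; NC: 0.0139, SD 0.0215), and demographics follow
#' the published cohort table (13/16 male ASD, 9/17 male NC; ages 6-17 and
#' 8-17). Off-task propensity and emotion-recognition accuracy have no
#' printed per-frame values; the defaults are realistic for school-age
#' children in a supervised task (modest off-AOI fraction, ~70-85% emotion
#' accuracy with lower accuracy in the ASD group).
#'
#' @return A tibble with one row per group.
#' @export
cohort_defaults <- function() {
  tibble::tibble(
    group = c("ASD", "NC"),
    distraction_mean = c(0.0433, 0.0139),
    distraction_sd = c(0.0911, 0.0215),
    offtask_mean = c(0.10, 0.08),
    offtask_sd = c(0.05, 0.04),
    accuracy_mean = c(0.72, 0.85),
    accuracy_sd = c(0.10, 0.06),
    male_prop = c(13 / 16, 9 / 17),
    age_min = c(6L, 8L),
    age_max = c(17L, 17L),
    scq_mean = c(18.86, 1.82), scq_sd = c(6.43, 1.07),
    srs_mean = c(78.85, 44.41), srs_sd = c(11.13, 8.11),
    abiq_mean = c(102.75, 108.94), abiq_sd = c(19.54, 9.58)
  )
}

# moment-matched Beta draw, degenerate at `mean` when sd == 0
rbeta_moments <- function(n, mean, sd, what = "parameter") {
  if (mean <= 0 || mean >= 1) {
    stop(sprintf("%s mean must lie in (0, 1)", what), call. = FALSE)
  }
  if (sd == 0) return(rep(mean, n))
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop(sprintf(
      "%s: SD %.4g is too large for a Beta distribution with mean %.4g",
      what, sd, mean
    ), call. = FALSE)
  }
  k <- mean * (1 - mean) / v - 1
  rbeta(n, mean * k, (1 - mean) * k)
}

# participant confusion profile: `acc` on the diagonal, remainder uniform
confusion_profile <- function(acc) {
  k <- length(emotion_levels())
  m <- matrix((1 - acc) / (k - 1), k, k,
              dimnames = list(emotion_levels(), emotion_levels()))
  diag(m) <- acc
  m
}

#' Generate a synthetic two-group cohort
#'
#' Draws `n_asd` + `n_nc` participants with latent per-frame distraction and
#' off-task propensities (Beta distributions moment-matched to the per-group
#' mean/SD), ages uniform on the per-group range, gender from the per-group
#' male proportion, a 7x7 row-stochastic emotion-confusion profile governed
#' by a participant-level accuracy, and inert clinical-score metadata
#' columns (SCQ, SRS, ABIQ) that the analysis never consumes.
#'
#' @param n_asd,n_nc Group sizes (default 16 and 17).
#' @param seed Integer seed; the cohort is a pure function of it.
#' @param params Per-group parameter tibble as in [cohort_defaults()].
#' @return A tibble with one row per participant: `participant_id`, `group`,
#'   `age`, `gender`, `latent_distraction`, `latent_offtask`,
#'   `accuracy`, `confusion_profile` (list of matrices), `scq`, `srs`,
#'   `abiq`.
#' @examples
#' cohort <- make_cohort(4, 4, seed = 1)
#' mean(cohort$latent_distraction[cohort$group == "ASD"])
#' @export
make_cohort <- function(n_asd = 16, n_nc = 17, seed = 1,
                        params = cohort_defaults()) {
  stopifnot(n_asd >= 1, n_nc >= 1)
  with_seed(seed, {
    rows <- purrr::map2(c("ASD", "NC"), c(n_asd, n_nc), function(g, n) {
      p <- params[params$group == g, ]
      if (nrow(p) != 1) stop("params must contain exactly one row for group ", g)
      ld <- rbeta_moments(n, p$distraction_mean, p$distraction_sd,
                          sprintf("group %s distraction", g))
      lo <- rbeta_moments(n, p$offtask_mean, p$offtask_sd,
                          sprintf("group %s offtask", g))
      lo <- pmin(lo, 1 - ld) # joint propensity cannot exceed 1
      acc <- rbeta_moments(n, p$accuracy_mean, p$accuracy_sd,
                           sprintf("group %s accuracy", g))
      tibble::tibble(
        group = g,
        age = sample(seq(p$age_min, p$age_max), n, replace = TRUE),
        gender = ifelse(runif(n) < p$male_prop, "male", "female"),
        latent_distraction = ld,
        latent_offtask = lo,
        accuracy = acc,
        confusion_profile = purrr::map(acc, confusion_profile),
        scq = rnorm(n, p$scq_mean, p$scq_sd),
        srs = rnorm(n, p$srs_mean, p$srs_sd),
        abiq = rnorm(n, p$abiq_mean, p$abiq_sd)
      )
    })
    cohort <- dplyr::bind_rows(rows)
    cohort <- dplyr::mutate(
      cohort,
      participant_id = sprintf("P%02d", dplyr::row_number()),
      .before = 1
    )
    cohort
  })
}
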