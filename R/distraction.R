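#' Distraction ratios per stimulus
#'
#' For each per-stimulus count tuple computes the distraction ratio
#' `d = (nL + nR) / (nF + nL + nR + nN)` (the fraction of all attributed
#' frames spent on either distractor) and the N-excluding variant
#' `d_flr = (nL + nR) / (nF + nL + nR)`. `d_flr` is undefined when no frame
#' landed on any region (`nF + nL + nR = 0`); rows with all counts zero are
#' flagged invalid and excluded from aggregation.
#'
#' @param counts Counts tibble from [stimulus_counts()] (any extra key
#'   columns such as `participant_id` are carried through).
#' @return The input with `d`, `d_flr`, `valid` (any frames at all) and
#'   `flr_defined` columns added.
#' @examples
#' distraction_ratios(tibble::tibble(nF = 3, nL = 1, nR = 1, nN = 5))
#' # d = 0.2, d_flr = 0.4
#' @export
distraction_ratios <- function(counts) {
  tot <- counts$nF + counts$nL + counts$nR + counts$nN
  flr <- counts$nF + counts$nL + counts$nR
  lr <- counts$nL + counts$nR
  dplyr::mutate(
    counts,
    d = ifelse(tot > 0, lr / tot, NA_real_),
    d_flr = ifelse(flr > 0, lr / flr, NA_real_),
    valid = tot > 0,
    flr_defined = flr > 0
  )
}

#' Per-participant mean distraction ratio d(p)
#'
#' Unweighted mean of the valid per-stimulus ratios `d(p,s,t)` across all
#' stimuli and trials for each participant (stimuli weighted equally;
#' trials with more surviving stimuli therefore weigh more).
#'
#' @param records Ratio tibble from [distraction_ratios()] with a
#'   `participant_id` column.
#' @return Tibble `participant_id`, `d`, `n_records`. Participants with no
#'   valid record are omitted with a warning.
#' @export
aggregate_participants <- function(records) {
  stopifnot("participant_id" %in% names(records))
  out <- records |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(d = mean(.data$d), n_records = dplyr::n(),
                     .groups = "drop")
  missing <- setdiff(unique(records$participant_id), out$participant_id)
  if (length(missing) > 0) {
    warning("participants with no valid distraction record omitted: ",
            paste(missing, collapse = ", "))
  }
  out
}

#' Per-emotion N-excluding distraction ratios
#'
#' Means of the defined `d_flr` values per participant, trial and true
#' emotion. Cells with no defined value stay `NA`.
#'
#' @param records Ratio tibble from [distraction_ratios()] carrying
#'   `participant_id`, `trial`, `true_emotion`.
#' @return Tibble `participant_id`, `trial`, `true_emotion`, `d_flr`, `n`.
#' @export
per_emotion_flr <- function(records) {
  records |>
    dplyr::group_by(.data$participant_id, .data$trial, .data$true_emotion) |>
    dplyr::summarise(
      d_flr = if (any(.data$flr_defined)) {
        mean(.data$d_flr[.data$flr_defined])
      } else NA_real_,
      n = sum(.data$flr_defined),
      .groups = "drop"
    )
}

#' One-tailed two-sample group test on distraction values
#'
#' Tests whether the ASD group mean exceeds the NC group mean. Welch's
#' unequal-variance t-test by default (the groups' spreads differ several
#' fold); a pooled-variance test is available via `var_equal`. The same
#' routine serves the per-participant primary test on `d(p)` and the
#' exploratory per-stimulus test on `d(p,s,t)` (the latter assumes
#' within-participant independence; set `independence_caveat` so the output
#' records that assumption).
#'
#' @param values_asd,values_nc Numeric vectors (>= 2 values each).
#' @param var_equal Pooled-variance test instead of Welch.
#' @param independence_caveat Flag recorded in the result metadata.
#' @return Object of class `h1_test`: list with `t`, `df`, `p` (one-tailed,
#'   ASD > NC), `mean_asd`, `mean_nc`, `sd_asd`, `sd_nc`, `n_asd`, `n_nc`,
#'   `var_equal`, `independence_caveat`, `degenerate`.
#' @export
group_ttest <- function(values_asd, values_nc, var_equal = FALSE,
                        independence_caveat = FALSE) {
  values_asd <- values_asd[is.finite(values_asd)]
  values_nc <- values_nc[is.finite(values_nc)]
  stopifnot(length(values_asd) >= 2, length(values_nc) >= 2)
  degenerate <- sd(values_asd) == 0 && sd(values_nc) == 0 &&
    mean(values_asd) == mean(values_nc)
  if (degenerate) {
    tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
               p.value = 0.5)
  } else {
    tt <- stats::t.test(values_asd, values_nc, alternative = "greater",
                        var.equal = var_equal)
  }
  out <- list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = if (degenerate) 0.5 else tt$p.value,
    mean_asd = mean(values_asd), mean_nc = mean(values_nc),
    sd_asd = sd(values_asd), sd_nc = sd(values_nc),
    n_asd = length(values_asd), n_nc = length(values_nc),
    var_equal = var_equal, independence_caveat = independence_caveat,
    degenerate = degenerate
  )
  class(out) <- "h1_test"
  out
}

#' @export
print.h1_test <- function(x, ...) {
  cat(sprintf(
    "<h1_test> one-tailed %s t-test (ASD > NC)\n  ASD: mean %.4f (SD %.4f, n %d)   NC: mean %.4f (SD %.4f, n %d)\n  t = %.3f, p = %.4g%s\n",
    if (x$var_equal) "pooled" else "Welch", x$mean_asd, x$sd_asd, x$n_asd,
    x$mean_nc, x$sd_nc, x$n_nc, x$t, x$p,
    if (x$independence_caveat) "  [assumes within-participant independence]" else ""
  ))
  invisible(x)
}

#' Distraction-hypothesis report for a cohort
#'
#' Runs both group comparisons: the primary per-participant test on `d(p)`
#' and the exploratory per-stimulus test on the raw `d(p,s,t)` values.
#'
#' @param records Ratio tibble from [distraction_ratios()] with
#'   `participant_id`.
#' @param participants Cohort tibble with `participant_id`, `group`.
#' @param var_equal Passed to [group_ttest()].
#' @return List with `participant_test`, `stimulus_test` (both `h1_test`),
#'   and `d_participant` (the aggregated `d(p)` tibble with group).
#' @export
h1_report <- function(records, participants, var_equal = FALSE) {
  dp <- aggregate_participants(records) |>
    dplyr::left_join(participants[, c("participant_id", "group")],
                     by = "participant_id")
  pt <- group_ttest(dp$d[dp$group == "ASD"], dp$d[dp$group == "NC"],
                    var_equal = var_equal)
  rec <- dplyr::left_join(records,
                          participants[, c("participant_id", "group")],
                          by = "participant_id")
  rec <- rec[rec$valid, ]
  st <- group_ttest(rec$d[rec$group == "ASD"], rec$d[rec$group == "NC"],
                    var_equal = var_equal, independence_caveat = TRUE)
  list(participant_test = pt, stimulus_test = st, d_participant = dp)
}
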