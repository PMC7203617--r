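#' Tidy a LOPO evaluation
#'
#' @param x A `lopo_eval`.
#' @param ... Unused.
#' @return Tibble of per-participant predictions: `participant_id`,
#'   `truth`, `pred`, `score`, `correct`.
#' @export
tidy.lopo_eval <- function(x, ...) {
  dplyr::mutate(x$predictions, correct = .data$truth == .data$pred)
}

#' One-row summary of a LOPO evaluation
#'
#' @param x A `lopo_eval`.
#' @param ... Unused.
#' @return Tibble with `accuracy`, `n`, cell counts of the 2x2 confusion
#'   matrix, sensitivity (ASD recall) and specificity.
#' @export
glance.lopo_eval <- function(x, ...) {
  cm <- x$confusion
  tibble::tibble(
    accuracy = x$accuracy, n = x$n,
    tp = cm["ASD", "ASD"], fn = cm["ASD", "NC"],
    fp = cm["NC", "ASD"], tn = cm["NC", "NC"],
    sensitivity = cm["ASD", "ASD"] / sum(cm["ASD", ]),
    specificity = cm["NC", "NC"] / sum(cm["NC", ])
  )
}

#' Tidy a group distraction test
#'
#' @param x An `h1_test`.
#' @param ... Unused.
#' @return One-row tibble with estimates and the one-tailed p-value.
#' @export
tidy.h1_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_asd - x$mean_nc,
    mean_asd = x$mean_asd, mean_nc = x$mean_nc,
    sd_asd = x$sd_asd, sd_nc = x$sd_nc,
    statistic = x$t, df = x$df, p.value = x$p,
    method = if (x$var_equal) "pooled t (one-tailed)" else "Welch t (one-tailed)",
    alternative = "ASD > NC"
  )
}

#' @rdname tidy.h1_test
#' @export
glance.h1_test <- function(x, ...) tidy(x)

#' One-row summary of a shuffle test
#'
#' @param x A `shuffle_test`.
#' @param ... Unused.
#' @return Tibble with observed accuracy, `p`, null-distribution summary
#'   and the convergence flag.
#' @export
glance.shuffle_test <- function(x, ...) {
  tibble::tibble(
    accuracy = x$observed$accuracy, p.value = x$p, B = x$B,
    null_mean = mean(x$null_accuracy), null_sd = sd(x$null_accuracy),
    null_q95 = unname(quantile(x$null_accuracy, 0.95)),
    converged = x$converged
  )
}

#' Tidy a shuffle test's null distribution
#'
#' @param x A `shuffle_test`.
#' @param ... Unused.
#' @return Tibble `iteration`, `null_accuracy`.
#' @export
tidy.shuffle_test <- function(x, ...) {
  tibble::tibble(iteration = seq_len(x$B), null_accuracy = x$null_accuracy)
}
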