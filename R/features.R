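#' Emotion confusion-matrix features (cm, 49 values)
#'
#' The 7x7 confusion matrix of a participant-trial: entry (r, c) counts
#' stimuli whose true emotion was r and response c, with each row divided
#' by its sum. Rows with no stimuli stay all zero (and are recorded in the
#' `zero_rows` attribute). Values are flattened row-major with names
#' `cm_<true>_<resp>`.
#'
#' @param responses Tibble for one participant-trial with `true_emotion`
#'   and `response` columns.
#' @return A named numeric vector of length 49 with attribute `zero_rows`.
#' @export
confusion_matrix_features <- function(responses) {
  emo <- emotion_levels()
  bad <- setdiff(unique(c(responses$true_emotion, responses$response)), emo)
  if (length(bad) > 0) {
    stop("response outside the emotion set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- table(factor(responses$true_emotion, levels = emo),
             factor(responses$response, levels = emo))
  m <- unclass(m)
  rs <- rowSums(m)
  zero <- rs == 0
  m[!zero, ] <- m[!zero, , drop = FALSE] / rs[!zero]
  v <- as.numeric(t(m)) # row-major
  names(v) <- paste0("cm_", rep(emo, each = 7), "_", rep(emo, 7))
  attr(v, "zero_rows") <- emo[zero]
  v
}

#' Emotion confusion-detail features (conf, S values)
#'
#' One binary value per stimulus in presentation order: 1 when the
#' participant identified the true emotion correctly.
#'
#' @param responses Tibble for one participant-trial with `stimulus_id`,
#'   `true_emotion`, `response`, ordered or orderable by `stimulus_id`.
#' @return Named numeric vector `conf_<stimulus_id>` of length S.
#' @export
confusion_detail_features <- function(responses) {
  if (anyNA(responses$response)) {
    stop("missing response; responses must be complete", call. = FALSE)
  }
  o <- order(responses$stimulus_id)
  v <- as.numeric(responses$true_emotion[o] == responses$response[o])
  names(v) <- paste0("conf_", responses$stimulus_id[o])
  v
}

# the three per-stimulus gaze quantities from one window's code sequence
gaze_stim_features <- function(codes, window_len) {
  codes <- as.character(codes)
  if (length(codes) == 0) { # fully dropped window: impute downstream
    return(c(face_frac = NA_real_, toward_face = NA_real_,
             latency = NA_real_))
  }
  nF <- sum(codes == "F"); nL <- sum(codes == "L"); nR <- sum(codes == "R")
  face_frac <- if (nF + nL + nR > 0) nF / (nF + nL + nR) else NA_real_
  # transitions between distinct consecutive codes (run boundaries)
  if (length(codes) >= 2) {
    a <- codes[-length(codes)]; b <- codes[-1]
    distinct <- a != b
    toward <- if (any(distinct)) {
      sum(distinct & b == "F") / sum(distinct)
    } else NA_real_
  } else {
    toward <- NA_real_
  }
  first_f <- which(codes == "F")
  latency <- if (length(first_f) > 0) first_f[1] - 1 else window_len
  c(face_frac = face_frac, toward_face = toward, latency = latency)
}

#' Gaze-pattern features (gaze, 3 values per stimulus)
#'
#' For each stimulus window: (a) the fraction of frames on the face out of
#' frames on any region (face versus either distractor), (b) the fraction
#' of changes of gaze fixation (transitions between distinct consecutive
#' codes, N included) whose destination is the face, and (c) the number of
#' frames elapsed before first looking at the face (the window length when
#' the face is never fixated). Undefined fractions stay `NA` for
#' fold-internal imputation downstream.
#'
#' @param coded A `coded_frames` tibble for one session (dropped frames are
#'   ignored when computing the sequence).
#' @param schedule The session's schedule.
#' @return Tibble `trial`, `stimulus_id`, `face_frac`, `toward_face`,
#'   `latency`.
#' @export
gaze_features <- function(coded, schedule) {
  st <- schedule$stimuli
  kept <- coded[!coded$dropped, ]
  split_codes <- split(as.character(kept$code),
                       factor(kept$stimulus_id, levels = st$stimulus_id))
  vals <- t(vapply(seq_len(nrow(st)), function(i) {
    gaze_stim_features(split_codes[[st$stimulus_id[i]]],
                       st$duration_frames[i])
  }, numeric(3)))
  tibble::tibble(
    trial = st$trial, stimulus_id = st$stimulus_id,
    face_frac = vals[, 1], toward_face = vals[, 2], latency = vals[, 3]
  )
}

#' Participant metadata features (pat, 2 values)
#'
#' Age in years and gender coded male = 0, female = 1.
#'
#' @param participants Cohort tibble with `participant_id`, `age`,
#'   `gender`.
#' @return Tibble `participant_id`, `pat_age`, `pat_gender`.
#' @export
metadata_features <- function(participants) {
  if (anyNA(participants$age) || anyNA(participants$gender)) {
    stop("missing participant metadata (age/gender)", call. = FALSE)
  }
  tibble::tibble(
    participant_id = participants$participant_id,
    pat_age = as.numeric(participants$age),
    pat_gender = ifelse(participants$gender == "female", 1, 0)
  )
}

# one participant-trial's feature vector for the requested families,
# as a named list of named numeric vectors
trial_family_vectors <- function(responses_pt, coded_p, schedule, trial) {
  st <- schedule$stimuli[schedule$stimuli$trial == trial, ]
  out <- list()
  out$cm <- confusion_matrix_features(responses_pt)
  out$conf <- confusion_detail_features(responses_pt)
  gz <- gaze_features(coded_p, schedule)
  gz <- gz[gz$trial == trial, ]
  gv <- as.numeric(t(as.matrix(gz[, c("face_frac", "toward_face", "latency")])))
  names(gv) <- paste0(
    "gaze_", rep(c("face_frac", "toward_face", "latency"), nrow(gz)),
    "_", rep(gz$stimulus_id, each = 3)
  )
  out$gaze <- gv
  out
}

#' Assemble the participant-by-feature table
#'
#' Builds and column-concatenates the per-trial feature families (cm 49,
#' conf S, gaze 3S) for the requested trials, plus the trial-invariant
#' participant metadata (pat, included once). Per-trial columns are named
#' `t<trial>_<family>_<name>`. Participants missing a requested trial get
#' `NA` in that trial's columns (imputed fold-internally at fit time);
#' participants missing every requested trial are dropped with a warning.
#'
#' @param participants Cohort tibble (`participant_id`, `group`, `age`,
#'   `gender`).
#' @param responses Stacked response tibble (`participant_id`, `trial`,
#'   `stimulus_id`, `true_emotion`, `response`).
#' @param coded_list Named list (by participant id) of `coded_frames`
#'   tibbles, e.g. from per-participant [code_frames_session()].
#' @param schedule The session schedule.
#' @param trials `"all"` or an integer vector of trials.
#' @param families Subset of `c("cm", "conf", "gaze", "pat")`.
#' @return A tibble of class `feature_table`: `participant_id`, `group`,
#'   then feature columns; attribute `manifest` is a tibble mapping column
#'   to family and trial (`NA` trial for pat).
#' @export
build_features <- function(participants, responses, coded_list, schedule,
                           trials = "all",
                           families = c("cm", "conf", "gaze", "pat")) {
  families <- match.arg(families, several.ok = TRUE)
  all_trials <- sort(unique(schedule$stimuli$trial))
  if (identical(trials, "all")) trials <- all_trials
  stopifnot(all(trials %in% all_trials))

  per_trial_fams <- intersect(families, c("cm", "conf", "gaze"))
  rows <- purrr::map(participants$participant_id, function(pid) {
    vec <- numeric(0)
    for (t in trials) {
      rp <- responses[responses$participant_id == pid & responses$trial == t, ]
      coded_p <- coded_list[[pid]]
      have <- nrow(rp) > 0 && !is.null(coded_p)
      for (fam in per_trial_fams) {
        v <- if (!have) {
          template_family(fam, schedule, t)
        } else if (fam == "gaze") {
          trial_family_vectors(rp, coded_p, schedule, t)$gaze
        } else if (fam == "cm") {
          confusion_matrix_features(rp)
        } else {
          confusion_detail_features(rp)
        }
        names(v) <- paste0("t", t, "_", names(v))
        vec <- c(vec, v)
      }
    }
    vec
  })
  mat <- do.call(rbind, rows)
  out <- tibble::tibble(participant_id = participants$participant_id,
                        group = participants$group)
  if (!is.null(mat) && ncol(mat) > 0) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(mat))
  }
  if ("pat" %in% families) {
    out <- dplyr::left_join(out, metadata_features(participants),
                            by = "participant_id")
  }
  feat_cols <- setdiff(names(out), c("participant_id", "group"))
  # participants with no data in any requested trial
  row_na <- apply(is.na(as.matrix(out[feat_cols])), 1, all)
  if (any(row_na)) {
    warning("dropping participants with no data in any requested trial: ",
            paste(out$participant_id[row_na], collapse = ", "))
    out <- out[!row_na, ]
  }
  manifest <- tibble::tibble(
    column = feat_cols,
    family = dplyr::case_when(
      grepl("^pat_", feat_cols) ~ "pat",
      grepl("^t\\d+_cm_", feat_cols) ~ "cm",
      grepl("^t\\d+_conf_", feat_cols) ~ "conf",
      grepl("^t\\d+_gaze_", feat_cols) ~ "gaze"
    ),
    trial = ifelse(grepl("^t\\d+_", feat_cols),
                   suppressWarnings(
                     as.integer(sub("^t(\\d+)_.*", "\\1", feat_cols))
                   ),
                   NA_integer_)
  )
  attr(out, "manifest") <- manifest
  class(out) <- c("feature_table", class(out))
  out
}

# NA template of a family's columns for a missing participant-trial
template_family <- function(fam, schedule, trial) {
  st <- schedule$stimuli[schedule$stimuli$trial == trial, ]
  emo <- emotion_levels()
  if (fam == "cm") {
    v <- rep(NA_real_, 49)
    names(v) <- paste0("cm_", rep(emo, each = 7), "_", rep(emo, 7))
  } else if (fam == "conf") {
    v <- rep(NA_real_, nrow(st))
    names(v) <- paste0("conf_", sort(st$stimulus_id))
  } else {
    v <- rep(NA_real_, 3 * nrow(st))
    names(v) <- paste0(
      "gaze_", rep(c("face_frac", "toward_face", "latency"), nrow(st)),
      "_", rep(st$stimulus_id, each = 3)
    )
  }
  v
}

#' Select feature-table columns by family and trial
#'
#' Subsets a [build_features()] table using its manifest, for ablation
#' runs. `pat` columns are trial-invariant and are retained for any trial
#' selection when requested.
#'
#' @param features A `feature_table`.
#' @param families Families to keep.
#' @param trials `"all"` or integer vector.
#' @return A `feature_table` with the reduced manifest.
#' @export
select_features <- function(features, families, trials = "all") {
  man <- attr(features, "manifest")
  stopifnot(!is.null(man))
  keep <- man$family %in% families &
    (man$family == "pat" | identical(trials, "all") | man$trial %in% trials)
  cols <- man$column[keep]
  out <- features[, c("participant_id", "group", cols)]
  attr(out, "manifest") <- man[keep, ]
  class(out) <- unique(c("feature_table", class(out)))
  out
}
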