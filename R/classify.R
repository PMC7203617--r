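#' Classifier specification
#'
#' Describes the penalized linear model family and its hyperparameter grid.
#' `"elastic_net"` is penalized logistic loss with a combined l1+l2 penalty
#' (mixing grid `alpha`); `"logistic"` is the pure-penalty ablation
#' (`alpha` restricted to 0 = ridge/l2 or 1 = lasso/l1); `"linear_net"` is
#' the squared-loss elastic net whose fitted value is thresholded at 0.5.
#' With more than one `(alpha, lambda)` candidate, the pair is chosen per
#' training fold by inner cross-validated misclassification.
#'
#' @param kind One of `"elastic_net"`, `"logistic"`, `"linear_net"`.
#' @param alpha Mixing values in `[0, 1]`; defaults: `seq(0.1, 0.9, 0.2)`
#'   for elastic net, `c(0, 1)` for logistic, `0` for linear_net.
#' @param lambda Optional fixed penalty strength(s); `NULL` lets the inner
#'   search use a data-driven path of `n_lambda` values.
#' @param n_lambda Length of the data-driven penalty path.
#' @param inner_folds Inner cross-validation folds (default 5).
#' @param standardize Standardize features with training-fold statistics
#'   before fitting (default `TRUE`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("elastic_net", "logistic", "linear_net"),
                       alpha = NULL, lambda = NULL, n_lambda = 20,
                       inner_folds = 5, standardize = TRUE) {
  kind <- match.arg(kind)
  if (is.null(alpha)) {
    alpha <- switch(kind, elastic_net = seq(0.1, 0.9, by = 0.2),
                    logistic = c(0, 1), linear_net = 0)
  }
  stopifnot(length(alpha) >= 1, all(alpha >= 0), all(alpha <= 1))
  if (kind == "logistic" && !all(alpha %in% c(0, 1))) {
    stop("logistic ablation uses pure penalties: alpha must be 0 (l2) or 1 (l1)",
         call. = FALSE)
  }
  out <- list(kind = kind, alpha = alpha, lambda = lambda,
              n_lambda = n_lambda, inner_folds = inner_folds,
              standardize = standardize)
  class(out) <- "model_spec"
  out
}

# stratified inner-fold ids, deterministic in seed
make_foldid <- function(y01, k, seed) {
  id <- integer(length(y01))
  with_seed(seed, {
    for (cls in unique(y01)) {
      idx <- which(y01 == cls)
      id[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  id
}

# training-fold preprocessing: median imputation then optional z-scaling
fit_preprocess <- function(Xtr, standardize) {
  med <- apply(Xtr, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  ctr <- scl <- NULL
  Xtr <- impute_with(Xtr, med)
  if (standardize) {
    ctr <- colMeans(Xtr)
    scl <- apply(Xtr, 2, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    Xtr <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")
  }
  list(X = Xtr, medians = med, center = ctr, scale = scl,
       standardize = standardize)
}

impute_with <- function(X, med) {
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- med[j]
  X
}

apply_preprocess <- function(pp, X) {
  X <- impute_with(X, pp$medians)
  if (pp$standardize) X <- sweep(sweep(X, 2, pp$center), 2, pp$scale, "/")
  X
}

# ridge least squares with unpenalized intercept; penalty is
# lambda * ||beta||^2 / 2 against RSS / 2 (raw, not 1/n, scale)
ridge_fit <- function(X, y, lambda) {
  mu <- colMeans(X); yb <- mean(y)
  Xc <- sweep(X, 2, mu); yc <- y - yb
  n <- nrow(X); p <- ncol(X)
  if (p <= n) {
    beta <- solve(crossprod(Xc) + diag(lambda, p), crossprod(Xc, yc))
  } else {
    a <- solve(tcrossprod(Xc) + diag(lambda, n), yc)
    beta <- crossprod(Xc, a)
  }
  list(beta = as.numeric(beta), intercept = yb - sum(mu * beta), mu = mu)
}

ridge_predict <- function(fit, X) {
  as.numeric(X %*% fit$beta) + fit$intercept
}

glmnet_family <- function(kind) {
  if (kind == "linear_net") "gaussian" else "binomial"
}

# glmnet warns on every small LOPO training fold; that condition is the
# study design here, not an anomaly
quiet_small_class <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# fit on one training fold (hyperparameter selection included) and predict
# the held-out rows; returns numeric scores on the probability/response scale
fit_fold <- function(Xtr, ytr, Xte, spec, seed) {
  fam <- glmnet_family(spec$kind)
  single <- length(spec$alpha) == 1 && length(spec$lambda) == 1
  if (spec$kind == "linear_net" && single && spec$alpha == 0) {
    fit <- ridge_fit(Xtr, ytr, spec$lambda)
    return(ridge_predict(fit, Xte))
  }
  if (single) {
    lam_seq <- sort(unique(c(spec$lambda * c(8, 3), spec$lambda)),
                    decreasing = TRUE)
    fit <- quiet_small_class(
      glmnet::glmnet(Xtr, ytr, family = fam, alpha = spec$alpha,
                     lambda = lam_seq, standardize = FALSE)
    )
    return(as.numeric(predict(fit, Xte, s = spec$lambda,
                              type = "response")))
  }
  foldid <- make_foldid(ytr, min(spec$inner_folds, length(ytr)), seed)
  best <- NULL
  for (a in spec$alpha) {
    cv <- quiet_small_class(glmnet::cv.glmnet(
      Xtr, ytr, family = fam, alpha = a, foldid = foldid,
      type.measure = if (fam == "binomial") "class" else "mse",
      lambda = spec$lambda,
      nlambda = spec$n_lambda, standardize = FALSE
    ))
    sc <- min(cv$cvm)
    if (is.null(best) || sc < best$score) {
      best <- list(score = sc, alpha = a, lambda = cv$lambda.min, cv = cv)
    }
  }
  as.numeric(predict(best$cv, Xte, s = best$lambda, type = "response"))
}

#' Leave-one-participant-out cross-validated classification
#'
#' For each participant, fits the specified penalized model on all other
#' participants (imputation, standardization and hyperparameter selection
#' confined to the training fold) and predicts the held-out participant's
#' group. A predicted score strictly above 0.5 is called ASD; exactly 0.5
#' ties to NC.
#'
#' @param features A `feature_table` from [build_features()] (or any tibble
#'   with `participant_id`, `group` and numeric feature columns).
#' @param spec A [model_spec()].
#' @param seed Integer seed governing inner-fold assignment.
#' @return Object of class `lopo_eval`: list with `predictions` (tibble
#'   `participant_id`, `truth`, `pred`, `score`), `accuracy`, `confusion`
#'   (2x2, truth in rows), `spec`, `seed`, `n`.
#' @export
fit_predict_lopo <- function(features, spec = model_spec(), seed = 1) {
  # canonical row order: results must not depend on how rows were stacked
  features <- features[order(features$participant_id), ]
  feat_cols <- setdiff(names(features), c("participant_id", "group"))
  X <- as.matrix(features[, feat_cols])
  storage.mode(X) <- "double"
  y <- features$group
  y01 <- as.numeric(y == "ASD")
  n <- nrow(X)
  if (min(table(y)) < 2) {
    stop("need at least 2 participants per class for LOPO", call. = FALSE)
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    pp <- fit_preprocess(X[-i, , drop = FALSE], spec$standardize)
    Xte <- apply_preprocess(pp, X[i, , drop = FALSE])
    scores[i] <- fit_fold(pp$X, y01[-i], Xte, spec, derive_seed(seed, i))
  }
  pred <- ifelse(scores > 0.5, "ASD", "NC")
  conf <- table(factor(y, c("ASD", "NC")), factor(pred, c("ASD", "NC")))
  out <- list(
    predictions = tibble::tibble(participant_id = features$participant_id,
                                 truth = y, pred = pred, score = scores),
    accuracy = mean(pred == y),
    confusion = unclass(conf),
    spec = spec, seed = seed, n = n
  )
  class(out) <- "lopo_eval"
  out
}

#' @export
print.lopo_eval <- function(x, ...) {
  cat(sprintf("<lopo_eval> n = %d, LOPO accuracy = %.3f\n", x$n, x$accuracy))
  print(x$confusion)
  invisible(x)
}

# exact LOPO prediction operator for fixed-lambda linear ridge:
# returns n x n matrix A with pred = A %*% y (A[i, i] = 0)
ridge_lopo_operator <- function(X, lambda, standardize) {
  n <- nrow(X)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    pp <- fit_preprocess(X[-i, , drop = FALSE], standardize)
    Xtr <- pp$X
    xte <- as.numeric(apply_preprocess(pp, X[i, , drop = FALSE]))
    m <- nrow(Xtr)
    mu <- colMeans(Xtr)
    Xc <- sweep(Xtr, 2, mu)
    k <- as.numeric(Xc %*% (xte - mu))
    q <- solve(tcrossprod(Xc) + diag(lambda, m), k) # q' = k'(G+lambda I)^-1
    r <- q + (1 - sum(q)) / m
    A[i, -i] <- r
  }
  A
}

#' Monte Carlo label-shuffle significance test
#'
#' Permutes group labels at the participant level `B` times, re-runs the
#' full leave-one-participant-out pipeline on each permutation, and reports
#' the add-one permutation p-value
#' `p = (1 + #\{null accuracy >= observed\}) / (B + 1)`. A convergence
#' check (whether the running p-value stays within 0.01 of its final value
#' over the last half of iterations) is reported, not enforced.
#'
#' For a fixed-penalty linear ridge spec the LOPO prediction is a linear
#' operator in the label vector, so all permutations are evaluated exactly
#' with one matrix product; every other spec takes the explicit refit path.
#'
#' @param features A `feature_table`.
#' @param spec A [model_spec()].
#' @param B Number of permutations (the study design used 2500).
#' @param seed Integer seed for the permutations.
#' @return Object of class `shuffle_test`: list with `observed` (the
#'   un-permuted `lopo_eval`), `p`, `null_accuracy` (length B),
#'   `converged`, `B`, `seed`.
#' @export
shuffle_test <- function(features, spec = model_spec(), B = 2500, seed = 1) {
  stopifnot(B >= 1)
  features <- features[order(features$participant_id), ]
  observed <- fit_predict_lopo(features, spec, seed = seed)
  y <- features$group
  n <- length(y)
  fast <- spec$kind == "linear_net" && length(spec$alpha) == 1 &&
    spec$alpha == 0 && length(spec$lambda) == 1
  if (fast) {
    feat_cols <- setdiff(names(features), c("participant_id", "group"))
    X <- as.matrix(features[, feat_cols])
    storage.mode(X) <- "double"
    A <- ridge_lopo_operator(X, spec$lambda, spec$standardize)
    Y <- with_seed(seed, {
      vapply(seq_len(B), function(b) as.numeric(sample(y) == "ASD"),
             numeric(n))
    })
    S <- A %*% Y
    null_acc <- colMeans((S > 0.5) == Y)
  } else {
    null_acc <- vapply(seq_len(B), function(b) {
      perm <- with_seed(derive_seed(seed, b), sample(y))
      f2 <- features
      f2$group <- perm
      fit_predict_lopo(f2, spec, seed = derive_seed(seed, b, 1))$accuracy
    }, numeric(1))
  }
  hits <- cumsum(null_acc >= observed$accuracy)
  p_run <- (1 + hits) / (seq_len(B) + 1)
  p <- p_run[B]
  lastB <- seq(max(1, floor(B / 2)), B)
  out <- list(observed = observed, p = p, null_accuracy = null_acc,
              converged = all(abs(p_run[lastB] - p) <= 0.01),
              B = B, seed = seed)
  class(out) <- "shuffle_test"
  out
}

#' @export
print.shuffle_test <- function(x, ...) {
  cat(sprintf(
    "<shuffle_test> observed accuracy %.3f, B = %d, p = %.4f%s\n",
    x$observed$accuracy, x$B, x$p,
    if (!x$converged) " (running p-value not yet converged)" else ""
  ))
  invisible(x)
}

#' The standard feature-subset list for ablation runs
#'
#' The fifteen family combinations evaluated in the ablation table:
#' metadata baseline, the full model, and all informative subsets of
#' cm/conf/gaze with and without metadata.
#'
#' @return Named list of character vectors of family names.
#' @export
ablation_subsets <- function() {
  l <- list(
    "pat" = "pat",
    "pat-gaze-cm-conf" = c("pat", "gaze", "cm", "conf"),
    "cm" = "cm",
    "conf" = "conf",
    "cm-conf" = c("cm", "conf"),
    "gaze" = "gaze",
    "gaze-conf" = c("gaze", "conf"),
    "gaze-cm" = c("gaze", "cm"),
    "gaze-cm-conf" = c("gaze", "cm", "conf"),
    "pat-gaze" = c("pat", "gaze"),
    "pat-gaze-cm" = c("pat", "gaze", "cm"),
    "pat-gaze-conf" = c("pat", "gaze", "conf"),
    "pat-cm" = c("pat", "cm"),
    "pat-conf" = c("pat", "conf"),
    "pat-cm-conf" = c("pat", "cm", "conf")
  )
  l
}

#' Feature-subset by trial ablation grid
#'
#' Evaluates a classifier on every requested feature-family subset and
#' trial selection, optionally with a shuffle test per cell.
#'
#' @param features A full `feature_table` built over all trials.
#' @param spec A [model_spec()].
#' @param subsets Named list of family subsets (default
#'   [ablation_subsets()]).
#' @param trials List of trial selections (default
#'   `list("all", 1, 2, 3)`).
#' @param B Shuffle iterations per cell (0 to skip significance).
#' @param seed Integer seed.
#' @return Tibble `subset`, `trial`, `accuracy`, `p` (NA when `B = 0`),
#'   `n`.
#' @export
ablation_grid <- function(features, spec = model_spec(),
                          subsets = ablation_subsets(),
                          trials = list("all", 1, 2, 3), B = 0, seed = 1) {
  cells <- tidyr::expand_grid(subset = names(subsets),
                              trial_sel = seq_along(trials))
  res <- purrr::pmap_dfr(cells, function(subset, trial_sel) {
    tr <- trials[[trial_sel]]
    f <- select_features(features, subsets[[subset]], tr)
    cell_seed <- derive_seed(seed, match(subset, names(subsets)), trial_sel)
    if (B > 0) {
      stest <- shuffle_test(f, spec, B = B, seed = cell_seed)
      acc <- stest$observed$accuracy
      p <- stest$p
    } else {
      acc <- fit_predict_lopo(f, spec, seed = cell_seed)$accuracy
      p <- NA_real_
    }
    tibble::tibble(
      subset = subset,
      trial = if (identical(tr, "all")) "all" else as.character(tr),
      accuracy = acc, p = p, n = nrow(f)
    )
  })
  res
}
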