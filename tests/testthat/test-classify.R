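test_that("separable clusters are classified perfectly under LOPO", {
  f <- separable_features()
  ev <- fit_predict_lopo(f, model_spec("elastic_net", alpha = 0.5,
                                       lambda = 0.05))
  expect_equal(ev$accuracy, 1)
  expect_equal(sum(diag(ev$confusion)), 30)
  g <- glance(ev)
  expect_equal(g$accuracy, 1)
  expect_equal(g$sensitivity, 1)
})

test_that("LOPO results are invariant to feature-table row order", {
  f <- separable_features(n_per = 8, gap = 1, seed = 3)
  spec <- model_spec("linear_net", lambda = 2)
  a <- fit_predict_lopo(f, spec)
  b <- fit_predict_lopo(f[rev(seq_len(nrow(f))), ], spec)
  expect_equal(a$predictions, b$predictions)
  expect_equal(a$accuracy, b$accuracy)
})

test_that("duplicating feature columns leaves predicted labels unchanged", {
  f <- separable_features(n_per = 10, gap = 3, seed = 5)
  f2 <- dplyr::bind_cols(f, setNames(f[, paste0("f", 1:4)],
                                     paste0("g", 1:4)))
  spec <- model_spec("elastic_net", alpha = 0.5, lambda = 0.05)
  a <- fit_predict_lopo(f, spec)
  b <- fit_predict_lopo(f2, spec)
  expect_equal(a$predictions$pred, b$predictions$pred)
})

test_that("LOPO errors when a class has fewer than two members", {
  f <- separable_features(n_per = 4)
  f$group[f$group == "NC"][1:3] <- "ASD"
  expect_error(fit_predict_lopo(f), "2 participants per class")
})

test_that("the closed-form ridge LOPO operator equals explicit refits", {
  f <- separable_features(n_per = 7, gap = 1.5, seed = 9)
  fo <- f[order(f$participant_id), ]
  X <- as.matrix(fo[, -(1:2)])
  y01 <- as.numeric(fo$group == "ASD")
  for (std in c(TRUE, FALSE)) {
    spec <- model_spec("linear_net", lambda = 3, standardize = std)
    scores <- fit_predict_lopo(f, spec)$predictions$score
    A <- phenogaze:::ridge_lopo_operator(X, 3, std)
    expect_equal(as.numeric(A %*% y01), scores, tolerance = 1e-10)
  }
})

test_that("fast-path shuffle accuracies equal explicit refit accuracies", {
  f <- separable_features(n_per = 6, gap = 0.8, seed = 8)
  spec <- model_spec("linear_net", lambda = 2)
  B <- 12
  st <- shuffle_test(f, spec, B = B, seed = 5)
  fo <- f[order(f$participant_id), ]
  y <- fo$group
  perms <- withr::with_seed(5, lapply(seq_len(B), function(b) sample(y)))
  explicit <- vapply(seq_len(B), function(b) {
    f2 <- fo
    f2$group <- perms[[b]]
    fit_predict_lopo(f2, spec)$accuracy
  }, numeric(1))
  expect_equal(st$null_accuracy, explicit, tolerance = 1e-12)
})

test_that("ridge solver agrees with glmnet at the matched penalty", {
  withr::with_seed(4, {
    X <- matrix(rnorm(40 * 6), 40)
    y <- rnorm(40)
  })
  n <- nrow(X)
  lam <- 0.7
  ours <- phenogaze:::ridge_fit(X, y, lambda = n * lam)
  gn <- glmnet::glmnet(X, y, family = "gaussian", alpha = 0,
                       lambda = c(5, 1, lam), standardize = FALSE,
                       thresh = 1e-14)
  b_gn <- as.numeric(coef(gn, s = lam, exact = TRUE, x = X, y = y))
  expect_equal(c(ours$intercept, ours$beta), b_gn, tolerance = 0.05)
  # the closed form attains at least glmnet's (approximate) objective
  obj <- function(b0, b) sum((y - b0 - X %*% b)^2) / (2 * n) +
    lam * sum(b^2) / 2
  expect_lte(obj(ours$intercept, ours$beta), obj(b_gn[1], b_gn[-1]) + 1e-10)
})

test_that("the add-one shuffle p-value respects its boundaries", {
  # constant feature: the leave-one-out group mean always sits on the
  # wrong side, observed accuracy 0, every permutation ties or beats it
  f <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:8),
    group = rep(c("ASD", "NC"), each = 4),
    f1 = rep(1, 8)
  )
  spec <- model_spec("linear_net", lambda = 1, standardize = FALSE)
  st <- shuffle_test(f, spec, B = 25, seed = 2)
  expect_equal(st$observed$accuracy, 0)
  expect_equal(st$p, 1)
  # separable clusters: observed beats every permutation, B = 99 -> 0.01
  fs <- separable_features(n_per = 15, gap = 8, seed = 6)
  st2 <- shuffle_test(fs, model_spec("linear_net", lambda = 0.5), B = 99,
                      seed = 3)
  expect_equal(st2$observed$accuracy, 1)
  expect_equal(st2$p, 0.01)
  expect_true(st2$p > 0 && st2$p <= 1)
})

test_that("the ablation grid covers every subset-by-trial cell", {
  co <- make_cohort(4, 4, seed = 2)
  sched <- make_schedule(c(9, 9), seed = 1)
  sim <- simulate_coded_cohort(co, sched, seed = 3)
  resp <- simulate_responses(co, sched, seed = 4)
  f <- build_features(co, resp, sim$coded, sched)
  subs <- ablation_subsets()
  expect_length(subs, 15)
  grid <- ablation_grid(f, model_spec("linear_net", lambda = 5),
                        subsets = subs[c("pat", "gaze", "cm-conf")],
                        trials = list("all", 1, 2))
  expect_equal(nrow(grid), 9)
  # pat is trial-invariant: identical accuracy in every trial column
  pat <- grid[grid$subset == "pat", ]
  expect_equal(length(unique(pat$accuracy)), 1)
})

test_that("tidiers expose predictions and summaries", {
  f <- separable_features(n_per = 5, gap = 5)
  ev <- fit_predict_lopo(f, model_spec("linear_net", lambda = 0.5))
  td <- tidy(ev)
  expect_named(td, c("participant_id", "truth", "pred", "score", "correct"))
  st <- shuffle_test(f, model_spec("linear_net", lambda = 0.5), B = 19,
                     seed = 1)
  expect_equal(nrow(tidy(st)), 19)
  gl <- glance(st)
  expect_true(gl$p.value > 0 && gl$p.value <= 1)
})
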