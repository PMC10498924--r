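# constant-probability stub model for protocol tests
stub_model <- function(p) structure(list(p = p), class = "petrad_stub")
predict_proba.petrad_stub <- function(model, newdata, ...) {
  rep(model$p, petrad:::n_samples(newdata))
}
registerS3method("predict_proba", "petrad_stub", predict_proba.petrad_stub)

test_that("stratified folds preserve proportions and are reproducible", {
  strata <- rep(c("I-II", "III-IV"), c(72, 67))   # 139 patients
  plan <- make_folds(strata, k = 5, seed = 1)
  sizes <- table(plan$fold)
  expect_true(all(sizes %in% c(27L, 28L)))
  expect_equal(sum(sizes), 139L)
  # per-fold stratum proportion within 1 patient of the global proportion
  for (f in 1:5) {
    in_fold <- sum(strata[plan$fold == f] == "I-II")
    expected <- 72 / 139 * sizes[[f]]
    expect_lte(abs(in_fold - expected), 1)
  }
  expect_identical(make_folds(strata, 5, seed = 1)$fold, plan$fold)
  expect_false(identical(make_folds(strata, 5, seed = 2)$fold, plan$fold))
  expect_error(make_folds(rep(c("a", "b"), c(3, 30)), k = 5), "stratum")
})

test_that("nested CV builds exactly 20 disjoint models with one internal
           prediction per patient", {
  set.seed(4)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, 0.5)
  if (length(unique(y)) == 1) y[1] <- 1 - y[1]
  plan <- make_folds(y, k = 5, seed = 2)
  factory <- function(Xtr, ytr, Xval, yval) stub_model(0.7)
  res <- nested_cv_train(factory, X, y, plan)
  expect_length(res$models, 20L)
  expect_equal(as.integer(table(vapply(res$models, `[[`, 1, "test_fold"))),
               rep(4L, 5))
  # no model's training set intersects its test fold
  for (m in res$models) {
    expect_length(intersect(m$train_index, which(plan$fold == m$test_fold)),
                  0L)
    expect_length(intersect(m$train_index, which(plan$fold == m$val_fold)),
                  0L)
  }
  # constant stub: every internal prediction is exactly 0.7
  expect_true(all(res$predictions$prob == 0.7))
  expect_equal(nrow(res$predictions), n)
  expect_false(any(is.na(res$predictions$prob)))
})

test_that("external prediction averages the member models", {
  stubs <- lapply(seq(0, 0.95, by = 0.05), stub_model)
  X <- matrix(0, 7, 2)
  p <- external_predict(stubs, X)
  expect_equal(p, rep(0.475, 7))
  # within the member range, order preserved
  expect_true(all(p >= 0 & p <= 0.95))
})

test_that("ensemble_combine averages aligned sets and rejects mismatches", {
  a <- c(p1 = 0.2, p2 = 0.8)
  b <- c(p1 = 0.8, p2 = 0.2)
  expect_equal(ensemble_combine(a, a), a)
  expect_equal(unname(ensemble_combine(a, b)), c(0.5, 0.5))
  expect_equal(unname(ensemble_combine(a, b, c(p1 = 0.5, p2 = 0.5))),
               c(0.5, 0.5))
  expect_error(ensemble_combine(a, c(p2 = 1, p1 = 0)), "different patient")
  expect_error(ensemble_combine(a, c(0.1, 0.2, 0.3)), "lengths")
})

test_that("metric suite: perfect, inverted, toy AUC and null AUC", {
  y <- c(0, 0, 1, 1)
  perfect <- metric_suite(y, c(0.1, 0.2, 0.8, 0.9))
  expect_true(all(perfect == 1))
  inverted <- metric_suite(y, c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unname(inverted["mcc_scaled"]), 0)
  expect_equal(unname(inverted["auc"]), 0)

  expect_equal(unname(metric_suite(y, c(0.1, 0.4, 0.35, 0.8))["auc"]), 0.75)

  set.seed(5)
  y2 <- rbinom(1e4, 1, 0.5)
  p2 <- runif(1e4)
  expect_lt(abs(auc_rank(y2, p2) - 0.5), 0.02)

  # degenerate denominators report 0 with a flag
  deg <- metric_suite(c(0, 0, 0, 1), c(0.1, 0.1, 0.2, 0.3))
  expect_equal(unname(deg["precision"]), 0)
  expect_true("precision" %in% attr(deg, "degenerate"))
})

test_that("balanced bootstrap: equal class draws, perfect-classifier medians,
           chance behaviour", {
  y <- rep(c(0, 1), c(30, 20))
  p_perfect <- ifelse(y == 1, 0.9, 0.1)
  rep1 <- balanced_bootstrap_metrics(y, p_perfect, n_boot = 100, seed = 1,
                                     return_indices = TRUE)
  expect_true(all(rep1$summary[, "median"] == 1))
  for (idx in rep1$indices) {
    expect_equal(sum(y[idx] == 0), sum(y[idx] == 1))
    expect_length(idx, rep1$replicate_size)
  }

  # constant 0.5 probabilities: accuracy and scaled MCC medians coincide
  set.seed(2)
  yb <- rbinom(200, 1, 0.5)
  pb <- rep(0.5, 200)
  rep2 <- balanced_bootstrap_metrics(yb, pb, n_boot = 200, seed = 3)
  expect_equal(rep2$summary["accuracy", "median"], 0.5, tolerance = 0.02)
  expect_lt(abs(rep2$summary["accuracy", "median"] -
                  rep2$summary["mcc_scaled", "median"]), 0.02)
  expect_error(balanced_bootstrap_metrics(rep(1, 5), runif(5)),
               "both classes")
})
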