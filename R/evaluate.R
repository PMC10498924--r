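# Training/evaluation workflow: stratified folds, nested five-fold CV with
# ensemble averaging (20 models), external-cohort ensembling, and
# class-balanced bootstrap metrics.

#' Stratified fold assignment
#'
#' Partitions the cohort into `k` folds preserving the stratum proportions
#' (e.g. TNM stage I-II vs III-IV) within one patient per fold.
#'
#' @param strata stratification label per patient (any atomic vector), or a
#'   `phantom_cohort` (stratified on its `stage_group`).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return object of class `fold_plan`: `fold` (1..k per patient),
#'   `strata`, `k`, `seed`.
#' @export
make_folds <- function(strata, k = 5L, seed = NULL) {
  if (inherits(strata, "phantom_cohort")) strata <- strata$clinical$stage_group
  n <- length(strata)
  tab <- table(strata)
  if (any(tab < k))
    stop("every stratum needs at least k members; smallest has ", min(tab))
  fold <- integer(n)
  with_seed(seed, {
    start <- 0L   # rotate the deal across strata so leftovers spread out
    for (s in names(tab)) {
      ix <- sample(which(strata == s))
      fold[ix] <- ((seq_along(ix) - 1L + start) %% k) + 1L
      start <- (start + length(ix)) %% k
    }
  })
  structure(list(fold = fold, strata = strata, k = as.integer(k),
                 seed = seed), class = "fold_plan")
}

# uniform subsetting across the supported data containers
subset_data <- function(data, idx) {
  if (is.matrix(data)) return(data[idx, , drop = FALSE])
  if (is.array(data) && length(dim(data)) == 5L) {
    out <- data[, , , , idx, drop = FALSE]
    return(out)
  }
  if (is.list(data)) return(data[idx])
  data[idx]
}

#' Nested five-fold cross-validation with ensemble averaging
#'
#' For each outer test fold, one model is trained per remaining validation
#' fold (training on the other three folds), giving `k - 1` models per test
#' fold and `k (k - 1)` models total (20 for k = 5). The per-patient
#' internal prediction is the ensemble average of that fold's models, so
#' stacking the test folds yields exactly one prediction per patient.
#'
#' @param model_factory `function(train_data, train_y, val_data, val_y)`
#'   returning a fitted model supporting [predict_proba()].
#' @param data feature matrix, 5D volume array, or list of samples.
#' @param y binary outcome.
#' @param fold_plan a [make_folds()] plan.
#' @return list: `models` (each with `fit`, `test_fold`, `val_fold`),
#'   `predictions` (data frame `index`, `y`, `prob`, `test_fold`), `k`.
#' @export
nested_cv_train <- function(model_factory, data, y, fold_plan) {
  k <- fold_plan$k
  fold <- fold_plan$fold
  models <- list()
  pred <- rep(NA_real_, length(y))
  for (test_f in seq_len(k)) {
    test_ix <- which(fold == test_f)
    probs <- matrix(0, length(test_ix), 0)
    for (val_f in setdiff(seq_len(k), test_f)) {
      train_ix <- which(!fold %in% c(test_f, val_f))
      val_ix <- which(fold == val_f)
      fit <- tryCatch(
        model_factory(subset_data(data, train_ix), y[train_ix],
                      subset_data(data, val_ix), y[val_ix]),
        error = function(e) stop(sprintf(
          "model training failed for (test fold %d, val fold %d): %s",
          test_f, val_f, conditionMessage(e))))
      models[[length(models) + 1L]] <-
        list(fit = fit, test_fold = test_f, val_fold = val_f,
             train_index = train_ix)
      probs <- cbind(probs,
                     predict_proba(fit, subset_data(data, test_ix)))
    }
    pred[test_ix] <- rowMeans(probs)
  }
  list(models = models,
       predictions = data.frame(index = seq_along(y), y = y, prob = pred,
                                test_fold = fold),
       k = k)
}

#' Ensemble-average predictions of the nested-CV models on a new cohort
#'
#' @param models the `models` element of [nested_cv_train()] (or any list
#'   of fitted models / of lists with a `fit` element).
#' @param newdata external-cohort data container.
#' @return per-patient mean class-1 probability.
#' @export
external_predict <- function(models, newdata) {
  probs <- vapply(models, function(m) {
    fit <- if (is.list(m) && !is.null(m$fit)) m$fit else m
    predict_proba(fit, newdata)
  }, numeric(n_samples(newdata)))
  rowMeans(as.matrix(probs))
}

n_samples <- function(data) {
  if (is.matrix(data)) nrow(data)
  else if (is.array(data) && length(dim(data)) == 5L) dim(data)[5]
  else length(data)
}

#' Combine prediction sets by ensemble averaging
#'
#' Element-wise mean of class-1 probabilities across model families. All
#' sets must cover the same patients in the same order (names checked when
#' present).
#'
#' @param ... numeric probability vectors.
#' @return mean probability vector.
#' @export
ensemble_combine <- function(...) {
  sets <- list(...)
  n <- unique(vapply(sets, length, integer(1)))
  if (length(n) != 1L) stop("prediction sets have different lengths")
  nms <- lapply(sets, names)
  nms <- nms[!vapply(nms, is.null, logical(1))]
  if (length(nms) > 1L && !all(vapply(nms[-1], identical, logical(1), nms[[1]])))
    stop("prediction sets cover different patient ids")
  Reduce(`+`, sets) / length(sets)
}

#' Rank-statistic AUC
#'
#' Equivalent to the Mann-Whitney statistic: ties contribute 1/2.
#'
#' @param y binary labels (both classes present).
#' @param p scores.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(y, p) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes")
  r <- rank(p)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Full metric suite at a probability threshold
#'
#' Accuracy, AUC, scaled MCC (`(mcc + 1) / 2`), F1 on class 1 and on
#' class 0 (class 0 treated as the positive class), precision, recall and
#' specificity. Metrics with a degenerate denominator are reported as 0 and
#' flagged (attribute `degenerate`).
#'
#' @param y_true binary labels with both classes present.
#' @param y_prob class-1 probabilities.
#' @param threshold decision threshold in (0, 1).
#' @return named numeric vector with attribute `degenerate`.
#' @export
metric_suite <- function(y_true, y_prob, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  y <- stopifnot_binary(y_true)
  yh <- hard_labels(y_prob, threshold)
  tp <- sum(y == 1 & yh == 1); fp <- sum(y == 0 & yh == 1)
  tn <- sum(y == 0 & yh == 0); fn <- sum(y == 1 & yh == 0)
  flags <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); return(0) }
    num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  specificity <- safe(tn, tn + fp, "specificity")
  f1_1 <- safe(2 * tp, 2 * tp + fp + fn, "f1_class1")
  f1_0 <- safe(2 * tn, 2 * tn + fn + fp, "f1_class0")
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) { flags <- c(flags, "mcc"); 0 }
         else (tp * tn - fp * fn) / mcc_den
  out <- c(accuracy = (tp + tn) / length(y),
           auc = auc_rank(y, y_prob),
           mcc_scaled = (mcc + 1) / 2,
           f1_class1 = f1_1, f1_class0 = f1_0,
           precision = precision, recall = recall,
           specificity = specificity)
  attr(out, "degenerate") <- flags
  out
}

#' Class-balanced bootstrap metrics
#'
#' Every replicate draws the same number of patients from each class with
#' replacement (count = the minority class size, giving the 1:1 ratio);
#' the metric suite is computed per replicate and summarized by the median
#' and the 2.5/97.5 percentile interval.
#'
#' @param y_true binary labels with both classes present.
#' @param probs class-1 probabilities.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param threshold decision threshold.
#' @param return_indices keep the drawn index vectors (for auditing)?
#' @return object of class `metric_report`: `summary` (metrics x
#'   median/lo/hi matrix), `n_boot`, `ratio`, and optionally `indices`.
#' @export
balanced_bootstrap_metrics <- function(y_true, probs, n_boot = 1000L,
                                       seed = NULL, threshold = 0.5,
                                       return_indices = FALSE) {
  y <- stopifnot_binary(y_true)
  ix0 <- which(y == 0L); ix1 <- which(y == 1L)
  m <- min(length(ix0), length(ix1))
  with_seed(seed, {
    reps <- matrix(NA_real_, n_boot, 8L)
    indices <- if (return_indices) vector("list", n_boot) else NULL
    for (b in seq_len(n_boot)) {
      idx <- c(sample(ix0, m, replace = TRUE), sample(ix1, m, replace = TRUE))
      reps[b, ] <- metric_suite(y[idx], probs[idx], threshold)
      if (return_indices) indices[[b]] <- idx
    }
    colnames(reps) <- names(metric_suite(y, probs, threshold))
    summ <- t(apply(reps, 2, quantile, c(0.5, 0.025, 0.975), names = FALSE))
    colnames(summ) <- c("median", "lo", "hi")
    structure(list(summary = summ, n_boot = n_boot, ratio = "1:1",
                   replicate_size = 2L * m, indices = indices),
              class = "metric_report")
  })
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Class-balanced bootstrap metrics (%d replicates, %s, %d per replicate)\n",
              x$n_boot, x$ratio, x$replicate_size))
  print(round(x$summary, 3))
  invisible(x)
}
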