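# Tabular model family M1 (logistic regression) and M2 (bagged forest),
# behind the uniform predict_proba() contract shared by all models M1-M7.

#' Class-1 probability predictions
#'
#' Uniform contract for every model in the family: probabilities in
#' \[0, 1\]; hard labels are 1 iff probability >= 0.5 (see
#' [hard_labels()]).
#'
#' @param model a fitted model object.
#' @param newdata feature matrix (tabular models) or volume array (CNN).
#' @param ... method-specific arguments.
#' @return numeric probability vector.
#' @export
predict_proba <- function(model, newdata, ...) UseMethod("predict_proba")

#' Hard labels at the 0.5 probability threshold
#'
#' @param prob probability vector.
#' @param threshold decision threshold (default 0.5).
#' @return integer 0/1 labels, 1 iff `prob >= threshold`.
#' @export
hard_labels <- function(prob, threshold = 0.5) as.integer(prob >= threshold)

#' M1: regularized logistic regression
#'
#' Elastic-net logistic regression via glmnet; the default `l1_ratio = 0`
#' gives ridge.
#'
#' @param X standardized feature matrix.
#' @param y binary outcome (both classes present).
#' @param reg regularization strength (glmnet lambda).
#' @param l1_ratio elastic-net mixing (glmnet alpha).
#' @return object of class `petrad_m1`.
#' @export
fit_m1_logistic <- function(X, y, reg = 0.01, l1_ratio = 0) {
  y <- stopifnot_binary(y)
  fit <- suppressWarnings(           # benign small-class warning on tiny folds
    glmnet::glmnet(X, y, family = "binomial", alpha = l1_ratio,
                   lambda = reg, standardize = FALSE))
  structure(list(fit = fit, reg = reg, features = colnames(X)),
            class = "petrad_m1")
}

#' @export
predict_proba.petrad_m1 <- function(model, newdata, ...) {
  as.numeric(stats::predict(model$fit,
                            newdata[, model$features, drop = FALSE],
                            s = model$reg, type = "response"))
}

#' Coefficients of an M1 model
#' @param object a `petrad_m1`.
#' @param ... unused.
#' @return named coefficient vector including the intercept.
#' @export
coef.petrad_m1 <- function(object, ...) {
  cf <- as.numeric(glmnet::coef.glmnet(object$fit, s = object$reg))
  names(cf) <- c("(Intercept)", object$features)
  cf
}

# ---- M2: bagged CART forest (no forest package in this stack) ----------

# Grow one gini tree. Split search: for `mtry` candidate features, evaluate
# the gini decrease of every midpoint threshold; ties and zero-gain splits
# are allowed while the node is impure (required for XOR-type targets).
grow_tree <- function(X, y, mtry, min_node, max_depth, depth = 0L) {
  n <- length(y)
  p1 <- mean(y)
  if (n < 2L * min_node || p1 == 0 || p1 == 1 || depth >= max_depth) {
    return(list(leaf = TRUE, prob = p1))
  }
  feats <- sample.int(ncol(X), min(mtry, ncol(X)))
  best <- NULL
  best_gain <- -Inf
  imp <- 2 * p1 * (1 - p1)
  for (j in feats) {
    v <- X[, j]
    cuts <- sort(unique(v))
    if (length(cuts) < 2L) next
    thr <- (cuts[-1] + cuts[-length(cuts)]) / 2
    for (t in thr) {
      left <- v <= t
      nl <- sum(left)
      if (nl < min_node || n - nl < min_node) next
      pl <- mean(y[left]); pr <- mean(y[!left])
      child <- (nl * 2 * pl * (1 - pl) + (n - nl) * 2 * pr * (1 - pr)) / n
      gain <- imp - child
      if (gain > best_gain) {
        best_gain <- gain
        best <- list(j = j, t = t, left = left)
      }
    }
  }
  if (is.null(best) || best_gain < 0) return(list(leaf = TRUE, prob = p1))
  list(leaf = FALSE, j = best$j, t = best$t,
       left = grow_tree(X[best$left, , drop = FALSE], y[best$left],
                        mtry, min_node, max_depth, depth + 1L),
       right = grow_tree(X[!best$left, , drop = FALSE], y[!best$left],
                         mtry, min_node, max_depth, depth + 1L))
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  rec <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (node$leaf) {
      out[idx] <<- node$prob
      return(invisible())
    }
    go_left <- X[idx, node$j] <= node$t
    rec(node$left, idx[go_left])
    rec(node$right, idx[!go_left])
  }
  rec(tree, seq_len(n))
  out
}

#' M2: bagged random forest classifier
#'
#' From-scratch CART/gini forest: each tree is grown on a bootstrap (or
#' full, when `replace = FALSE` and `sample_fraction = 1`) sample, with
#' `mtry` candidate features per split. Probabilities are the mean of the
#' per-tree leaf class-1 fractions.
#'
#' @param X feature matrix.
#' @param y binary outcome.
#' @param n_estimators number of trees.
#' @param max_features `"sqrt"`, `"all"`, or an integer mtry.
#' @param min_node minimum leaf size.
#' @param max_depth depth cap.
#' @param sample_fraction per-tree sample fraction.
#' @param replace bootstrap with replacement?
#' @param seed RNG seed.
#' @return object of class `petrad_m2`.
#' @export
fit_m2_forest <- function(X, y, n_estimators = 100L, max_features = "sqrt",
                          min_node = 1L, max_depth = 12L,
                          sample_fraction = 1, replace = TRUE, seed = NULL) {
  y <- stopifnot_binary(y)
  mtry <- if (identical(max_features, "sqrt")) max(1L, floor(sqrt(ncol(X))))
          else if (identical(max_features, "all")) ncol(X)
          else as.integer(max_features)
  n <- nrow(X)
  trees <- with_seed(seed, lapply(seq_len(n_estimators), function(b) {
    idx <- sample.int(n, size = round(sample_fraction * n), replace = replace)
    if (length(unique(y[idx])) < 2L) idx <- seq_len(n)   # degenerate draw
    grow_tree(X[idx, , drop = FALSE], y[idx], mtry, min_node, max_depth)
  }))
  structure(list(trees = trees, features = colnames(X)),
            class = "petrad_m2")
}

#' @export
predict_proba.petrad_m2 <- function(model, newdata, ...) {
  if (!is.null(model$features))
    newdata <- newdata[, model$features, drop = FALSE]
  rowMeans(vapply(model$trees, function(tr) predict_tree(tr, newdata),
                  numeric(nrow(newdata))))
}

#' Weighted hyperparameter score
#'
#' Weighted mean of validation AUC, validation scaled MCC, validation F1 on
#' class 1 and class 0, and training F1 on class 1; equal weights by
#' default. Weights not summing to 1 are normalized with a warning.
#'
#' @param val_auc,val_mcc,val_f1_c1,val_f1_c0,train_f1_c1 components in
#'   \[0, 1\].
#' @param weights length-5 nonnegative weight vector.
#' @return scalar score in \[0, 1\].
#' @export
weighted_score <- function(val_auc, val_mcc, val_f1_c1, val_f1_c0,
                           train_f1_c1, weights = rep(0.2, 5)) {
  comp <- c(val_auc, val_mcc, val_f1_c1, val_f1_c0, train_f1_c1)
  stopifnot(length(weights) == 5L, all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8) {
    warning("weights do not sum to 1; normalizing")
    weights <- weights / sum(weights)
  }
  sum(weights * comp)
}
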