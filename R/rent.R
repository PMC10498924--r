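# RENT: repeated elastic net stability feature selection, plus the
# brute-force repeated stratified K-fold frequency protocol.
#
# A RENT run trains K elastic-net-regularized logistic models on K random
# stratified subsets of the training data and summarizes, per feature,
# three stability criteria on the ensemble weight matrix:
#   c1 - fraction of models with a nonzero weight,
#   c2 - |sum of weight signs| / K,
#   c3 - one-sample t-test of the K weights against zero.
# A feature is selected when all three pass their thresholds.

#' RENT configuration
#'
#' @param n_models K, size of the model ensemble (>= 2).
#' @param subset_fraction per-model training fraction in (0, 1); subsets
#'   are stratified draws without replacement.
#' @param l1_ratio elastic-net mixing in \[0, 1\] (glmnet `alpha`).
#' @param reg_strength regularization strength (glmnet `lambda`).
#' @param tau1 threshold on the nonzero-frequency criterion c1.
#' @param tau2 threshold on the sign-agreement criterion c2.
#' @param tau3 one-sided significance level for the t-test criterion c3.
#' @return object of class `rent_config`.
#' @export
rent_config <- function(n_models = 100L, subset_fraction = 0.8,
                        l1_ratio = 0.5, reg_strength = 0.1,
                        tau1 = 0.9, tau2 = 0.9, tau3 = 0.05) {
  if (n_models < 2L) stop("need at least 2 ensemble models")
  if (subset_fraction <= 0 || subset_fraction >= 1)
    stop("subset_fraction must be in (0,1)")
  if (l1_ratio < 0 || l1_ratio > 1) stop("l1_ratio must be in [0,1]")
  structure(list(n_models = as.integer(n_models),
                 subset_fraction = subset_fraction, l1_ratio = l1_ratio,
                 reg_strength = reg_strength,
                 tau1 = tau1, tau2 = tau2, tau3 = tau3),
            class = "rent_config")
}

# stratified subsample of indices: `fraction` of each class, no replacement
stratified_subsample <- function(y, fraction) {
  unlist(lapply(split(seq_along(y), y), function(ix) {
    k <- max(1L, round(fraction * length(ix)))
    if (length(ix) == 1L) ix else sample(ix, k)
  }), use.names = FALSE)
}

#' Fit one RENT ensemble
#'
#' @param X standardized numeric feature matrix (column names required).
#' @param y binary 0/1 outcome with both classes present.
#' @param config a [rent_config()].
#' @param seed RNG seed.
#' @return object of class `rent_result`: `weights` (K x p coefficient
#'   matrix), `intercepts`, `criteria` (data frame with c1, c2, c3
#'   p-values), `selected` (character vector), `config`.
#' @export
fit_rent <- function(X, y, config = rent_config(), seed = NULL) {
  y <- stopifnot_binary(y)
  stopifnot(is.matrix(X), !is.null(colnames(X)), ncol(X) >= 2L)
  K <- config$n_models
  with_seed(seed, {
    W <- matrix(0, K, ncol(X), dimnames = list(NULL, colnames(X)))
    b0 <- numeric(K)
    for (k in seq_len(K)) {
      repeat {
        idx <- stratified_subsample(y, config$subset_fraction)
        if (length(unique(y[idx])) == 2L) break
      }
      # small stratified subsets trip glmnet's benign class-size warning
      fit <- suppressWarnings(
        glmnet::glmnet(X[idx, , drop = FALSE], y[idx],
                       family = "binomial", alpha = config$l1_ratio,
                       lambda = config$reg_strength,
                       standardize = FALSE))
      cf <- as.numeric(glmnet::coef.glmnet(fit, s = config$reg_strength))
      b0[k] <- cf[1]
      W[k, ] <- cf[-1]
    }
    res <- structure(list(weights = W, intercepts = b0,
                          criteria = rent_criteria(W),
                          config = config), class = "rent_result")
    crit <- res$criteria
    res$selected <- crit$feature[crit$c1 >= config$tau1 &
                                 crit$c2 >= config$tau2 &
                                 crit$c3_p < config$tau3]
    res
  })
}

#' Recompute the three RENT stability criteria from a weight matrix
#'
#' @param W K x p matrix of ensemble coefficients.
#' @return data frame: feature, c1 (nonzero fraction), c2 (normalized
#'   absolute sign sum), c3_t, c3_p (one-sided t-test p-value of the
#'   weights against zero, in the direction of the observed mean).
#' @export
rent_criteria <- function(W) {
  K <- nrow(W)
  c1 <- colMeans(W != 0)
  c2 <- abs(colSums(sign(W))) / K
  mu <- colMeans(W)
  s <- apply(W, 2, sd)
  tt <- ifelse(s > 0, sqrt(K) * abs(mu) / s, ifelse(mu != 0, Inf, 0))
  p <- pt(tt, df = K - 1, lower.tail = FALSE)
  p[s == 0 & mu == 0] <- 1        # constant-zero feature: never significant
  data.frame(feature = colnames(W), c1 = unname(c1), c2 = unname(c2),
             c3_t = unname(tt), c3_p = unname(p), row.names = NULL)
}

#' Predict event probabilities with a RENT ensemble
#'
#' Mean of the K member logistic probabilities.
#'
#' @param object a `rent_result`.
#' @param newX standardized feature matrix.
#' @return probability vector.
#' @export
predict_rent <- function(object, newX) {
  lp <- sweep(newX[, colnames(object$weights), drop = FALSE] %*%
                t(object$weights), 2, object$intercepts, "+")
  rowMeans(sigmoid(lp))
}

#' Brute-force RENT: repeated stratified K-fold selection frequencies
#'
#' For each hyperparameter combination, runs [fit_rent()] on the training
#' side of every partition of a repeated stratified K-fold scheme
#' (`n_splits x n_repeats` runs; 5 x 20 = 100 by default) and records which
#' features each run selects. The selection frequency is the percentage of
#' runs selecting a feature. Standardization is fit on each training
#' partition and applied to its held-out fold; predictive performance of
#' each run's ensemble on the held-out fold (MCC at threshold 0.5 by
#' default) scores the hyperparameter combination.
#'
#' @param X raw (unstandardized) feature matrix.
#' @param y binary outcome.
#' @param hyperparam_grid data frame with columns `l1_ratio` and
#'   `reg_strength`, one row per combination.
#' @param n_splits folds per repeat (>= 2).
#' @param n_repeats repeats.
#' @param config base [rent_config()] supplying K, subset fraction and
#'   thresholds.
#' @param seed RNG seed.
#' @param metric held-out scoring metric (`"mcc"` or `"auc"`).
#' @return list: `frequency` (combinations x features matrix, percent),
#'   `scores` (mean held-out score per combination), `best` (row index),
#'   `best_hyperparams`, `best_frequency` (named percent vector for the
#'   winning combination), `n_runs`.
#' @export
brute_force_rent <- function(X, y, hyperparam_grid, n_splits = 5L,
                             n_repeats = 20L, config = rent_config(),
                             seed = NULL, metric = c("mcc", "auc")) {
  metric <- match.arg(metric)
  y <- stopifnot_binary(y)
  if (n_splits < 2L) stop("n_splits must be >= 2")
  if (nrow(hyperparam_grid) == 0L) stop("hyperparameter grid is empty")
  n_runs <- n_splits * n_repeats
  seeds <- child_seeds(seed, n_repeats * nrow(hyperparam_grid) + n_repeats)

  freq <- matrix(0, nrow(hyperparam_grid), ncol(X),
                 dimnames = list(NULL, colnames(X)))
  scores <- numeric(nrow(hyperparam_grid))
  runs_done <- integer(nrow(hyperparam_grid))
  for (g in seq_len(nrow(hyperparam_grid))) {
    cfg <- config
    cfg$l1_ratio <- hyperparam_grid$l1_ratio[g]
    cfg$reg_strength <- hyperparam_grid$reg_strength[g]
    run_scores <- numeric(0)
    run <- 0L
    for (r in seq_len(n_repeats)) {
      folds <- with_seed(seeds[[r]],          # same partitions for every combo
                         make_folds(y, k = n_splits)$fold)
      for (f in seq_len(n_splits)) {
        run <- run + 1L
        tr <- folds != f
        sc <- scale_fit(X[tr, , drop = FALSE])
        Xtr <- scale_apply(X[tr, , drop = FALSE], sc)
        Xte <- scale_apply(X[!tr, , drop = FALSE], sc)
        run_seed <- (seeds[[n_repeats + (g - 1L) * n_repeats + r]] + f) %%
          .Machine$integer.max
        res <- fit_rent(Xtr, y[tr], cfg, seed = run_seed)
        freq[g, res$selected] <- freq[g, res$selected] + 1
        p <- predict_rent(res, Xte)
        run_scores[run] <- if (metric == "mcc") {
          metric_suite(y[!tr], p)[["mcc_scaled"]]
        } else {
          auc_rank(y[!tr], p)
        }
      }
    }
    scores[g] <- mean(run_scores)
    runs_done[g] <- run
  }
  freq <- freq / n_runs * 100
  best <- which.max(scores)
  list(frequency = freq, scores = scores, best = best,
       best_hyperparams = hyperparam_grid[best, , drop = FALSE],
       best_frequency = freq[best, ], n_runs = n_runs,
       runs_per_combination = runs_done)
}

#' Features at or above a selection-frequency cutoff
#'
#' @param frequencies named percent vector (0-100).
#' @param cutoff_percent cutoff in (0, 100\].
#' @return character vector of feature names; warns when empty.
#' @export
frequency_subset <- function(frequencies, cutoff_percent) {
  if (cutoff_percent <= 0 || cutoff_percent > 100)
    stop("cutoff must be in (0, 100]")
  out <- names(frequencies)[frequencies >= cutoff_percent]
  if (length(out) == 0L)
    warning("no feature reaches a selection frequency of ", cutoff_percent, "%")
  out
}

# column scaler helpers shared by rent / tabular_prep; binary columns and
# zero-variance columns are left unscaled (flagged in `scaled`)
scale_fit <- function(X, binary_untouched = TRUE) {
  is_bin <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  s <- apply(X, 2, sd)
  scaled <- (!binary_untouched | !is_bin) & s > 0
  list(center = ifelse(scaled, colMeans(X), 0),
       scale = ifelse(scaled, s, 1), scaled = scaled)
}

scale_apply <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}
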