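# M3/M4: fully connected networks on tabular data, trained by
# manually-derived backpropagation (no deep-learning package exists in this
# stack). M4 prepends an explicit pairwise multiplicative interaction block
# to the input so the first layer sees x_i * x_j terms.

relu <- function(x) pmax(x, 0)

# pairwise products x_i * x_j (i < j) appended to X
interaction_expand <- function(X) {
  p <- ncol(X)
  if (p < 2L) return(X)
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  inter <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
  colnames(inter) <- paste0(colnames(X)[pairs[, 1]], ":",
                            colnames(X)[pairs[, 2]])
  cbind(X, inter)
}

# focal-loss gradient w.r.t. the pre-sigmoid logit, averaged over the batch
focal_grad <- function(p, y, gamma = 2) {
  eps <- 1e-12
  pp <- pmin(pmax(p, eps), 1 - eps)
  # pt = p if y==1 else 1-p ; L = -(1-pt)^g log(pt)
  pt <- ifelse(y == 1, pp, 1 - pp)
  dL_dpt <- gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt
  dpt_dlogit <- ifelse(y == 1, pp * (1 - pp), -pp * (1 - pp))
  dL_dpt * dpt_dlogit / length(y)
}

adam_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    state$params[[nm]] <- state$params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  state
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(params = params, m = zeros, v = zeros, t = 0L)
}

#' Fit a fully connected network (M3/M4)
#'
#' Single sigmoid output; hidden layers use ReLU, trained full-batch with
#' Adam. With `interactions = TRUE` (M4) the input is augmented with all
#' pairwise products before the first layer.
#'
#' @param X feature matrix (standardize continuous columns first).
#' @param y binary outcome.
#' @param hidden integer vector of hidden-layer widths.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param dropout dropout rate on hidden activations during training.
#' @param l2 weight decay.
#' @param loss `"bce"` or `"focal"` (gamma = 2).
#' @param interactions add the pairwise interaction block (M4)?
#' @param seed RNG seed (weight init, dropout).
#' @return object of class `petrad_fcnn`.
#' @export
fit_fcnn <- function(X, y, hidden = 16L, epochs = 300L, lr = 0.01,
                     dropout = 0, l2 = 1e-4, loss = c("bce", "focal"),
                     interactions = FALSE, seed = NULL) {
  loss <- match.arg(loss)
  y <- stopifnot_binary(y)
  raw_names <- colnames(X)
  if (interactions) X <- interaction_expand(X)
  widths <- c(ncol(X), hidden, 1L)
  L <- length(widths) - 1L

  with_seed(seed, {
    params <- list()
    for (l in seq_len(L)) {
      params[[paste0("W", l)]] <- matrix(
        rnorm(widths[l] * widths[l + 1], 0, sqrt(2 / widths[l])),
        widths[l], widths[l + 1])
      params[[paste0("b", l)]] <- rep(0, widths[l + 1])
    }
    st <- adam_init(params)
    for (ep in seq_len(epochs)) {
      pr <- params
      # forward
      acts <- list(X)
      drops <- list()
      for (l in seq_len(L - 1L)) {
        z <- sweep(acts[[l]] %*% st$params[[paste0("W", l)]], 2,
                   st$params[[paste0("b", l)]], "+")
        a <- relu(z)
        if (dropout > 0) {
          mask <- matrix(runif(length(a)) >= dropout, nrow(a)) / (1 - dropout)
          a <- a * mask
          drops[[l]] <- mask
        }
        acts[[l + 1L]] <- a
      }
      logit <- sweep(acts[[L]] %*% st$params[[paste0("W", L)]], 2,
                     st$params[[paste0("b", L)]], "+")
      p <- sigmoid(as.vector(logit))
      if (any(!is.finite(p))) stop("divergent FCNN loss (non-finite output); ",
                                   "lower the learning rate")
      # backward
      dlogit <- if (loss == "bce") (p - y) / length(y) else focal_grad(p, y)
      grads <- list()
      delta <- matrix(dlogit, ncol = 1L)
      for (l in rev(seq_len(L))) {
        grads[[paste0("W", l)]] <- crossprod(acts[[l]], delta) +
          l2 * st$params[[paste0("W", l)]]
        grads[[paste0("b", l)]] <- colSums(delta)
        if (l > 1L) {
          delta <- delta %*% t(st$params[[paste0("W", l)]])
          if (dropout > 0) delta <- delta * drops[[l - 1L]]
          delta <- delta * (acts[[l]] > 0)
        }
      }
      st <- adam_step(st, grads, lr)
    }
    structure(list(params = st$params, widths = widths, L = L,
                   interactions = interactions, raw_features = raw_names,
                   loss = loss),
              class = "petrad_fcnn")
  })
}

#' M3: fully connected network without interactions
#' @inheritParams fit_fcnn
#' @param ... passed to [fit_fcnn()].
#' @return a `petrad_fcnn`.
#' @export
fit_m3_fcnn <- function(X, y, ...) fit_fcnn(X, y, interactions = FALSE, ...)

#' M4: fully connected network with a pairwise interaction block
#' @inheritParams fit_fcnn
#' @param ... passed to [fit_fcnn()].
#' @return a `petrad_fcnn`.
#' @export
fit_m4_fcnn_interactions <- function(X, y, ...)
  fit_fcnn(X, y, interactions = TRUE, ...)

fcnn_forward <- function(model, X, keep = FALSE) {
  if (model$interactions) X <- interaction_expand(X)
  acts <- list(X)
  for (l in seq_len(model$L - 1L)) {
    z <- sweep(acts[[l]] %*% model$params[[paste0("W", l)]], 2,
               model$params[[paste0("b", l)]], "+")
    acts[[l + 1L]] <- relu(z)
  }
  logit <- as.vector(sweep(acts[[model$L]] %*%
                             model$params[[paste0("W", model$L)]], 2,
                           model$params[[paste0("b", model$L)]], "+"))
  if (keep) list(p = sigmoid(logit), logit = logit, acts = acts)
  else sigmoid(logit)
}

#' @export
predict_proba.petrad_fcnn <- function(model, newdata, ...) {
  if (!is.null(model$raw_features) && !is.null(colnames(newdata)))
    newdata <- newdata[, model$raw_features, drop = FALSE]
  fcnn_forward(model, newdata)
}

# gradient of the class-1 probability (or logit) w.r.t. the raw inputs
fcnn_input_gradient <- function(model, X, target = c("probability", "logit")) {
  target <- match.arg(target)
  fw <- fcnn_forward(model, X, keep = TRUE)
  delta <- matrix(if (target == "probability") fw$p * (1 - fw$p) else 1,
                  ncol = 1L)
  for (l in rev(seq_len(model$L))) {
    delta <- delta %*% t(model$params[[paste0("W", l)]])
    if (l > 1L) delta <- delta * (fw$acts[[l]] > 0)
  }
  if (model$interactions) {
    p <- if (!is.null(model$raw_features)) length(model$raw_features)
         else ncol(X)
    base <- delta[, seq_len(p), drop = FALSE]
    pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    dint <- delta[, -seq_len(p), drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      base[, i] <- base[, i] + dint[, k] * X[, j]
      base[, j] <- base[, j] + dint[, k] * X[, i]
    }
    delta <- base
  }
  delta
}
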