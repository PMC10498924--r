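# Independent brute-force oracles. These deliberately re-derive each
# quantity by naive enumeration, sharing no code with the implementation.

# mean PET over all grid voxels within r_mm of each in-mask center; max.
oracle_suv_peak <- function(pet, mask, spacing = 1, volume_mm3 = 1000) {
  spacing <- rep(spacing, length.out = 3)
  r2 <- (3 * volume_mm3 / (4 * pi))^(2 / 3)
  d <- dim(pet)
  all_idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                   k = seq_len(d[3])))
  phys <- sweep(all_idx, 2, spacing, "*")
  centers <- which(mask > 0, arr.ind = TRUE)
  best <- -Inf
  for (c in seq_len(nrow(centers))) {
    cp <- centers[c, ] * spacing
    d2 <- (phys[, 1] - cp[1])^2 + (phys[, 2] - cp[2])^2 + (phys[, 3] - cp[3])^2
    best <- max(best, mean(pet[all_idx[d2 <= r2, , drop = FALSE]]))
  }
  best
}

oracle_dirs13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# symmetric co-occurrence count matrices by explicit voxel-pair loops
oracle_glcm <- function(levels, ng) {
  d <- dim(levels)
  out <- array(0, c(ng, ng, 13))
  for (dd in 1:13) {
    v <- oracle_dirs13[dd, ]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      a <- levels[i, j, k]
      if (is.na(a)) next
      ii <- i + v[1]; jj <- j + v[2]; kk <- k + v[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
        next
      b <- levels[ii, jj, kk]
      if (is.na(b)) next
      out[a, b, dd] <- out[a, b, dd] + 1
      out[b, a, dd] <- out[b, a, dd] + 1
    }
  }
  out
}

# 26-connected constant-level zones by BFS flood fill
oracle_zones <- function(levels) {
  d <- dim(levels)
  seen <- array(FALSE, d)
  zones <- list()
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (s in which(!is.na(levels) & !seen)) {
    if (seen[s]) next
    lev <- levels[s]
    queue <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      pos <- arrayInd(cur, d)
      for (q in seq_len(nrow(nb))) {
        np <- pos + nb[q, ]
        if (any(np < 1) || any(np > d)) next
        li <- np[1] + d[1] * (np[2] - 1) + d[1] * d[2] * (np[3] - 1)
        if (!seen[li] && !is.na(levels[li]) && levels[li] == lev) {
          seen[li] <- TRUE
          queue <- c(queue, li)
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(level = lev, size = size)
  }
  do.call(rbind, zones)
}

# run list (level, length) per direction by walking each voxel forward
oracle_runs <- function(levels) {
  d <- dim(levels)
  runs <- list()
  for (dd in 1:13) {
    v <- oracle_dirs13[dd, ]
    counted <- array(FALSE, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (counted[i, j, k] || is.na(levels[i, j, k])) next
      # only start at run heads
      pi <- i - v[1]; pj <- j - v[2]; pk <- k - v[3]
      if (pi >= 1 && pi <= d[1] && pj >= 1 && pj <= d[2] &&
          pk >= 1 && pk <= d[3] && !is.na(levels[pi, pj, pk]) &&
          levels[pi, pj, pk] == levels[i, j, k]) next
      len <- 0L
      ci <- i; cj <- j; ck <- k
      while (ci >= 1 && ci <= d[1] && cj >= 1 && cj <= d[2] &&
             ck >= 1 && ck <= d[3] && !is.na(levels[ci, cj, ck]) &&
             levels[ci, cj, ck] == levels[i, j, k]) {
        len <- len + 1L
        ci <- ci + v[1]; cj <- cj + v[2]; ck <- ck + v[3]
      }
      runs[[length(runs) + 1L]] <- c(dir = dd, level = levels[i, j, k],
                                     len = len)
    }
  }
  do.call(rbind, runs)
}

# HGLRE from the oracle run list, averaged over directions with runs
oracle_hglre <- function(levels) {
  runs <- as.data.frame(oracle_runs(levels))
  vals <- sapply(split(runs, runs$dir), function(df) {
    sum(df$level^2) / nrow(df)
  })
  mean(vals)
}

# per-voxel LBP codes by an explicit neighbor loop with its own clamped
# trilinear interpolation
oracle_lbp_codes <- function(vol, mask, pts) {
  d <- dim(vol)
  interp1 <- function(x, y, z) {
    x <- min(max(x, 1), d[1]); y <- min(max(y, 1), d[2])
    z <- min(max(z, 1), d[3])
    x0 <- min(floor(x), d[1]); x1 <- min(x0 + 1, d[1])
    y0 <- min(floor(y), d[2]); y1 <- min(y0 + 1, d[2])
    z0 <- min(floor(z), d[3]); z1 <- min(z0 + 1, d[3])
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    v00 <- vol[x0, y0, z0] * (1 - fx) + vol[x1, y0, z0] * fx
    v10 <- vol[x0, y1, z0] * (1 - fx) + vol[x1, y1, z0] * fx
    v01 <- vol[x0, y0, z1] * (1 - fx) + vol[x1, y0, z1] * fx
    v11 <- vol[x0, y1, z1] * (1 - fx) + vol[x1, y1, z1] * fx
    (v00 * (1 - fy) + v10 * fy) * (1 - fz) + (v01 * (1 - fy) + v11 * fy) * fz
  }
  idx <- which(mask > 0, arr.ind = TRUE)
  codes <- integer(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    code <- 0
    for (p in seq_len(nrow(pts))) {
      nv <- interp1(idx[r, 1] + pts[p, 1], idx[r, 2] + pts[p, 2],
                    idx[r, 3] + pts[p, 3])
      if (nv >= vol[idx[r, 1], idx[r, 2], idx[r, 3]]) {
        code <- code + 2^(p - 1)
      }
    }
    codes[r] <- code
  }
  codes
}

# AUC by all positive-negative pair enumeration (ties count 1/2)
oracle_auc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# metric suite by direct confusion-matrix counting
oracle_metrics <- function(y, p, thr = 0.5) {
  yh <- as.integer(p >= thr)
  tp <- sum(y == 1 & yh == 1); fp <- sum(y == 0 & yh == 1)
  tn <- sum(y == 0 & yh == 0); fn <- sum(y == 1 & yh == 0)
  div <- function(a, b) if (b == 0) 0 else a / b
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  c(accuracy = (tp + tn) / length(y),
    mcc_scaled = (mcc + 1) / 2,
    f1_class1 = div(2 * tp, 2 * tp + fp + fn),
    f1_class0 = div(2 * tn, 2 * tn + fn + fp),
    precision = div(tp, tp + fp),
    recall = div(tp, tp + fn),
    specificity = div(tn, tn + fp))
}

# random small phantom for texture-oracle comparisons
random_grid <- function(seed, max_dim = 6L, ng = 4L) {
  set.seed(seed)
  d <- sample(2:max_dim, 3, replace = TRUE)
  vol <- array(sample.int(ng, prod(d), replace = TRUE), d)
  mask <- array(rbinom(prod(d), 1, 0.8), d)
  if (sum(mask) < 2) mask[1:2] <- 1
  levels <- array(NA_integer_, d)
  levels[mask > 0] <- vol[mask > 0]
  list(vol = vol, mask = mask, levels = levels, ng = ng, d = d)
}
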