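# planted-signal design shared across the RENT tests
planted_xy <- function(n, p = 8, beta = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, c("planted", paste0("noise", 1:(p - 1)))))
  y <- rbinom(n, 1, plogis(beta * X[, 1]))
  list(X = X, y = y)
}

test_that("RENT criteria follow their definitions on the weight matrix", {
  W <- cbind(allpos = c(0.5, 1, 0.2, 0.8),
             mixed = c(0.5, -0.5, 0.1, 0),
             zero = c(0, 0, 0, 0))
  cr <- rent_criteria(W)
  expect_equal(cr$c1, c(1, 0.75, 0))
  expect_equal(cr$c2, c(1, 0.25, 0))
  expect_equal(cr$c3_p[3], 1)
  # independent recomputation of the t statistic
  expect_equal(cr$c3_t[1], sqrt(4) * abs(mean(W[, 1])) / sd(W[, 1]))
})

test_that("fit_rent selects a planted feature and not strong-penalty noise", {
  d <- planted_xy(300, beta = 2, seed = 11)
  res <- fit_rent(d$X, d$y, rent_config(n_models = 50), seed = 4)
  expect_true("planted" %in% res$selected)
  expect_equal(dim(res$weights), c(50L, 8L))
  cr <- res$criteria
  expect_true(all(cr$c1 >= 0 & cr$c1 <= 1))
  expect_true(all(cr$c2 >= 0 & cr$c2 <= 1))
  # criteria recomputed from the stored weights agree
  expect_equal(rent_criteria(res$weights), cr)

  # pure-noise features under strong regularization: rarely selected
  set.seed(12)
  hits <- 0L
  for (s in 1:20) {
    dn <- planted_xy(120, p = 6, beta = 0, seed = 100 + s)
    rn <- fit_rent(dn$X, dn$y,
                   rent_config(n_models = 20, reg_strength = 0.3), seed = s)
    hits <- hits + length(rn$selected)
  }
  expect_lt(hits / 20, 0.2 * 6)

  # error paths
  expect_error(fit_rent(d$X, rep(1, 300), rent_config()), "both classes")
})

test_that("constant features are never selected", {
  d <- planted_xy(150, seed = 5)
  X <- cbind(d$X, constant = rep(0, 150))
  res <- fit_rent(X, d$y, rent_config(n_models = 20), seed = 6)
  expect_false("constant" %in% res$selected)
  expect_true(all(res$weights[, "constant"] == 0))
})

test_that("selection frequency is monotone in the planted coefficient", {
  ladder <- c(0, 0.8, 2.5)
  mean_c1 <- vapply(ladder, function(b) {
    c1s <- vapply(1:8, function(s) {
      d <- planted_xy(200, p = 5, beta = b, seed = 300 + s)
      res <- fit_rent(d$X, d$y, rent_config(n_models = 20), seed = s)
      res$criteria$c1[res$criteria$feature == "planted"]
    }, numeric(1))
    mean(c1s)
  }, numeric(1))
  expect_true(all(diff(mean_c1) >= -0.02))
  expect_gt(mean_c1[3], mean_c1[1])
})

test_that("permuting labels destroys selection", {
  d <- planted_xy(250, beta = 2.5, seed = 21)
  res <- fit_rent(d$X, d$y, rent_config(n_models = 30), seed = 1)
  set.seed(2)
  yperm <- sample(d$y)
  resp <- fit_rent(d$X, yperm, rent_config(n_models = 30), seed = 1)
  c1_planted <- res$criteria$c1[1]
  expect_gt(c1_planted, max(resp$criteria$c1))
})

test_that("brute-force RENT produces 100 runs and ranks the planted feature", {
  d <- planted_xy(120, p = 5, beta = 2, seed = 31)
  grid <- data.frame(l1_ratio = c(0.5, 1), reg_strength = c(0.1, 0.1))
  bf <- brute_force_rent(d$X, d$y, grid, n_splits = 5, n_repeats = 20,
                         config = rent_config(n_models = 8), seed = 7)
  expect_equal(bf$n_runs, 100L)
  expect_true(all(bf$frequency >= 0 & bf$frequency <= 100))
  expect_gt(bf$best_frequency["planted"],
            max(bf$best_frequency[-1]))
  expect_equal(length(bf$scores), 2L)
  expect_error(brute_force_rent(d$X, d$y, grid[0, ], 5, 20), "empty")
  expect_error(brute_force_rent(d$X, d$y, grid, n_splits = 1), "n_splits")
})

test_that("frequency_subset applies cutoffs, including the D1 table", {
  fr <- c(A = 98, B = 0, C = 1)
  expect_setequal(frequency_subset(fr, 1), c("A", "C"))
  d1_dfs <- c("HPV-related" = 98, "TNM8 stage" = 89,
              "Smoking (pack year)" = 41, "Tumor site-oral cavity" = 39,
              "Tumor site-oropharynx" = 37)
  expect_setequal(frequency_subset(d1_dfs, 50),
                  c("HPV-related", "TNM8 stage"))
  expect_equal(frequency_subset(c(A = 100, B = 99.9), 100), "A")
  expect_warning(out <- frequency_subset(c(A = 10), 50), "no feature")
  expect_length(out, 0)
  expect_error(frequency_subset(fr, 0), "cutoff")
})
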