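# Model-fitting tests use small covariate sets so each fit runs in well under
# a second; the full synthetic world is exercised in the model-recovery and
# acceptance tests.

fast_cfg <- function(seed = 1L, n_background = 500) {
  maxent_config(n_background = n_background, seed = seed)
}

test_that("background sampling is seeded, distinct, and falls back to all valid cells", {
  w <- fixture_world(21)
  stack <- fixture_stack(w)
  bg1 <- sample_background(stack, fast_cfg(seed = 5))
  bg2 <- sample_background(stack, fast_cfg(seed = 5))
  expect_identical(bg1, bg2)
  expect_equal(nrow(bg1), 500)
  expect_equal(nrow(dplyr::distinct(bg1, row, col)), 500)
  expect_warning(all_bg <- sample_background(stack, maxent_config(n_background = 1e6)),
                 "using all")
  expect_equal(nrow(all_bg), sum(stack_valid_mask(stack)))
})

test_that("no-signal fits shrink towards the uniform model", {
  set.seed(11)
  bg <- matrix(runif(400), ncol = 2, dimnames = list(NULL, c("a", "b")))
  pres <- bg[sample(200, 60), ]  # presences drawn from the background itself
  fit <- maxent_fit(pres, bg)
  expect_lt(fit$training_gain, 0.15)
  # huge regularization forces all weights to zero -> exactly uniform
  fit0 <- maxent_fit(pres, bg, maxent_config(regularization_multiplier = 1e4))
  expect_true(all(fit0$weights == 0))
  expect_equal(fit0$training_gain, 0)
  expect_equal(fit0$entropy, log(nrow(bg)))
  expect_equal(predict(fit0, bg, type = "raw"), rep(1 / nrow(bg), nrow(bg)))
})

test_that("a 1-D shifted niche gets a positive linear weight, matching a brute-force grid fit", {
  set.seed(7)
  bg <- matrix(runif(300), ncol = 1, dimnames = list(NULL, "x"))
  pres <- matrix(runif(40, 0.6, 1), ncol = 1, dimnames = list(NULL, "x"))
  fit <- maxent_fit(pres, bg, feature_classes = "linear")
  lam <- fit$weights[["x"]]
  expect_gt(lam, 0)
  # brute-force oracle: maximize the same regularized objective over a grid
  # of the single linear weight
  xs <- (pmin(pmax(bg[, 1], fit$scaling$min), fit$scaling$max) - fit$scaling$min) /
    (fit$scaling$max - fit$scaling$min)
  xp <- (pmin(pmax(pres[, 1], fit$scaling$min), fit$scaling$max) - fit$scaling$min) /
    (fit$scaling$max - fit$scaling$min)
  obj <- function(l) mean(l * xp) - log(sum(exp(l * xs))) + log(length(xs)) -
    fit$beta[1] * abs(l)
  grid <- seq(-10, 10, by = 0.001)
  best <- grid[which.max(vapply(grid, obj, numeric(1)))]
  expect_equal(lam, best, tolerance = 0.05)
  expect_gte(obj(lam), obj(best) - 1e-4)
})

test_that("the fitting trace is non-decreasing and the Gibbs weights stay normalized", {
  set.seed(13)
  bg <- matrix(runif(600), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  pres <- matrix(runif(90, 0.3, 0.9), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- maxent_fit(pres, bg)
  expect_true(all(diff(fit$gain_trace) >= -1e-9))
  q <- predict(fit, bg, type = "raw")
  expect_equal(sum(q), 1, tolerance = 1e-9)
  expect_true(all(q >= 0))
})

test_that("logistic output is bounded, uniform at no signal, and monotone in a positive linear weight", {
  set.seed(17)
  bg <- matrix(runif(500), ncol = 1, dimnames = list(NULL, "x"))
  pres <- matrix(runif(30, 0.7, 1), ncol = 1, dimnames = list(NULL, "x"))
  fit <- maxent_fit(pres, bg, feature_classes = "linear")
  news <- matrix(seq(0, 1, length.out = 50), dimnames = list(NULL, "x"))
  hsi <- predict(fit, news)
  expect_true(all(hsi >= 0 & hsi <= 1))
  expect_true(all(diff(hsi) >= -1e-12))  # monotone sweep
  # uniform model: HSI = (exp(H)/N) / (1 + exp(H)/N) = 1/2 for all cells
  fit0 <- maxent_fit(pres, bg, maxent_config(regularization_multiplier = 1e4),
                     feature_classes = "linear")
  expect_equal(predict(fit0, news), rep(0.5, 50))
  # clamping: predictions beyond the training range equal the boundary value
  extreme <- matrix(c(-5, 5), dimnames = list(NULL, "x"))
  expect_equal(predict(fit, extreme),
               predict(fit, matrix(c(fit$scaling$min, fit$scaling$max),
                                   dimnames = list(NULL, "x"))))
})

test_that("the jack-knife credits the truly driving variable and ignores pure noise", {
  set.seed(23)
  n_bg <- 800
  bg <- cbind(temp = runif(n_bg, 0, 20), noise = runif(n_bg))
  keep <- exp(-(bg[, "temp"] - 8)^2 / 8)
  pres_idx <- sample(n_bg, 120, prob = keep)
  pres <- bg[pres_idx, ]
  test_idx <- sample(setdiff(seq_len(n_bg), pres_idx), 40, prob = keep[-pres_idx])
  jk <- maxent_jackknife(pres, bg, bg[test_idx, ], fast_cfg())
  expect_equal(jk$variable, c("temp", "noise"))
  expect_gt(jk$gain_only[1], jk$gain_only[2])
  expect_lt(jk$gain_only[2], 0.1)       # noise-only model has ~no gain
  expect_gt(jk$test_auc_only[1], 0.7)   # temperature alone discriminates
  expect_true(all(is.finite(attr(jk, "full_gain"))))
})

test_that("binary maps threshold at >= and preserve nodata", {
  hsi <- coral_grid(matrix(c(0.1, 0.5, 0.9, NA), 2, 2), 0, 1, 0.5)
  bm <- binary_map(hsi, 0.5)
  expect_equal(bm$values, matrix(c(0, 1, 1, NA), 2, 2))
  expect_true(all(binary_map(hsi, 0)$values[!is.na(hsi$values)] == 1))
  expect_true(all(binary_map(hsi, 1 + 1e-9)$values[!is.na(hsi$values)] == 0))
  # count oracle
  thr <- 0.4
  expect_equal(sum(binary_map(hsi, thr)$values, na.rm = TRUE),
               sum(hsi$values >= thr, na.rm = TRUE))
})

test_that("tidy and glance expose features and fit summary", {
  set.seed(3)
  bg <- matrix(runif(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
  pres <- bg[1:20, ]
  fit <- maxent_fit(pres, bg)
  td <- tidy(fit)
  expect_true(all(c("kind", "label", "variable", "weight", "beta") %in% names(td)))
  expect_equal(nrow(td), length(fit$weights))
  gl <- glance(fit)
  expect_equal(gl$n_presence, 20)
  expect_equal(gl$n_active, sum(fit$weights != 0))
})

test_that("permuting presence labels against covariates drives test AUC to chance", {
  set.seed(31)
  n_bg <- 600
  bg <- cbind(temp = runif(n_bg, 0, 20), sal = runif(n_bg, 34, 36))
  keep <- exp(-(bg[, "temp"] - 8)^2 / 8)
  pres <- bg[sample(n_bg, 80, prob = keep), ]
  fit <- maxent_fit(pres, bg)
  scores_p <- predict(fit, pres)
  scores_b <- predict(fit, bg)
  expect_gt(auc_presence_background(scores_p, scores_b), 0.7)  # real labels discriminate
  pool <- c(scores_p, scores_b)
  null_aucs <- vapply(1:30, function(i) {
    perm <- withr::with_seed(i, sample(length(pool)))
    auc_presence_background(pool[perm[seq_along(scores_p)]],
                            pool[perm[-seq_along(scores_p)]])
  }, numeric(1))
  # single-permutation AUC sd here is ~0.034 (m = 80, n = 680), so the
  # 30-permutation mean should sit within a few thousandths' standard error
  expect_lt(abs(mean(null_aucs) - 0.5), 0.03)
  expect_true(all(null_aucs > 0.35 & null_aucs < 0.65))
})
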