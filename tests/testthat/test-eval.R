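test_that("partitioning is a seeded exact split with the documented sizes", {
  set.seed(1)
  recs <- tibble::tibble(species = "A", lon = runif(10), lat = runif(10),
                         x = rnorm(10))
  p <- partition_presences(recs, 0.7, seed = 9)
  expect_equal(nrow(p$train), 7)
  expect_equal(nrow(p$test), 3)
  # true partition: disjoint and exhaustive
  both <- dplyr::bind_rows(p$train, p$test)
  expect_equal(dplyr::arrange(both, x), dplyr::arrange(recs, x))
  expect_equal(nrow(dplyr::inner_join(p$train, p$test, by = "x")), 0)
  # reproducible per seed
  p2 <- partition_presences(recs, 0.7, seed = 9)
  expect_identical(p$train, p2$train)
  # property over n and seeds
  for (n in c(4, 7, 13, 40)) {
    for (sd in 1:3) {
      r <- tibble::tibble(id = seq_len(n))
      pp <- partition_presences(r, 0.7, seed = sd)
      expect_equal(nrow(pp$train), round(0.7 * n))
      expect_setequal(c(pp$train$id, pp$test$id), r$id)
    }
  }
  expect_error(partition_presences(recs, 0), "between 0 and 1")
  expect_error(partition_presences(recs, 1), "between 0 and 1")
  expect_error(partition_presences(recs[1:3, ], 0.7), "at least 4")
})

test_that("presence-background AUC matches hand enumeration and its stated extremes", {
  # all pairs enumerated by hand: presences {0.9, 0.4}, background {0.5, 0.3, 0.1}
  expect_equal(auc_presence_background(c(0.9, 0.4), c(0.5, 0.3, 0.1)), 5 / 6)
  # perfectly separated scores attain the maximum of 1
  expect_equal(auc_presence_background(rep(1, 5), rep(0, 7)), 1)
  # identical distributions hover at 0.5
  set.seed(2)
  aucs <- replicate(50, auc_presence_background(runif(100), runif(100)))
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
  expect_error(auc_presence_background(numeric(0), 1), "nonempty")
})

test_that("AUC equals the brute-force all-pairs oracle and is rank-invariant", {
  for (seed in 1:50) {
    set.seed(seed)
    m <- sample(3:40, 1); n <- sample(3:60, 1)
    p <- round(runif(m), 2)  # rounding forces ties
    b <- round(runif(n), 2)
    expect_equal(auc_presence_background(p, b), auc_oracle(p, b))
  }
  # invariance under strictly monotone transforms
  set.seed(99)
  p <- rnorm(25); b <- rnorm(35)
  a0 <- auc_presence_background(p, b)
  expect_equal(auc_presence_background(exp(p), exp(b)), a0)
  expect_equal(auc_presence_background(qlogis(plogis(p)), qlogis(plogis(b))), a0)
})

test_that("test gain matches direct formula evaluation and is zero for the uniform model", {
  set.seed(5)
  bg <- matrix(runif(200, 0, 10), ncol = 1, dimnames = list(NULL, "x"))
  pres <- matrix(runif(30, 6, 10), ncol = 1, dimnames = list(NULL, "x"))
  fit <- maxent_fit(pres, bg, feature_classes = "linear")
  tst <- matrix(c(7, 8.5, 9.9), dimnames = list(NULL, "x"))
  # direct arithmetic from the model's own definition
  eta <- predict(fit, tst, type = "link")
  eta_bg <- predict(fit, bg, type = "link")
  oracle <- mean(eta - log(sum(exp(eta_bg))) + log(nrow(bg)))
  expect_equal(test_gain(fit, tst), oracle)
  # uniform model: every test point exactly as likely as a background pixel
  fit0 <- maxent_fit(pres, bg, maxent_config(regularization_multiplier = 1e6),
                     feature_classes = "linear")
  expect_equal(test_gain(fit0, tst), 0)
  expect_equal(gain_likelihood_ratio(test_gain(fit0, tst)), 1)
})

test_that("percentile thresholds interpolate order statistics", {
  expect_equal(percentile_threshold(1:10, 10), 1.9)
  expect_equal(percentile_threshold(c(1, 3), 50), 2)
  expect_equal(percentile_threshold(rep(0.4, 8), 10), 0.4)
  expect_error(percentile_threshold(numeric(0)), "no training scores")
  expect_error(percentile_threshold(1:5, 0), "0, 100")
  expect_error(percentile_threshold(1:5, 100), "0, 100")
})

test_that("omission is the strictly-below fraction", {
  expect_equal(omission_rate(c(0.2, 0.6, 0.8), 0.5), 1 / 3)
  expect_equal(omission_rate(c(0.6, 0.7), 0.5), 0)
  expect_equal(omission_rate(c(0.1, 0.2), 0.9), 1)
  # a score exactly at the threshold is predicted present
  expect_equal(omission_rate(c(0.5, 0.4), 0.5), 1 / 2)
  # tie-free training scores at the 10% threshold: the interpolated
  # threshold omits at most one record beyond the nominal 10%, and exactly
  # at most 10% whenever (n - 1) / 10 is integral (as at n = 200)
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(20:200, 1)
    s <- runif(n)
    thr <- percentile_threshold(s, 10)
    expect_lte(omission_rate(s, thr), 0.10 + 1 / n)
  }
  s200 <- runif(200)
  expect_lte(omission_rate(s200, percentile_threshold(s200, 10)), 0.10)
})

test_that("AUC significance agrees with exhaustive permutation enumeration at n = 5", {
  x <- c(0.91, 0.93, 0.96, 0.98, 0.99)
  y <- c(0.48, 0.52, 0.50, 0.47, 0.55)
  p_pkg <- auc_significance(x, y)
  # oracle: exact two-sided rank-sum p by enumerating all C(10,5) labelings
  pool <- c(x, y)
  combos <- utils::combn(10, 5)
  w_obs <- sum(rank(pool)[1:5])
  w_all <- apply(combos, 2, function(ix) sum(rank(pool)[ix]))
  mu <- mean(w_all)
  p_exact <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  expect_equal(p_pkg, p_exact)
  expect_lt(p_pkg, 0.01)
  # indistinguishable groups -> large p
  expect_gt(auc_significance(y, y + 0.001), 0.3)
  expect_error(auc_significance(x[1:4], y), "at least 5")
})

test_that("the covariation screen reports Pearson correlations with 0.7 flags", {
  g <- tiny_grid(nr = 10, nc = 10, seed = 50, cell = 0.1, lon0 = 0, lat0 = 1)
  g$values[is.na(g$values)] <- 5
  neg <- coral_grid(-g$values, 0, 1, 0.1)
  noise <- coral_grid(matrix(rnorm(100), 10, 10), 0, 1, 0.1)
  flat <- coral_grid(matrix(1, 10, 10), 0, 1, 0.1)
  stack <- layer_stack(list(a = g, b = neg, c = noise, d = flat))
  sc <- covariation_screen(stack, seed = 4)
  m <- attr(sc, "matrix")
  expect_equal(m["a", "b"], -1)
  expect_true(is.na(m["a", "d"]))  # zero-variance layer: undefined correlation
  ab <- sc[sc$var1 == "a" & sc$var2 == "b", ]
  expect_true(ab$flagged)
  expect_true(all(sc$flagged[is.na(sc$r)]))  # zero-variance layer flagged
  # 5-point hand case against the textbook formula
  x <- c(1, 2, 4, 5, 9); y <- c(2, 1, 5, 4, 10)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cor(x, y), r_hand)
  s2 <- layer_stack(list(
    x = coral_grid(matrix(x, 1, 5), 0, 1, 1),
    y = coral_grid(matrix(y, 1, 5), 0, 1, 1)
  ))
  expect_equal(covariation_screen(s2)$r, r_hand)
})

test_that("niche summaries report presence-cell statistics and threshold exceedance", {
  stack <- layer_stack(list(
    temp = coral_grid(matrix(c(2, 6, 10, NA), 2, 2), 0, 2, 1),
    omega = coral_grid(matrix(c(0.8, 1.2, 1.5, NA), 2, 2), 0, 2, 1)
  ))
  recs <- tibble::tibble(species = "A",
                         lon = c(0.5, 0.5, 1.5), lat = c(1.5, 0.5, 1.5))
  set <- suppressMessages(dedup_and_filter(recs, stack))
  expect_equal(nrow(set), 3)
  ns <- niche_summary(set, stack,
                      thresholds = tibble::tibble(variable = "omega",
                                                  operator = ">", value = 1))
  tmp <- ns[ns$variable == "temp", ]
  expect_equal(tmp$mean, mean(c(2, 6, 10)))
  expect_equal(tmp$sd, sd(c(2, 6, 10)))
  expect_equal(c(tmp$min, tmp$max), c(2, 10))
  exc <- attr(ns, "exceedance")
  expect_equal(exc$percent, 100 * 2 / 3)  # omega > 1 in 2 of 3 presence cells

  # single presence: mean is the cell value, sd 0
  one <- suppressMessages(dedup_and_filter(recs[1, ], stack))
  ns1 <- niche_summary(one, stack)
  expect_equal(ns1$sd, c(0, 0))
  expect_equal(ns1$mean[ns1$variable == "temp"], 2)
})

test_that("presence-background AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(123)
  p <- rnorm(40, 1); b <- rnorm(60)
  a_ref <- as.numeric(pROC::auc(
    pROC::roc(c(rep(1, 40), rep(0, 60)), c(p, b), quiet = TRUE,
              direction = "<")))
  expect_equal(auc_presence_background(p, b), a_ref)
})
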