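#' Random train/test partition of a presence set
#'
#' Splits presence records uniformly at random into training and test
#' subsets (default 70/30); the training size is `round(fraction_train * n)`.
#'
#' @param set a `presence_set` (or any data frame of records).
#' @param fraction_train fraction in (0, 1).
#' @param seed integer seed; the same seed reproduces the split.
#' @return list of class `presence_partition` with tibbles `train`, `test`
#'   and the settings.
#' @export
partition_presences <- function(set, fraction_train = 0.7, seed = 1L) {
  n <- nrow(set)
  if (n < 4) stop("need at least 4 presence records to partition")
  if (fraction_train <= 0 || fraction_train >= 1) {
    stop("fraction_train must be strictly between 0 and 1")
  }
  n_train <- round(fraction_train * n)
  idx <- withr::with_seed(as.integer(seed), sample.int(n, n_train))
  structure(
    list(
      train = tibble::as_tibble(set)[sort(idx), ],
      test = tibble::as_tibble(set)[setdiff(seq_len(n), idx), ],
      fraction_train = fraction_train,
      seed = as.integer(seed)
    ),
    class = "presence_partition"
  )
}

#' Presence-background AUC
#'
#' The rank (Mann-Whitney) formulation of the area under the ROC curve for
#' presence-only evaluation: the probability that a presence site is ranked
#' above a random background site, with ties counted one half. 0.5 means
#' discrimination no better than random; 1 is the maximum.
#'
#' @param presence_scores,background_scores numeric score vectors (any
#'   monotone transform of suitability gives the same AUC).
#' @return AUC in \[0, 1\].
#' @export
auc_presence_background <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  if (m == 0 || n == 0) stop("both score vectors must be nonempty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Test gain of a fitted model
#'
#' The average log-likelihood of held-out presences relative to a uniform
#' distribution over the background: `mean(log(q(x) N))` with `q` the raw
#' Gibbs density and `N` the background size. A gain of `g` means a test
#' presence is on average `exp(g)` times as likely as a random background
#' cell (`exp(2)` is about 7.4); the uniform model has gain 0.
#'
#' @param model a `maxent_model`.
#' @param test_presences raw covariates of held-out presences.
#' @return test gain (natural log scale).
#' @export
test_gain <- function(model, test_presences) {
  stopifnot(inherits(model, "maxent_model"))
  eta <- maxent_link(model, test_presences)
  log_rel <- eta - model$log_partition + log(model$n_background)
  if (any(log_rel < -700)) {
    warning("near-zero density at some test presences; clamping")
    log_rel <- pmax(log_rel, -700)
  }
  mean(log_rel)
}

#' Interpret a gain as a likelihood ratio
#'
#' @param gain a (test or training) gain on the natural log scale.
#' @return `exp(gain)`: the mean likelihood of a presence relative to a
#'   random background cell.
#' @export
gain_likelihood_ratio <- function(gain) exp(gain)

#' Fixed-percentile threshold of training-presence scores
#'
#' The score at the given percentile of the training-presence suitability
#' values, with linear interpolation between order statistics. The default
#' 10th percentile yields the customary cut-off under which the lowest-
#' scoring 10% of training presences fall.
#'
#' @param training_scores numeric scores of training presences.
#' @param percentile percentile in (0, 100).
#' @return the threshold score.
#' @export
percentile_threshold <- function(training_scores, percentile = 10) {
  if (length(training_scores) == 0) stop("no training scores")
  if (percentile <= 0 || percentile >= 100) stop("percentile must be in (0, 100)")
  unname(stats::quantile(training_scores, probs = percentile / 100, type = 7))
}

#' Omission rate at a threshold
#'
#' Fraction of scores strictly below the threshold; a presence exactly at the
#' threshold counts as predicted present, matching the `>=` rule of
#' [binary_map()].
#'
#' @param test_scores numeric scores (usually test presences).
#' @param threshold suitability cut-off.
#' @return omission rate in \[0, 1\].
#' @export
omission_rate <- function(test_scores, threshold) {
  if (length(test_scores) == 0) stop("no test scores")
  mean(test_scores < threshold)
}

#' Significance of test AUC against a random-prediction null
#'
#' Two-sided Wilcoxon rank-sum test comparing replicate test AUCs with
#' matched null AUCs (models whose presence/background labels were permuted),
#' testing whether discrimination differs from the AUC = 0.5 behaviour of a
#' random prediction.
#'
#' @param test_auc_replicates AUCs from repeated seeded partitions (>= 5).
#' @param null_auc_replicates matched label-permuted AUCs (>= 5).
#' @return the p-value.
#' @export
auc_significance <- function(test_auc_replicates, null_auc_replicates) {
  if (length(test_auc_replicates) < 5 || length(null_auc_replicates) < 5) {
    stop("need at least 5 replicates in each group")
  }
  stats::wilcox.test(test_auc_replicates, null_auc_replicates)$p.value
}

#' Pairwise covariation screen of a layer stack
#'
#' Pearson correlations between layers over a seeded random sample of
#' jointly valid cells. Pairs exceeding the flag threshold (default |r| >
#' 0.7) are flagged but never dropped automatically: the choice of which
#' correlated variable to retain is left to the analyst.
#'
#' @param stack a `layer_stack` with >= 2 layers.
#' @param n_points number of random cells (all valid cells if fewer).
#' @param seed integer seed.
#' @param flag_threshold absolute correlation above which a pair is flagged.
#' @return tibble of pairs (`var1`, `var2`, `r`, `flagged`); the full
#'   correlation matrix is attached as attribute `matrix`. Zero-variance
#'   layers yield `NA` correlations, flagged.
#' @export
covariation_screen <- function(stack, n_points = 10000, seed = 1L,
                               flag_threshold = 0.7) {
  stopifnot(inherits(stack, "layer_stack"))
  if (length(stack$layers) < 2) stop("need at least 2 layers")
  cells <- as_tibble.layer_stack(stack)
  vars <- names(stack$layers)
  X <- as.matrix(cells[, vars, drop = FALSE])
  if (nrow(X) > n_points) {
    idx <- withr::with_seed(as.integer(seed), sample.int(nrow(X), n_points))
    X <- X[idx, , drop = FALSE]
  }
  cm <- suppressWarnings(stats::cor(X, method = "pearson"))
  pr <- utils::combn(length(vars), 2)
  out <- tibble::tibble(
    var1 = vars[pr[1, ]],
    var2 = vars[pr[2, ]],
    r = cm[cbind(pr[1, ], pr[2, ])]
  )
  out$flagged <- is.na(out$r) | abs(out$r) > flag_threshold
  attr(out, "matrix") <- cm
  attr(out, "n_points") <- nrow(X)
  out
}

#' Environmental niche summary of a presence set
#'
#' Per-variable mean, standard deviation, minimum and maximum of the stack
#' values at presence cells, optionally with threshold-exceedance
#' percentages (e.g. the share of records in aragonite-supersaturated water,
#' shallower than 1500 m, or with dissolved oxygen above 4 ml/l).
#'
#' @param set a `presence_set`.
#' @param stack a `layer_stack` on the set's geotransform.
#' @param thresholds optional tibble with columns `variable`, `operator`
#'   (`">"` or `"<"`) and `value`.
#' @return tibble of per-variable summaries; when `thresholds` is given the
#'   exceedance table is attached as attribute `exceedance` (columns
#'   `variable`, `rule`, `percent`).
#' @export
niche_summary <- function(set, stack, thresholds = NULL) {
  stopifnot(inherits(set, "presence_set"), nrow(set) >= 1)
  covs <- tibble::as_tibble(stack_extract(stack, set$row, set$col))
  out <- tidyr::pivot_longer(covs, cols = dplyr::everything(),
                             names_to = "variable", values_to = "value") |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (sum(!is.na(.data$value)) > 1) stats::sd(.data$value, na.rm = TRUE) else 0,
      min = min(.data$value, na.rm = TRUE),
      max = max(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$variable, names(stack$layers)))
  if (!is.null(thresholds)) {
    exc <- purrr::pmap(thresholds, function(variable, operator, value) {
      x <- covs[[variable]]
      x <- x[!is.na(x)]
      hit <- if (operator == ">") x > value else x < value
      tibble::tibble(
        variable = variable,
        rule = paste(variable, operator, value),
        percent = 100 * mean(hit)
      )
    })
    attr(out, "exceedance") <- dplyr::bind_rows(exc)
  }
  out
}

#' Full evaluation of a niche model run
#'
#' Computes the customary validation suite for one species run: test AUC
#' (with a standard deviation over repeated seeded 70/30 partitions), test
#' gain, the fixed-percentile training threshold, omission rates of test and
#' training presences at that threshold, a Wilcoxon rank-sum p-value against
#' label-permuted null models, and the jack-knife of variable importance.
#'
#' @param swd SWD tibble of presences (covariate columns after
#'   `species`/`lon`/`lat`; see [export_swd()]).
#' @param background background covariate tibble (see [sample_background()];
#'   covariate columns only are used).
#' @param config a [maxent_config()].
#' @param fraction_train training fraction (default 0.7).
#' @param percentile threshold percentile (default 10).
#' @param n_replicates partitions used for the AUC mean/SD and the
#'   significance test (default 10).
#' @param seed integer seed driving all partitions.
#' @param feature_classes as in [maxent_fit()].
#' @return object of class `evaluation_report`.
#' @export
evaluate_model <- function(swd, background, config = maxent_config(),
                           fraction_train = 0.7, percentile = 10,
                           n_replicates = 10, seed = 1L,
                           feature_classes = "auto") {
  vars <- setdiff(names(swd), c("species", "lon", "lat", "row", "col"))
  Xall <- as.matrix(swd[, vars, drop = FALSE])
  Xb <- as.matrix(tibble::as_tibble(background)[, vars, drop = FALSE])
  seed <- as.integer(seed)

  reps <- purrr::map(seq_len(n_replicates), function(i) {
    part <- partition_presences(swd, fraction_train, seed = seed + i)
    fit <- maxent_fit(as.matrix(part$train[, vars, drop = FALSE]), Xb,
                      config, feature_classes)
    test_scores <- predict.maxent_model(
      fit, as.matrix(part$test[, vars, drop = FALSE]), type = "logistic")
    bg_scores <- predict.maxent_model(fit, Xb, type = "logistic")
    auc <- auc_presence_background(test_scores, bg_scores)
    # matched null: permute presence/background labels of the same scores
    pool <- c(test_scores, bg_scores)
    perm <- withr::with_seed(seed + 1000L + i, sample(seq_along(pool)))
    null_auc <- auc_presence_background(
      pool[perm[seq_along(test_scores)]],
      pool[perm[-seq_along(test_scores)]]
    )
    list(fit = fit, part = part, auc = auc, null_auc = null_auc,
         test_scores = test_scores)
  })
  aucs <- vapply(reps, `[[`, numeric(1), "auc")
  null_aucs <- vapply(reps, `[[`, numeric(1), "null_auc")

  # headline statistics from the first replicate's partition/model
  main <- reps[[1]]
  train_scores <- predict.maxent_model(
    main$fit, as.matrix(main$part$train[, vars, drop = FALSE]), type = "logistic")
  thr <- percentile_threshold(train_scores, percentile)
  gain <- test_gain(main$fit, as.matrix(main$part$test[, vars, drop = FALSE]))
  jk <- maxent_jackknife(
    as.matrix(main$part$train[, vars, drop = FALSE]), Xb,
    as.matrix(main$part$test[, vars, drop = FALSE]), config, feature_classes
  )
  structure(
    list(
      test_auc = mean(aucs),
      test_auc_sd = stats::sd(aucs),
      test_gain = gain,
      threshold = thr,
      percentile = percentile,
      omission_rate = omission_rate(main$test_scores, thr),
      training_omission_rate = omission_rate(train_scores, thr),
      wilcoxon_p = auc_significance(aucs, null_aucs),
      auc_replicates = aucs,
      null_auc_replicates = null_aucs,
      jackknife = jk,
      model = main$fit,
      n_train = nrow(main$part$train),
      n_test = nrow(main$part$test),
      n_replicates = n_replicates
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<evaluation_report> %d train / %d test presences, %d replicates\n",
      "  test AUC %.3f (sd %.3f), test gain %.3f\n",
      "  %g%% training threshold %.3f; omission: test %.1f%%, training %.1f%%\n",
      "  Wilcoxon vs null p = %.3g\n"
    ),
    x$n_train, x$n_test, x$n_replicates,
    x$test_auc, x$test_auc_sd, x$test_gain,
    x$percentile, x$threshold,
    100 * x$omission_rate, 100 * x$training_omission_rate, x$wilcoxon_p
  ))
  invisible(x)
}

#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) x$jackknife

#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    test_auc = x$test_auc,
    test_auc_sd = x$test_auc_sd,
    test_gain = x$test_gain,
    threshold = x$threshold,
    omission_rate = x$omission_rate,
    training_omission_rate = x$training_omission_rate,
    wilcoxon_p = x$wilcoxon_p,
    n_train = x$n_train,
    n_test = x$n_test
  )
}

#' Jack-knife importance plot
#'
#' @param object an `evaluation_report`.
#' @param ... unused.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$jackknife,
                            cols = c("gain_without", "gain_only"),
                            names_to = "measure", values_to = "gain")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gain, y = .data$variable,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Training gain", y = NULL, fill = NULL)
}
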