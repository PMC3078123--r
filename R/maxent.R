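# Presence-background maximum-entropy niche model.
#
# The model is the Gibbs distribution q_lambda(x) ∝ exp(lambda . f(x)) over
# the background cells, with features f built from the environmental
# covariates (linear, quadratic, product and hinge classes, auto-selected by
# presence count) scaled to [0, 1]. Weights maximise the L1-regularized
# average log-likelihood of the presences ("gain"): per-feature coordinate
# updates minimise the standard upper bound of the change in the regularized
# log loss, which is valid for features in [0, 1] and guarantees the gain
# never decreases across updates.

#' Maximum-entropy model configuration
#'
#' Defaults follow the configuration commonly used for presence-only coral
#' habitat modelling: convergence threshold 1e-5 on the per-iteration gain
#' change, at most 500 iterations, regularization multiplier 1 and 10,000
#' background cells.
#'
#' @param convergence_threshold stop when the gain improves by less than this
#'   over one full pass.
#' @param max_iterations maximum number of full coordinate passes.
#' @param regularization_multiplier scales every per-feature L1 penalty.
#' @param n_background background sample size.
#' @param seed integer seed for background sampling.
#' @return list of class `maxent_config`.
#' @export
maxent_config <- function(convergence_threshold = 1e-5, max_iterations = 500,
                          regularization_multiplier = 1, n_background = 10000,
                          seed = 1L) {
  stopifnot(convergence_threshold > 0, max_iterations > 0,
            regularization_multiplier > 0, n_background > 0)
  structure(
    list(
      convergence_threshold = convergence_threshold,
      max_iterations = as.integer(max_iterations),
      regularization_multiplier = regularization_multiplier,
      n_background = as.integer(n_background),
      seed = as.integer(seed)
    ),
    class = "maxent_config"
  )
}

#' Sample background cells from a layer stack
#'
#' Draws `n_background` cells uniformly without replacement from the jointly
#' valid cells, seeded. If fewer valid cells exist, all of them are used with
#' a warning.
#'
#' @param stack a `layer_stack`.
#' @param config a [maxent_config()].
#' @return tibble of background cells: `row`, `col`, `lon`, `lat` and one
#'   column per layer.
#' @export
sample_background <- function(stack, config = maxent_config()) {
  cells <- as_tibble.layer_stack(stack)
  if (nrow(cells) == 0) stop("stack has no jointly valid cells")
  n <- config$n_background
  if (nrow(cells) <= n) {
    if (nrow(cells) < n) {
      warning(sprintf("only %d valid cells (< n_background = %d); using all",
                      nrow(cells), n))
    }
    return(cells)
  }
  idx <- withr::with_seed(config$seed, sample.int(nrow(cells), n))
  cells[idx, ]
}

# ---- feature machinery ------------------------------------------------------

# Feature classes by presence count, mirroring the auto-feature convention:
# linear only below 10 presences, plus quadratic from 10, hinge from 15 and
# product from 80.
auto_feature_classes <- function(m) {
  cls <- "linear"
  if (m >= 10) cls <- c(cls, "quadratic")
  if (m >= 15) cls <- c(cls, "hinge")
  if (m >= 80) cls <- c(cls, "product")
  cls
}

N_HINGE_KNOTS <- 25L  # per direction, i.e. 50 hinge features per variable

# Build the feature table for the given classes over p variables.
build_features <- function(var_names, classes) {
  p <- length(var_names)
  feats <- list(tibble::tibble(
    kind = "linear", var1 = seq_len(p), var2 = NA_integer_,
    knot = NA_real_, direction = NA_character_
  ))
  if ("quadratic" %in% classes) {
    feats <- c(feats, list(tibble::tibble(
      kind = "quadratic", var1 = seq_len(p), var2 = NA_integer_,
      knot = NA_real_, direction = NA_character_
    )))
  }
  if ("product" %in% classes && p >= 2) {
    pr <- utils::combn(p, 2)
    feats <- c(feats, list(tibble::tibble(
      kind = "product", var1 = pr[1, ], var2 = pr[2, ],
      knot = NA_real_, direction = NA_character_
    )))
  }
  if ("hinge" %in% classes) {
    knots <- seq_len(N_HINGE_KNOTS) / (N_HINGE_KNOTS + 1)
    feats <- c(feats, list(
      tidyr::expand_grid(kind = "hinge", var1 = seq_len(p), var2 = NA_integer_,
                         knot = knots, direction = "forward"),
      tidyr::expand_grid(kind = "hinge", var1 = seq_len(p), var2 = NA_integer_,
                         knot = knots, direction = "reverse")
    ))
  }
  out <- dplyr::bind_rows(feats)
  out$label <- with(out, dplyr::case_when(
    kind == "linear" ~ var_names[var1],
    kind == "quadratic" ~ paste0(var_names[var1], "^2"),
    kind == "product" ~ paste0(var_names[var1], "*", var_names[var2]),
    TRUE ~ sprintf("%s(%s@%.3f)", ifelse(direction == "forward", "hinge", "revhinge"),
                   var_names[var1], knot)
  ))
  out
}

# Clamp raw covariates to the training range and scale to [0, 1].
scale_covariates <- function(X, scaling) {
  X <- as.matrix(X)
  for (j in seq_len(ncol(X))) {
    lo <- scaling$min[j]; hi <- scaling$max[j]
    x <- pmin(pmax(X[, j], lo), hi)
    X[, j] <- if (hi > lo) (x - lo) / (hi - lo) else 0
  }
  X
}

# Evaluate all features on a scaled covariate matrix; every column in [0, 1].
evaluate_features <- function(features, Xs) {
  n <- nrow(Xs)
  F <- matrix(0, n, nrow(features))
  for (k in seq_len(nrow(features))) {
    kind <- features$kind[k]
    x1 <- Xs[, features$var1[k]]
    F[, k] <- switch(
      kind,
      linear = x1,
      quadratic = x1^2,
      product = x1 * Xs[, features$var2[k]],
      hinge = {
        kt <- features$knot[k]
        if (features$direction[k] == "forward") {
          pmax(0, x1 - kt) / (1 - kt)
        } else {
          pmax(0, kt - x1) / kt
        }
      }
    )
  }
  colnames(F) <- features$label
  F
}

# Default per-class regularization betas interpolated in presence count m
# (published Maxent default tables).
beta_class_value <- function(kind, m) {
  interp <- function(xs, ys) {
    if (m <= xs[1]) return(ys[1])
    if (m >= xs[length(xs)]) return(ys[length(ys)])
    stats::approx(xs, ys, xout = m)$y
  }
  switch(kind,
    linear = interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
    quadratic = interp(c(0, 10, 17, 30, 100), c(1.3, 0.8, 0.5, 0.25, 0.05)),
    product = interp(c(0, 10, 17, 30, 100), c(2.6, 1.6, 0.9, 0.55, 0.05)),
    hinge = 0.5,
    stop("unknown feature class: ", kind)
  )
}

# Per-feature L1 penalty: beta_class(m) * sd(feature | presences) / sqrt(m),
# sd floored at 0.05 so no feature is ever unpenalized.
feature_betas <- function(features, Fp, reg_mult) {
  m <- nrow(Fp)
  sds <- pmax(apply(Fp, 2, stats::sd), 0.05)
  cls <- vapply(features$kind, beta_class_value, numeric(1), m = m)
  reg_mult * cls * sds / sqrt(m)
}

# ---- fitting ----------------------------------------------------------------

#' Fit a maximum-entropy niche model
#'
#' @param presences matrix/data frame of covariates at presence cells (one
#'   column per variable).
#' @param background matrix/data frame of covariates at background cells with
#'   the same columns.
#' @param config a [maxent_config()].
#' @param feature_classes `"auto"` (selected by presence count) or a character
#'   vector among `"linear"`, `"quadratic"`, `"product"`, `"hinge"`.
#' @return an object of class `maxent_model` with feature definitions,
#'   weights, the background log-partition, the entropy of the fitted
#'   background distribution, the training gain and the per-iteration gain
#'   trace.
#' @export
maxent_fit <- function(presences, background, config = maxent_config(),
                       feature_classes = "auto") {
  Xp <- as.matrix(presences)
  Xb <- as.matrix(background)
  if (nrow(Xp) < 2) stop("need at least 2 presences")
  if (nrow(Xb) < 1) stop("background is empty")
  if (!all(is.finite(Xp)) || !all(is.finite(Xb))) stop("non-finite covariates")
  if (is.null(colnames(Xp))) colnames(Xp) <- paste0("v", seq_len(ncol(Xp)))
  if (is.null(colnames(Xb))) colnames(Xb) <- colnames(Xp)
  stopifnot(identical(colnames(Xp), colnames(Xb)))
  var_names <- colnames(Xp)
  m <- nrow(Xp); N <- nrow(Xb)

  pool <- rbind(Xp, Xb)
  scaling <- list(min = apply(pool, 2, min), max = apply(pool, 2, max))
  if (identical(feature_classes, "auto")) feature_classes <- auto_feature_classes(m)
  features <- build_features(var_names, feature_classes)
  Fp <- evaluate_features(features, scale_covariates(Xp, scaling))
  Fb <- evaluate_features(features, scale_covariates(Xb, scaling))
  beta <- feature_betas(features, Fp, config$regularization_multiplier)
  p_emp <- colMeans(Fp)

  nf <- ncol(Fb)
  lambda <- numeric(nf)
  eta_b <- numeric(N)
  eta_p <- numeric(m)
  w <- rep(1, N)  # unnormalized exp(eta_b - eta_max)
  eta_max <- 0
  gain_of <- function() {
    mean(eta_p) - (log(sum(w)) + eta_max) + log(N) - sum(beta * abs(lambda))
  }
  gain_trace <- numeric(0)
  prev_gain <- 0
  converged <- FALSE
  iter <- 0
  DELTA_CAP <- 30

  while (iter < config$max_iterations) {
    iter <- iter + 1
    Z <- sum(w)
    for (k in seq_len(nf)) {
      E <- sum(w * Fb[, k]) / Z
      E <- min(max(E, 1e-12), 1 - 1e-12)
      p <- p_emp[k]
      b <- beta[k]
      l0 <- lambda[k]
      # candidate minimizers of the per-feature upper bound
      # F(d) = -d p + log(1 + (e^d - 1) E) + b(|l0 + d| - |l0|)
      cand <- -l0
      if (p - b > 0) {
        d1 <- log((p - b) * (1 - E) / ((1 - p + b) * E))
        if (l0 + d1 >= 0) cand <- c(cand, d1)
      }
      if (p + b < 1) {
        d2 <- log((p + b) * (1 - E) / ((1 - p - b) * E))
        if (l0 + d2 <= 0) cand <- c(cand, d2)
      }
      cand <- pmin(pmax(cand, -DELTA_CAP), DELTA_CAP)
      Fbound <- -cand * p + log1p((exp(cand) - 1) * E) +
        b * (abs(l0 + cand) - abs(l0))
      d <- cand[which.min(Fbound)]
      if (min(Fbound) >= -1e-14 || abs(d) < 1e-14) next
      lambda[k] <- l0 + d
      eta_p <- eta_p + d * Fp[, k]
      eta_b <- eta_b + d * Fb[, k]
      mx <- max(eta_b)
      w <- exp(eta_b - mx)
      eta_max <- mx
      Z <- sum(w)
    }
    g <- gain_of()
    gain_trace <- c(gain_trace, g)
    if (abs(g - prev_gain) < config$convergence_threshold) {
      converged <- TRUE
      break
    }
    prev_gain <- g
  }

  q <- w / sum(w)
  entropy <- -sum(ifelse(q > 0, q * log(q), 0))
  log_partition <- log(sum(w)) + eta_max  # log sum over background of exp(eta)
  structure(
    list(
      var_names = var_names,
      features = features,
      scaling = scaling,
      weights = stats::setNames(lambda, features$label),
      beta = beta,
      log_partition = log_partition,
      entropy = entropy,
      n_background = N,
      n_presence = m,
      training_gain = gain_of(),
      gain_trace = gain_trace,
      iterations = iter,
      converged = converged,
      config = config
    ),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d variables, %d features (%d active)\n  %d presences vs %d background; training gain %.4f; entropy %.4f\n  %d iterations (%s)\n",
    length(x$var_names), length(x$weights), sum(x$weights != 0),
    x$n_presence, x$n_background, x$training_gain, x$entropy,
    x$iterations, if (x$converged) "converged" else "iteration cap reached"
  ))
  invisible(x)
}

# Linear predictor eta(x) for new raw covariates (clamped to training range).
maxent_link <- function(model, newdata) {
  X <- as.matrix(newdata)[, model$var_names, drop = FALSE]
  F <- evaluate_features(model$features, scale_covariates(X, model$scaling))
  drop(F %*% model$weights)
}

#' Predict from a maximum-entropy model
#'
#' @param object a `maxent_model`.
#' @param newdata matrix/data frame of raw covariates (columns as fitted).
#' @param type `"logistic"` for the habitat suitability index in \[0, 1\],
#'   `"raw"` for the Gibbs density relative to the background sample (sums to
#'   1 over the background), `"link"` for the linear predictor.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("logistic", "raw", "link"), ...) {
  type <- match.arg(type)
  eta <- maxent_link(object, newdata)
  if (type == "link") return(eta)
  raw <- exp(pmin(eta - object$log_partition, 700))
  if (type == "raw") return(raw)
  cq <- exp(object$entropy) * raw
  cq / (1 + cq)
}

#' Predict a habitat suitability grid
#'
#' Applies the fitted model to every jointly valid cell of a layer stack,
#' yielding the logistic habitat suitability index (HSI) in \[0, 1\]:
#' `HSI = c q(x) / (1 + c q(x))` with `q` the cell's Gibbs density relative
#' to the background and `c = exp(entropy)`, so a no-signal (uniform) model
#' scores 0.5 everywhere. Covariates beyond the training range are clamped.
#'
#' @param model a `maxent_model`.
#' @param stack a `layer_stack` containing every fitted variable.
#' @return a `coral_grid` of HSI values, nodata where any layer is nodata.
#' @export
predict_logistic <- function(model, stack) {
  stopifnot(inherits(model, "maxent_model"), inherits(stack, "layer_stack"))
  miss <- setdiff(model$var_names, names(stack$layers))
  if (length(miss) > 0) stop("stack lacks fitted variables: ", paste(miss, collapse = ", "))
  cells <- as_tibble.layer_stack(stack)
  hsi <- predict.maxent_model(model, cells[, model$var_names, drop = FALSE],
                              type = "logistic")
  gt <- geotransform(stack$layers[[1]])
  out <- matrix(NA_real_, gt$n_rows, gt$n_cols)
  out[cbind(cells$row, cells$col)] <- hsi
  coral_grid(out, gt$lon_origin, gt$lat_origin, gt$cell_size,
             nodata = stack$layers[[1]]$nodata)
}

#' Jack-knife of variable importance
#'
#' For each variable, fits one model with the variable left out and one with
#' only that variable, and scores the single-variable model on held-out test
#' presences by presence-background AUC. The full model's training gain is
#' attached as an attribute.
#'
#' @param presences,background raw covariate matrices (training presences and
#'   background).
#' @param test_presences raw covariates of held-out presences used for the
#'   single-variable test AUC.
#' @param config a [maxent_config()].
#' @param feature_classes as in [maxent_fit()].
#' @return tibble with `variable`, `gain_without`, `gain_only`,
#'   `test_auc_only`; attribute `full_gain`.
#' @export
maxent_jackknife <- function(presences, background, test_presences,
                             config = maxent_config(), feature_classes = "auto") {
  Xp <- as.matrix(presences); Xb <- as.matrix(background)
  Xt <- as.matrix(test_presences)
  if (ncol(Xp) < 2) stop("jack-knife needs at least 2 variables")
  vars <- colnames(Xp)
  full <- maxent_fit(Xp, Xb, config, feature_classes)
  rows <- purrr::map(vars, function(v) {
    keep <- setdiff(vars, v)
    m_wo <- maxent_fit(Xp[, keep, drop = FALSE], Xb[, keep, drop = FALSE],
                       config, feature_classes)
    m_only <- maxent_fit(Xp[, v, drop = FALSE], Xb[, v, drop = FALSE],
                         config, feature_classes)
    auc <- auc_presence_background(
      predict.maxent_model(m_only, Xt[, v, drop = FALSE], type = "link"),
      predict.maxent_model(m_only, Xb[, v, drop = FALSE], type = "link")
    )
    tibble::tibble(variable = v, gain_without = m_wo$training_gain,
                   gain_only = m_only$training_gain, test_auc_only = auc)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "full_gain") <- full$training_gain
  out
}

#' Binarize a suitability grid at a threshold
#'
#' @param hsi a `coral_grid` of suitability values.
#' @param threshold cells with `HSI >= threshold` become 1, below it 0;
#'   nodata is preserved.
#' @return a `coral_grid` of 0/1.
#' @export
binary_map <- function(hsi, threshold) {
  stopifnot(inherits(hsi, "coral_grid"), is.numeric(threshold), length(threshold) == 1)
  v <- hsi$values
  out <- ifelse(is.na(v), NA_real_, as.numeric(v >= threshold))
  coral_grid(out, hsi$lon_origin, hsi$lat_origin, hsi$cell_size, hsi$nodata)
}

#' @method tidy maxent_model
#' @export
tidy.maxent_model <- function(x, ...) {
  dplyr::bind_cols(
    x$features[, c("kind", "label")],
    tibble::tibble(
      variable = x$var_names[x$features$var1],
      weight = unname(x$weights),
      beta = x$beta
    )
  )
}

#' @method glance maxent_model
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    n_presence = x$n_presence,
    n_background = x$n_background,
    n_features = length(x$weights),
    n_active = sum(x$weights != 0),
    training_gain = x$training_gain,
    entropy = x$entropy,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Response curves of a fitted model
#'
#' Varies one variable at a time across its training range (others held at
#' the background mean) and plots the logistic suitability.
#'
#' @param object a `maxent_model`.
#' @param background raw covariate matrix used to anchor the non-varying
#'   variables at their means.
#' @param n points per curve.
#' @param ... unused.
#' @method autoplot maxent_model
#' @export
autoplot.maxent_model <- function(object, background, n = 100, ...) {
  Xb <- as.matrix(background)[, object$var_names, drop = FALSE]
  mu <- colMeans(Xb)
  curves <- purrr::map(object$var_names, function(v) {
    xs <- seq(object$scaling$min[v], object$scaling$max[v], length.out = n)
    X <- matrix(rep(mu, each = n), n, dimnames = list(NULL, object$var_names))
    X[, v] <- xs
    tibble::tibble(variable = v, x = xs,
                   hsi = predict.maxent_model(object, X, type = "logistic"))
  })
  df <- dplyr::bind_rows(curves)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$hsi)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(x = "Covariate value", y = "Habitat suitability index")
}
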