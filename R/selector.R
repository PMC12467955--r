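#' Reduced-budget fit settings for featurization
#'
#' Circuit-selection features are built from *quick* fits of every candidate
#' circuit: a small differential-evolution population, a short
#' Levenberg-Marquardt polish of the single best individual, and no
#' condition-triggered restarts. Final parameter estimates always come from
#' a full [eis_fit] of the selected circuit; the quick budget only has to
#' rank circuits, not to deliver publication-grade parameters.
#'
#' @param pop_size,max_gen,lm_iter budget knobs.
#' @return list with `de` and `lm` control objects.
#' @export
quick_budget <- function(pop_size = 32, max_gen = 24, lm_iter = 12) {
  list(de = de_control(pop_size = pop_size, max_gen = max_gen,
                       patience = 8, elite_frac = 1 / pop_size),
       lm = lm_control(max_iter = lm_iter, max_restarts = 3,
                       restart_pop = 50, cond_threshold = Inf,
                       ci_type = "robust"))
}

.feature_schema <- function(catalog) {
  as.vector(t(outer(names(catalog), .metric_names, paste, sep = ".")))
}

#' Error-metric feature vector for circuit selection
#'
#' Runs a reduced-budget fit of every catalog circuit against the spectrum
#' and records the six error metrics of each fit: a 48-dimensional vector
#' with schema `<circuit>.<metric>`. Failed fits are imputed with a large
#' sentinel (1e6) so that the classifier can treat them as "this circuit
#' cannot explain the data". Deterministic under a fixed seed.
#'
#' @param spectrum an [eis_spectrum].
#' @param catalog circuit catalog.
#' @param budget a [quick_budget] list.
#' @param seed integer seed.
#' @return named numeric vector, length `6 * length(catalog)`.
#' @export
build_features <- function(spectrum, catalog = circuit_catalog(),
                           budget = quick_budget(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  feats <- numeric(0)
  ok <- FALSE
  for (cid in names(catalog)) {
    m <- tryCatch({
      f <- eis_fit(spectrum, catalog[[cid]], de = budget$de, lm = budget$lm,
                   n_starts = 1L, max_rescues = 0L)
      ok <- TRUE
      unlist(f$metrics[.metric_names])
    }, error = function(e) {
      v <- rep(1e6, 6L); v[5L] <- -1e6  # r2 sentinel: arbitrarily bad
      names(v) <- .metric_names
      v
    })
    feats <- c(feats, m)
  }
  if (!ok) stop("all candidate-circuit fits failed")
  names(feats) <- .feature_schema(catalog)
  feats
}

#' Feature table for a list of spectra
#'
#' @param spectra list of [eis_spectrum] objects.
#' @param catalog,budget as in [build_features].
#' @param seed global seed; each spectrum gets a deterministic per-task seed
#'   derived from it, so results are independent of evaluation order and
#'   parallelism degree.
#' @param workers parallel workers (forked; 1 = serial).
#' @return numeric matrix, one row per spectrum.
#' @export
feature_table <- function(spectra, catalog = circuit_catalog(),
                          budget = quick_budget(), seed = 1, workers = 1L) {
  seeds <- derive_seeds(seed, length(spectra))
  one <- function(i) build_features(spectra[[i]], catalog, budget, seeds[i])
  rows <- if (workers > 1L)
    parallel::mclapply(seq_along(spectra), one, mc.cores = workers)
  else lapply(seq_along(spectra), one)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# composite-loss features (one per circuit) under a given weight vector:
# each sample's 8 candidate panels normalize each other (min-max phi)
.composite_features <- function(features, weights, catalog_ids) {
  K <- length(catalog_ids)
  t(apply(features[, seq_len(K * 6L), drop = FALSE], 1L, function(row) {
    panels <- lapply(seq_len(K), function(k) {
      m <- as.list(row[(k - 1L) * 6L + seq_len(6L)])
      names(m) <- .metric_names
      m$basis <- "reim"
      class(m) <- "eis_metrics"
      m
    })
    vapply(panels, function(p)
      suppressWarnings(composite_loss(p, panels, weights)$L), numeric(1))
  }))
}

#' Train the boosted-tree circuit selector
#'
#' Gradient-boosted-tree classification of the best equivalent circuit from
#' the 48 quick-fit error-metric features, with the error-importance
#' feedback loop: after an initial training round the per-metric feature
#' importances (gain, summed over the 8 circuit slots of each metric and
#' normalized) are turned into a metric weight vector by the
#' delta-threshold rule, per-circuit composite-loss features are computed
#' under those weights, and the classifier is retrained on the augmented
#' feature set (one cycle by default). Booster defaults: 300 trees, depth 6,
#' learning rate 0.1, L1 = 0.1, L2 = 1.0, subsample 0.8.
#'
#' @param features numeric matrix from [feature_table].
#' @param labels circuit-id vector (one per row).
#' @param holdout_frac stratified holdout fraction for reported accuracy.
#' @param feedback apply the error-feedback cycle (default TRUE).
#' @param delta importance threshold of the downweighting rule.
#' @param nrounds,max_depth,eta,alpha,lambda,subsample booster parameters.
#' @param seed integer seed (controls the split and booster subsampling).
#' @return object of class `"eis_selector"`: the booster, feature schema,
#'   classes, per-metric `importances` (sum 1), derived `weights`
#'   ([eis_weights]), `accuracy` (holdout), `accuracy_prefeedback`,
#'   `baseline_accuracy` (argmin-MSE single-metric ranking on the same
#'   holdout), `confusion` matrix, and the holdout row indices.
#' @export
train_selector <- function(features, labels, holdout_frac = 0.2,
                           feedback = TRUE, delta = 0.1, nrounds = 300,
                           max_depth = 6, eta = 0.1, alpha = 0.1,
                           lambda = 1.0, subsample = 0.8, seed = 1) {
  stopifnot(nrow(features) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes to train")
  set.seed(seed)
  test_idx <- unlist(lapply(classes, function(cl) {
    idx <- which(labels == cl)
    sample(idx, max(1L, round(holdout_frac * length(idx))))
  }))
  # top up / trim so the holdout size is exactly round(holdout_frac * n)
  want <- round(holdout_frac * length(labels))
  if (length(test_idx) > want) {
    test_idx <- sample(test_idx, want)
  } else if (length(test_idx) < want) {
    pool <- setdiff(seq_along(labels), test_idx)
    test_idx <- c(test_idx, sample(pool, want - length(test_idx)))
  }
  test_idx <- sort(test_idx)
  if (length(test_idx) == 0L || length(test_idx) == length(labels))
    stop("degenerate train/test split")
  y <- match(labels, classes) - 1L
  params <- list(objective = "multi:softprob", num_class = length(classes),
                 max_depth = max_depth, eta = eta, alpha = alpha,
                 lambda = lambda, subsample = subsample, nthread = 1L,
                 seed = seed)
  fit_once <- function(X) {
    dtrain <- xgboost::xgb.DMatrix(X[-test_idx, , drop = FALSE],
                                   label = y[-test_idx])
    bst <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = nrounds, verbose = 0)
    prob <- predict(bst, xgboost::xgb.DMatrix(X[test_idx, , drop = FALSE]))
    prob <- matrix(as.numeric(t(prob)), ncol = length(classes), byrow = TRUE)
    pred <- classes[max.col(prob)]
    list(bst = bst, pred = pred,
         acc = mean(pred == labels[test_idx]))
  }
  metric_importance <- function(bst, feat_names) {
    imp <- xgboost::xgb.importance(model = bst)
    gains <- stats::setNames(rep(0, length(feat_names)), feat_names)
    gains[imp$Feature] <- imp$Gain
    per_metric <- vapply(.metric_names, function(m)
      sum(gains[grepl(paste0("\\.", m, "$"), names(gains))]), numeric(1))
    if (sum(per_metric) == 0) per_metric <- rep(1, 6L)
    per_metric / sum(per_metric)
  }
  round1 <- fit_once(features)
  importances <- metric_importance(round1$bst, colnames(features))
  weights <- eis_weights(importances, delta = delta)
  acc_pre <- round1$acc
  # the feedback cycle needs the full (circuit x metric) panel to compute
  # per-circuit composite losses; partial feature tables train plain
  if (feedback && !all(paste0(classes, ".chi2") %in% colnames(features)))
    feedback <- FALSE
  if (feedback) {
    Lfeat <- .composite_features(features, weights, classes)
    colnames(Lfeat) <- paste0(classes, ".L")
    X2 <- cbind(features, Lfeat)
    round2 <- fit_once(X2)
    importances <- metric_importance(round2$bst, colnames(X2))
    weights <- eis_weights(importances, delta = delta)
    final <- round2
    feature_names <- colnames(X2)
  } else {
    final <- round1
    feature_names <- colnames(features)
  }
  # single-metric baseline: pick the circuit with the smallest quick-fit MSE
  mse_cols <- paste0(classes, ".mse")
  mse_cols <- mse_cols[mse_cols %in% colnames(features)]
  baseline_acc <- if (length(mse_cols) == length(classes)) {
    base_pred <- classes[max.col(-features[test_idx, mse_cols, drop = FALSE])]
    mean(base_pred == labels[test_idx])
  } else NA_real_
  confusion <- table(truth = factor(labels[test_idx], levels = classes),
                     predicted = factor(final$pred, levels = classes))
  structure(list(booster = final$bst, feature_names = feature_names,
                 classes = classes, importances = importances,
                 weights = weights, accuracy = final$acc,
                 accuracy_prefeedback = acc_pre,
                 baseline_accuracy = baseline_acc, confusion = confusion,
                 feedback = feedback, delta = delta, test_idx = test_idx),
            class = "eis_selector")
}

#' @export
print.eis_selector <- function(x, ...) {
  cat("Boosted-tree circuit selector (", length(x$classes), " classes)\n",
      sep = "")
  cat("  holdout accuracy: ", signif(100 * x$accuracy, 4), "%",
      if (x$feedback) paste0(" (pre-feedback ",
                             signif(100 * x$accuracy_prefeedback, 4), "%)"),
      "\n", sep = "")
  if (is.finite(x$baseline_accuracy))
    cat("  single-metric (argmin MSE) baseline: ",
        signif(100 * x$baseline_accuracy, 4), "%\n", sep = "")
  cat("  per-metric importances:\n")
  print(signif(x$importances, 4))
  invisible(x)
}

#' Derive the adaptive metric weight vector from a trained selector
#'
#' Normalized per-metric importances with entries below `delta` multiplied
#' by the downweight factor and renormalized; these weights feed
#' [composite_loss] for heuristic re-ranking, closing the error-feedback
#' loop.
#'
#' @param model an `"eis_selector"`.
#' @param delta importance threshold.
#' @return an [eis_weights] object.
#' @export
adapt_weights <- function(model, delta = 0.1) {
  stopifnot(inherits(model, "eis_selector"))
  eis_weights(model$importances, delta = delta)
}

#' Classify the best circuit for a spectrum
#'
#' Builds the quick-fit feature vector, scores it with the trained booster
#' and returns the most probable circuit with the class-probability vector.
#' When the margin between the top two classes is below `margin`, the
#' decision is handed to the composite-loss ranking under the selector's
#' adapted weights (documented tie-break).
#'
#' @param model an `"eis_selector"`.
#' @param spectrum an [eis_spectrum], or a precomputed feature vector from
#'   [build_features].
#' @param catalog,budget,seed passed to [build_features] when a spectrum is
#'   given.
#' @param margin probability-margin threshold for the composite tie-break.
#' @return list with `circuit_id`, `prob` (named probability vector),
#'   `tie_break` (logical).
#' @export
classify_spectrum <- function(model, spectrum, catalog = circuit_catalog(),
                              budget = quick_budget(), seed = NULL,
                              margin = 0.1) {
  stopifnot(inherits(model, "eis_selector"))
  feats <- if (inherits(spectrum, "eis_spectrum"))
    build_features(spectrum, catalog, budget, seed)
  else spectrum
  base_names <- .feature_schema(catalog)
  x <- feats[base_names]
  if (model$feedback) {
    Lf <- .composite_features(matrix(x, nrow = 1L), model$weights,
                              model$classes)[1L, ]
    names(Lf) <- paste0(model$classes, ".L")
    x <- c(x, Lf)
  }
  x <- x[model$feature_names]
  prob <- as.numeric(predict(model$booster,
                             xgboost::xgb.DMatrix(matrix(x, nrow = 1L,
                               dimnames = list(NULL, model$feature_names)))))
  names(prob) <- model$classes
  ord <- order(prob, decreasing = TRUE)
  tie <- (prob[ord[1L]] - prob[ord[2L]]) < margin
  pick <- model$classes[ord[1L]]
  if (tie) {
    Lf <- .composite_features(matrix(feats[base_names], nrow = 1L),
                              model$weights, model$classes)[1L, ]
    two <- model$classes[ord[1:2]]
    pick <- two[which.min(Lf[match(two, model$classes)])]
  }
  list(circuit_id = pick, prob = prob, tie_break = tie)
}

#' @export
predict.eis_selector <- function(object, newdata, ...) {
  classify_spectrum(object, newdata, ...)
}

#' Save / load a trained selector
#'
#' The booster is serialized with the native xgboost raw format inside a
#' versioned container.
#'
#' @param model an `"eis_selector"`; `path` a file path.
#' @export
save_selector <- function(model, path) {
  obj <- unclass(model)
  obj$booster <- xgboost::xgb.save.raw(model$booster)
  obj$.format_version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_selector
#' @export
load_selector <- function(path) {
  obj <- readRDS(path)
  obj$booster <- xgboost::xgb.load.raw(obj$booster)
  obj$.format_version <- NULL
  class(obj) <- "eis_selector"
  obj
}

#' Nested-model F-test between two circuit fits
#'
#' Post hoc verification that a more complex circuit improves the fit by
#' more than its extra parameters would explain by chance:
#' \deqn{F = \frac{(RSS_s - RSS_c)/(p_c - p_s)}{RSS_c/(2n - p_c)}}
#' with \eqn{2n} the comparison-vector length (real and imaginary parts of
#' \eqn{n} frequency points); the p-value is the upper tail of the
#' \eqn{F(p_c - p_s, 2n - p_c)} distribution.
#'
#' @param fit_simple,fit_complex [eis_fit] objects of circuits declared
#'   nested in the catalog.
#' @param catalog catalog carrying the nesting declarations.
#' @return list with `F`, `p_value`, `df1`, `df2`.
#' @export
nested_f_test <- function(fit_simple, fit_complex,
                          catalog = circuit_catalog()) {
  stopifnot(inherits(fit_simple, "eis_fit"), inherits(fit_complex, "eis_fit"))
  if (!circuit_is_nested(fit_simple$circuit$id, fit_complex$circuit$id,
                         catalog))
    stop("circuits ", fit_simple$circuit$id, " and ",
         fit_complex$circuit$id, " are not declared nested")
  p_s <- fit_simple$circuit$n_params
  p_c <- fit_complex$circuit$n_params
  if (p_c <= p_s) stop("complex model must have more parameters")
  n2 <- length(fit_complex$residuals)
  rss_s <- fit_simple$rss; rss_c <- fit_complex$rss
  if (rss_s < rss_c) rss_s <- rss_c  # numerical guard; F floored at 0
  F <- ((rss_s - rss_c) / (p_c - p_s)) / (rss_c / (n2 - p_c))
  list(F = F, p_value = stats::pf(F, p_c - p_s, n2 - p_c, lower.tail = FALSE),
       df1 = p_c - p_s, df2 = n2 - p_c)
}
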