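#' SVM model configuration
#'
#' Captures every knob of the classification protocol.  The preset used for
#' the published FMO model is `C = 15`, `gamma = "1/n"` (resolved to one over
#' the number of training instances at fit time), class weight `W = 1`,
#' min-max normalization and probability estimates on.
#'
#' @param C Soft-margin cost (> 0).
#' @param gamma RBF kernel width: a positive number, or the symbolic string
#'   `"1/n"` resolved against the training-set size.
#' @param weight Class weight W applied to the SOM class (> 0).
#' @param normalize Min-max scale each feature column to `[0, 1]` using
#'   training-set ranges.
#' @param probability Fit Platt probability estimates.
#' @param seed Seed used for every stochastic step (probability calibration,
#'   fold assignment).
#' @return An object of class `model_config`.
#' @export
model_config <- function(C = 15, gamma = "1/n", weight = 1,
                         normalize = TRUE, probability = TRUE, seed = 1L) {
  if (!is.numeric(C) || C <= 0) stop("C must be a positive number")
  if (is.numeric(gamma) && gamma <= 0) stop("gamma must be positive")
  if (!is.numeric(weight) || weight <= 0) stop("weight must be positive")
  structure(list(C = C, gamma = gamma, weight = weight,
                 normalize = isTRUE(normalize),
                 probability = isTRUE(probability), seed = as.integer(seed)),
            class = "model_config")
}

#' Resolve a symbolic gamma against a training-set size
#' @param gamma Numeric gamma or the string `"1/n"` / `"1/n_instances"`.
#' @param n_instances Training-set size.
#' @return Positive numeric gamma.
#' @export
resolve_gamma <- function(gamma, n_instances) {
  if (is.character(gamma)) {
    if (gamma %in% c("1/n", "1/n_instances")) {
      if (n_instances < 1L) stop("cannot resolve gamma: empty training set")
      return(1 / n_instances)
    }
    gamma <- suppressWarnings(as.numeric(gamma))
    if (is.na(gamma)) stop("gamma must be a positive number or '1/n'")
  }
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be positive")
  gamma
}

# ---- min-max normalization ---------------------------------------------

#' Min-max normalization fitted on the training partition
#'
#' Maps every feature column to `[0, 1]` by `(x - min) / (max - min)` using
#' the training-set column ranges; constant columns map to 0.  Test data may
#' fall outside `[0, 1]` -- that is expected and left untouched.
#'
#' @param x Numeric training matrix.
#' @return `normalize_fit()`: an object of class `minmax_params`.
#' @export
normalize_fit <- function(x) {
  x <- as.matrix(x)
  structure(list(min = apply(x, 2L, min), max = apply(x, 2L, max),
                 cols = colnames(x)),
            class = "minmax_params")
}

#' @rdname normalize_fit
#' @param params A `minmax_params` object.
#' @return `normalize_apply()`: the scaled matrix.
#' @export
normalize_apply <- function(params, x) {
  if (!inherits(params, "minmax_params"))
    stop("normalize_apply() called before normalize_fit()")
  x <- as.matrix(x)
  if (ncol(x) != length(params$min))
    stop("dimension error: expected ", length(params$min), " columns")
  rng <- params$max - params$min
  out <- sweep(x, 2L, params$min, "-")
  out <- sweep(out, 2L, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  out
}

# ---- training & prediction ---------------------------------------------

.labeled <- function(ds) ds[ds$label %in% c("nonsom", "som"), , drop = FALSE]

#' Train the RBF-SVM SOM classifier
#'
#' @param ds Training `som_dataset` (rows labeled `"unknown"` are dropped).
#' @param cfg A [model_config()].
#' @return An object of class `som_model` carrying the fitted SVM, the
#'   resolved gamma, the normalization parameters and the feature schema.
#' @export
train_svm <- function(ds, cfg = model_config()) {
  ds <- .labeled(ds)
  y <- droplevels(dataset_labels(ds))
  if (nlevels(y) < 2L || any(table(y) < 2L))
    stop("training error: need at least 2 instances of each class")
  x <- dataset_features(ds)
  gamma <- resolve_gamma(cfg$gamma, nrow(x))
  norm <- NULL
  if (cfg$normalize) {
    norm <- normalize_fit(x)
    x <- normalize_apply(norm, x)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  fit <- e1071::svm(x, y, kernel = "radial", cost = cfg$C, gamma = gamma,
                    class.weights = c(nonsom = 1, som = cfg$weight),
                    probability = cfg$probability, scale = FALSE)
  structure(list(fit = fit, cfg = cfg, gamma = gamma, norm = norm,
                 feature_names = colnames(dataset_features(ds)),
                 n_train = nrow(x)),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat("<som_model> RBF-SVM: C =", x$cfg$C, ", gamma =",
      format(x$gamma, digits = 6), ", W =", x$cfg$weight, ", trained on",
      x$n_train, "instances /", length(x$feature_names), "features\n")
  invisible(x)
}

#' Predict SOM probabilities for a dataset
#'
#' @param object A `som_model`.
#' @param ds A `som_dataset` with the same feature columns as the training
#'   data.
#' @param ... Unused.
#' @return Data frame with `compound_id`, `atom_index`, `label`, `pred`
#'   (predicted class), `prob_som`, `prob_nonsom` (Platt probabilities, `NA`
#'   when the model was fit without them) and `score` (a continuous score
#'   increasing with SOM likelihood, used for ROC curves).
#' @export
predict.som_model <- function(object, ds, ...) {
  x <- dataset_features(ds)
  miss <- setdiff(object$feature_names, colnames(x))
  if (length(miss))
    stop("dataset lacks feature column(s): ", paste(miss, collapse = ", "))
  x <- x[, object$feature_names, drop = FALSE]
  if (!is.null(object$norm)) x <- normalize_apply(object$norm, x)
  p <- predict(object$fit, x, decision.values = TRUE,
               probability = object$cfg$probability)
  dec <- attr(p, "decision.values")
  # orient the decision value so that larger always means "som"
  pair <- strsplit(colnames(dec)[1L], "/", fixed = TRUE)[[1]]
  dec_som <- if (pair[1L] == "som") dec[, 1L] else -dec[, 1L]
  if (object$cfg$probability) {
    pr <- attr(p, "probabilities")
    prob_som <- pr[, "som"]
    prob_nonsom <- pr[, "nonsom"]
    score <- prob_som
  } else {
    prob_som <- prob_nonsom <- rep(NA_real_, length(p))
    score <- dec_som
  }
  data.frame(compound_id = ds$compound_id, atom_index = ds$atom_index,
             label = ds$label, pred = as.character(p),
             prob_som = unname(prob_som), prob_nonsom = unname(prob_nonsom),
             score = unname(score), stringsAsFactors = FALSE)
}

# ---- confusion counts & metrics ----------------------------------------

#' Confusion counts under a declared positive class
#'
#' The published convention designates the non-SOM set as class I, i.e. the
#' positive class for sensitivity/specificity, so the default here is
#' `positive = "nonsom"`.  Swapping the positive class exchanges TP with TN
#' and FP with FN.
#'
#' @param labels Character/factor vector of true labels (`som`/`nonsom`).
#' @param predictions Vector of predicted labels.
#' @param positive Which label is the positive class.
#' @return An object of class `confusion_counts` with fields `TP`, `FN`,
#'   `TN`, `FP` and `positive_class`.
#' @export
confusion <- function(labels, predictions, positive = c("nonsom", "som")) {
  positive <- match.arg(positive)
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  ok <- c("som", "nonsom")
  if (!all(labels %in% ok) || !all(predictions %in% ok))
    stop("labels must be 'som' or 'nonsom'")
  pos <- labels == positive
  pred_pos <- predictions == positive
  structure(list(TP = sum(pos & pred_pos), FN = sum(pos & !pred_pos),
                 TN = sum(!pos & !pred_pos), FP = sum(!pos & pred_pos),
                 positive_class = positive),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> positive =", x$positive_class, ": TP", x$TP,
      "FN", x$FN, "TN", x$TN, "FP", x$FP, "\n")
  invisible(x)
}

#' Sensitivity, specificity, accuracy and Matthews correlation
#'
#' SE = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/total and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A metric whose denominator is zero is returned as `NA` (undefined).
#'
#' @param counts A [confusion()] object.
#' @return Named list with `SE`, `SP`, `ACC`, `MCC`.
#' @export
som_metrics <- function(counts) {
  tp <- counts$TP; fn <- counts$FN; tn <- counts$TN; fp <- counts$FP
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(SE = div(tp, tp + fn),
       SP = div(tn, tn + fp),
       ACC = div(tp + tn, tp + fn + tn + fp),
       MCC = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps a threshold over the unique scores (ties step simultaneously),
#' plotting the false positive rate against the true positive rate, and
#' integrates with the trapezoid rule.  A perfect ranking gives AUC 1.0; a
#' constant score gives the single diagonal segment and AUC 0.5.
#'
#' @param scores Numeric scores, larger meaning more likely `positive`.
#' @param labels True labels (`som`/`nonsom`).
#' @param positive The positive class.
#' @return List with `points` (data frame `FPR`, `TPR`, from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = c("nonsom", "som")) {
  positive <- match.arg(positive)
  labels <- as.character(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # cut only where the score actually changes, so tied scores move diagonally
  cuts <- which(diff(s) != 0)
  tp <- cumsum(p)[c(cuts, length(s))]
  fp <- cumsum(!p)[c(cuts, length(s))]
  pts <- data.frame(FPR = c(0, fp / n_neg), TPR = c(0, tp / n_pos))
  auc <- sum(diff(pts$FPR) * (utils::head(pts$TPR, -1) +
                                utils::tail(pts$TPR, -1)) / 2)
  list(points = pts, auc = auc)
}

# Build a full evaluation report from a prediction data frame.
.eval_report <- function(pred, positive = "nonsom") {
  pred <- pred[pred$label %in% c("som", "nonsom"), , drop = FALSE]
  counts <- confusion(pred$label, pred$pred, positive)
  score <- if (positive == "som") pred$score else -pred$score
  roc <- roc_auc(score, pred$label, positive)
  flipped <- confusion(pred$label, pred$pred,
                       setdiff(c("som", "nonsom"), positive))
  structure(list(counts = counts,
                 metrics = som_metrics(counts),
                 metrics_flipped = som_metrics(flipped),
                 roc_points = roc$points, auc = roc$auc,
                 predictions = pred, positive_class = positive),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat("<eval_report> positive =", x$positive_class, "on",
      nrow(x$predictions), "instances\n")
  cat(sprintf("  SE %.3f  SP %.3f  ACC %.3f  MCC %.3f  AUC %.3f\n",
              m$SE, m$SP, m$ACC, m$MCC, x$auc))
  f <- x$metrics_flipped
  cat(sprintf("  (flipped orientation: SE %.3f  SP %.3f)\n", f$SE, f$SP))
  invisible(x)
}

#' Evaluate a trained model on a dataset
#'
#' @param model A `som_model`.
#' @param ds A labeled `som_dataset`.
#' @param positive Positive-class convention (default non-SOM = class I).
#' @return An `eval_report`: confusion counts, SE/SP/ACC/MCC in both
#'   orientations, ROC points, AUC and per-instance predictions.
#' @export
evaluate <- function(model, ds, positive = c("nonsom", "som")) {
  positive <- match.arg(positive)
  .eval_report(predict(model, .labeled(ds)), positive)
}

# ---- cross-validation, jackknife, grid search --------------------------

.stratified_folds <- function(y, k, seed) {
  if (any(table(y) < k))
    stop("fold error: fold count ", k, " exceeds the size of a class")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    i <- which(y == cl)
    folds[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  folds
}

.run_folds <- function(ds, cfg, folds, positive) {
  preds <- vector("list", max(folds))
  for (f in sort(unique(folds))) {
    model <- train_svm(ds[folds != f, , drop = FALSE], cfg)
    preds[[f]] <- predict(model, ds[folds == f, , drop = FALSE])
  }
  .eval_report(do.call(rbind, preds), positive)
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class and assigned from `seed`; the pooled
#' out-of-fold predictions form one evaluation report.  Normalization and the
#' attribute ranges are re-fit inside every fold, so no information leaks
#' from the held-out instances.
#'
#' @param ds A labeled `som_dataset`.
#' @param cfg A [model_config()].
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed (defaults to `cfg$seed`).
#' @param positive Positive-class convention.
#' @return An `eval_report` of the pooled out-of-fold predictions.
#' @export
cross_validate <- function(ds, cfg = model_config(), k = 10L, seed = cfg$seed,
                           positive = c("nonsom", "som")) {
  positive <- match.arg(positive)
  ds <- .labeled(ds)
  y <- droplevels(dataset_labels(ds))
  if (k > nrow(ds)) stop("fold error: k exceeds the number of instances")
  folds <- .stratified_folds(y, k, seed)
  .run_folds(ds, cfg, folds, positive)
}

#' Jackknife (leave-one-out) cross-validation
#'
#' Deterministic: one fold per instance, no stratification, exactly n fits.
#'
#' @inheritParams cross_validate
#' @return An `eval_report` of the pooled leave-one-out predictions.
#' @export
jackknife <- function(ds, cfg = model_config(),
                      positive = c("nonsom", "som")) {
  positive <- match.arg(positive)
  ds <- .labeled(ds)
  .run_folds(ds, cfg, seq_len(nrow(ds)), positive)
}

#' Grid search over C and gamma by cross-validated AUC
#'
#' Every grid point is scored with the same seeded fold assignment; the best
#' configuration maximizes the objective, with ties broken by smaller C and
#' then smaller gamma.  The default grid is the standard log-2 lattice for
#' RBF SVMs.
#'
#' @param ds A labeled `som_dataset`.
#' @param C_grid,gamma_grid Numeric grids (gamma entries may be `"1/n"`).
#' @param folds Number of CV folds.
#' @param seed Fold seed.
#' @param objective `"auc"` (default) or `"acc"`.
#' @param cfg_base Base [model_config()] supplying weight/normalize/
#'   probability settings.
#' @return List with `best` (a `model_config`) and `table` (one row per grid
#'   point with its CV score).
#' @export
grid_search <- function(ds, C_grid = 2^seq(-5, 15, 2),
                        gamma_grid = 2^seq(-15, 3, 2), folds = 10L,
                        seed = 1L, objective = c("auc", "acc"),
                        cfg_base = model_config()) {
  objective <- match.arg(objective)
  if (!length(C_grid) || !length(gamma_grid)) stop("grids must be non-empty")
  ds <- .labeled(ds)
  y <- droplevels(dataset_labels(ds))
  fold_ids <- .stratified_folds(y, folds, seed)
  grid <- expand.grid(C = C_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  score <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- cfg_base
    cfg$C <- grid$C[i]
    cfg$gamma <- grid$gamma[i]
    r <- .run_folds(ds, cfg, fold_ids, "nonsom")
    score[i] <- if (objective == "auc") r$auc else r$metrics$ACC
  }
  grid$score <- score
  res_gamma <- vapply(grid$gamma,
                      function(g) resolve_gamma(g, nrow(ds)), 0)
  best_i <- order(-grid$score, grid$C, res_gamma)[1L]
  best <- cfg_base
  best$C <- grid$C[best_i]
  best$gamma <- grid$gamma[best_i]
  list(best = best, table = grid)
}
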