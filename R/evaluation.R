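#' Confusion-matrix metrics for a binary task
#'
#' Standard definitions with `positive_label` as the positive class:
#' sensitivity = recall = TP/(TP+FN); specificity = TN/(TN+FP);
#' precision = TP/(TP+FP); F1 = harmonic mean of precision and recall.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive_label the value counted as positive.
#' @return named list: accuracy, sensitivity, specificity, precision,
#'   recall, f1.
#' @export
confusion_metrics <- function(y_true, y_pred, positive_label) {
  check_that(length(y_true) == length(y_pred), "length mismatch")
  yt <- as.character(y_true); yp <- as.character(y_pred)
  pos <- as.character(positive_label)
  check_that(pos %in% yt, "undefined metric: positive class absent from y_true (sensitivity)")
  check_that(any(yt != pos), "undefined metric: negative class absent from y_true (specificity)")
  tp <- sum(yt == pos & yp == pos)
  fn <- sum(yt == pos & yp != pos)
  tn <- sum(yt != pos & yp != pos)
  fp <- sum(yt != pos & yp == pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  list(accuracy = (tp + tn) / length(yt),
       sensitivity = recall,
       specificity = tn / (tn + fp),
       precision = precision,
       recall = recall,
       f1 = if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values as thresholds; the ROC starts at (0,0) and
#' ends at (1,1) and the AUC is the trapezoidal area, which equals the
#' Mann-Whitney concordance probability (ties counted half).
#'
#' @param y_true labels.
#' @param scores finite numeric scores, higher = more positive.
#' @param positive_label the positive class value.
#' @return list: `roc` data frame of (fpr, tpr) points, `auc`.
#' @export
roc_auc <- function(y_true, scores, positive_label) {
  check_that(length(y_true) == length(scores), "length mismatch")
  scores[scores == -Inf] <- min(scores[is.finite(scores)], 0) - 1
  scores[scores == Inf] <- max(scores[is.finite(scores)], 0) + 1
  check_that(all(is.finite(scores)), "scores must be finite")
  pos <- as.character(y_true) == as.character(positive_label)
  check_that(any(pos) && any(!pos), "both classes must be present")
  np <- sum(pos); nn <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group by unique score (ties move together)
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Stratified fold assignment
#'
#' @param y labels.
#' @param k fold count (>= 2, at most the smallest class count).
#' @param seed RNG seed.
#' @return integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(y, k, seed = 1) {
  f <- factor(y)
  check_that(k >= 2, "k must be >= 2")
  check_that(k <= min(table(f)), "k exceeds the smallest class count")
  folds <- integer(length(f))
  with_seed(seed, {
    for (lv in levels(f)) {
      idx <- which(f == lv)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Stratified train/test split
#'
#' @param y labels.
#' @param train_frac fraction of each class assigned to training.
#' @param seed RNG seed.
#' @return logical vector, TRUE = training sample.
#' @export
stratified_split <- function(y, train_frac, seed = 1) {
  f <- factor(y)
  check_that(train_frac > 0 && train_frac < 1, "train_frac must be in (0,1)")
  tr <- logical(length(f))
  with_seed(seed, {
    for (lv in levels(f)) {
      idx <- which(f == lv)
      n_tr <- round(train_frac * length(idx))
      check_that(n_tr >= 1 && n_tr < length(idx),
                 "split ratio %.2f leaves class '%s' empty on one side",
                 train_frac, lv)
      tr[sample(idx, n_tr)] <- TRUE
    }
  })
  tr
}

eval_split <- function(spec, X, y, tr, positive, descriptors = NULL, seed = 1) {
  fitted <- fit_model(spec, X[tr, , drop = FALSE], y[tr],
                      descriptors = if (is.null(descriptors)) NULL else
                        descriptors[tr, , drop = FALSE], seed = seed)
  pred <- predict(fitted, X[!tr, , drop = FALSE],
                  descriptors = if (is.null(descriptors)) NULL else
                    descriptors[!tr, , drop = FALSE])
  confusion_metrics(y[!tr], pred, positive)
}

#' Train/test split ladder
#'
#' For each training fraction, performs a stratified split, trains the
#' declared model and evaluates the held-out part — the classical way to
#' chart how accuracy grows with training data.
#'
#' @param X,y data.
#' @param ratios training fractions, e.g. `c(0.2, 0.4, 0.5, 0.6, 0.8)`.
#' @param spec a [model_spec()].
#' @param positive positive class value.
#' @param seed RNG seed (split and fit).
#' @param descriptors optional rule descriptors (hybrid models).
#' @return data frame, one row per ratio, columns split/accuracy/sensitivity/
#'   specificity/precision/recall/f1.
#' @export
split_ladder <- function(X, y, ratios = c(0.2, 0.4, 0.5, 0.6, 0.8), spec,
                         positive, seed = 1, descriptors = NULL) {
  X <- as_feature_matrix(X)
  rows <- lapply(ratios, function(r) {
    tr <- stratified_split(y, r, seed = seed)
    m <- eval_split(spec, X, y, tr, positive, descriptors, seed = seed)
    data.frame(split = sprintf("%d/%d", round(100 * r), round(100 * (1 - r))),
               as.data.frame(m))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Stratified k-fold cross-validation
#'
#' @inheritParams split_ladder
#' @param k number of folds.
#' @return list: `mean` and `sd` of each metric over folds, plus the
#'   per-fold data frame `folds`.
#' @export
kfold_cv <- function(X, y, k = 5, spec, positive, seed = 1, descriptors = NULL) {
  X <- as_feature_matrix(X)
  fold <- stratified_folds(y, k, seed)
  per <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    as.data.frame(eval_split(spec, X, y, tr, positive, descriptors, seed = seed))
  })
  tab <- do.call(rbind, per)
  list(mean = colMeans(tab), sd = apply(tab, 2, stats::sd), folds = tab)
}

#' Paired LDA ablation
#'
#' Fits the declared model with and without LDA reduction on the *same*
#' stratified split and reports both metric sets plus their difference.
#'
#' @inheritParams split_ladder
#' @param train_frac training fraction.
#' @return list: `with_lda`, `without_lda` (metric lists), `delta`
#'   (with - without), `train_index` (the shared split).
#' @export
ablation_lda <- function(X, y, spec, positive, train_frac = 0.7, seed = 1,
                         descriptors = NULL) {
  X <- as_feature_matrix(X)
  tr <- stratified_split(y, train_frac, seed = seed)
  spec_lda <- spec; spec_lda$use_lda <- TRUE
  spec_raw <- spec; spec_raw$use_lda <- FALSE
  a <- eval_split(spec_lda, X, y, tr, positive, descriptors, seed = seed)
  b <- eval_split(spec_raw, X, y, tr, positive, descriptors, seed = seed)
  list(with_lda = a, without_lda = b,
       delta = Map(function(u, v) u - v, a, b),
       train_index = which(tr))
}
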