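#' Fit the hybrid rule + SVM nodule classifier
#'
#' Rule thresholds act first: a candidate violating any active bound is
#' classified non-nodule outright, without consulting the SVM. The SVM is
#' trained only on rule-passing samples, mirroring a two-stage detector in
#' which obvious non-nodules are cropped out before the margin classifier
#' runs. This cuts false positives relative to a plain SVM.
#'
#' @param X feature matrix of candidates.
#' @param y binary labels (+1 nodule / -1 non-nodule, or a 2-level factor).
#' @param descriptors matrix or data frame of rule descriptors, one row per
#'   sample, with columns named as in [rule_descriptors()].
#' @param thresholds a [rule_thresholds()].
#' @param gamma,C SVM hyperparameters (see [fit_svm()]).
#' @param seed solver seed.
#' @return a `hybrid_model`.
#' @export
fit_hybrid <- function(X, y, descriptors, thresholds = default_rule_thresholds(),
                       gamma = NULL, C = 1, seed = 1) {
  X <- as_feature_matrix(X)
  descriptors <- as.data.frame(descriptors)
  check_that(nrow(descriptors) == nrow(X), "descriptors must parallel X rows")
  lv <- label_pm1(y)
  pass <- vapply(seq_len(nrow(X)), function(i) {
    length(violated_rules(as.list(descriptors[i, ]), thresholds)) == 0
  }, logical(1))
  # the SVM sees only rule-surviving samples; if pruning empties a class,
  # fall back to training on everything so the model stays usable
  use <- if (length(unique(lv$t[pass])) == 2) pass else rep(TRUE, nrow(X))
  svm <- fit_svm(X[use, , drop = FALSE], y[use], gamma = gamma, C = C, seed = seed)
  structure(list(kind = "hybrid", thresholds = thresholds, svm = svm,
                 levels = lv$levels, positive = lv$positive),
            class = c("hybrid_model", "nc_model"))
}

#' Predict with the hybrid rule + SVM classifier
#'
#' @param h a `hybrid_model`.
#' @param cand_features feature matrix.
#' @param cand_descriptors rule-descriptor rows parallel to the features.
#' @return list: `label` (predictions), `rationale` (per sample,
#'   `"rule:<name>"` if a rule decided, else `"svm"`), `score` (SVM decision
#'   value; rule-rejected samples get -Inf).
#' @export
predict_hybrid <- function(h, cand_features, cand_descriptors) {
  check_that(inherits(h, "hybrid_model"), "not a fitted hybrid model")
  X <- as_feature_matrix(cand_features)
  d <- as.data.frame(cand_descriptors)
  check_that(nrow(d) == nrow(X), "descriptors must parallel features")
  n <- nrow(X)
  rationale <- character(n)
  t <- numeric(n)
  score <- numeric(n)
  needs_svm <- logical(n)
  for (i in seq_len(n)) {
    viol <- violated_rules(as.list(d[i, ]), h$thresholds)
    if (length(viol)) {
      t[i] <- -1
      score[i] <- -Inf
      rationale[i] <- paste0("rule:", viol[1])
    } else {
      needs_svm[i] <- TRUE
      rationale[i] <- "svm"
    }
  }
  if (any(needs_svm)) {
    sc <- predict(h$svm, X[needs_svm, , drop = FALSE], type = "score")
    score[needs_svm] <- sc
    t[needs_svm] <- ifelse(sc >= 0, 1, -1)
  }
  list(label = pm1_to_labels(t, h$levels, h$positive),
       rationale = rationale, score = score)
}

#' @export
predict.hybrid_model <- function(object, newdata, type = c("class", "score"),
                                 descriptors = NULL, ...) {
  type <- match.arg(type)
  check_that(!is.null(descriptors), "hybrid prediction needs `descriptors`")
  out <- predict_hybrid(object, newdata, descriptors)
  if (type == "score") out$score else out$label
}
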