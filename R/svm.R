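#' Radial basis function kernel
#'
#' `K(x1, x2) = exp(-gamma ||x1 - x2||^2)`.
#'
#' @param x1,x2 numeric vectors of equal length.
#' @param gamma kernel width parameter, > 0.
#' @export
rbf_kernel <- function(x1, x2, gamma) {
  check_that(gamma > 0, "gamma must be > 0")
  check_that(length(x1) == length(x2), "dimension mismatch")
  exp(-gamma * sum((x1 - x2)^2))
}

# Gram matrix between row sets (vectorized).
rbf_gram <- function(X1, X2, gamma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * X1 %*% t(X2)
  exp(-gamma * pmax(d2, 0))
}

#' Fit a soft-margin RBF-kernel SVM (SMO)
#'
#' Solves the dual of the soft-margin maximum-margin problem with a
#' simplified sequential-minimal-optimization solver (pairwise alpha updates
#' to KKT tolerance). Features are z-score standardized internally and the
#' scaler is stored with the model. Labels are coerced to +1 (positive class)
#' and -1.
#'
#' @param X feature matrix.
#' @param y labels with exactly two distinct values; numeric +1/-1 is used
#'   as-is, otherwise the second sorted level is +1 unless `positive` names it.
#' @param gamma RBF width; default `1 / (ncol(X) * var(X))` (scale heuristic).
#' @param C soft-margin cost.
#' @param tol KKT tolerance of the solver.
#' @param max_passes SMO passes without progress before stopping.
#' @param positive optional value of `y` to treat as the +1 class.
#' @param seed seed for the solver's random second-index choice.
#' @return an `svm_model` with support vectors, dual coefficients and bias.
#' @export
fit_svm <- function(X, y, gamma = NULL, C = 1, tol = 1e-3, max_passes = 5,
                    positive = NULL, seed = 1) {
  X <- as_feature_matrix(X)
  lv <- label_pm1(y, positive)
  t <- lv$t
  check_that(length(unique(t)) == 2, "need both classes present")
  scaler <- fit_scaler(X)
  Z <- apply_scaler(scaler, X)
  if (is.null(gamma)) {
    v <- stats::var(as.vector(Z)); if (!is.finite(v) || v <= 0) v <- 1
    gamma <- 1 / (ncol(Z) * v)
  }
  check_that(gamma > 0 && C > 0, "gamma and C must be > 0")
  K <- rbf_gram(Z, Z, gamma)
  n <- nrow(Z)
  alpha <- numeric(n); b <- 0
  fcache <- function(i) sum(alpha * t * K[, i]) + b
  with_seed(seed, {
    passes <- 0L
    while (passes < max_passes) {
      changed <- 0L
      for (i in seq_len(n)) {
        Ei <- fcache(i) - t[i]
        if ((t[i] * Ei < -tol && alpha[i] < C) || (t[i] * Ei > tol && alpha[i] > 0)) {
          j <- sample(seq_len(n)[-i], 1)
          Ej <- fcache(j) - t[j]
          ai_old <- alpha[i]; aj_old <- alpha[j]
          if (t[i] != t[j]) {
            L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
          } else {
            L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
          }
          if (L >= H) next
          eta <- 2 * K[i, j] - K[i, i] - K[j, j]
          if (eta >= 0) next
          aj <- aj_old - t[j] * (Ei - Ej) / eta
          aj <- min(max(aj, L), H)
          if (abs(aj - aj_old) < 1e-7) next
          ai <- ai_old + t[i] * t[j] * (aj_old - aj)
          b1 <- b - Ei - t[i] * (ai - ai_old) * K[i, i] - t[j] * (aj - aj_old) * K[i, j]
          b2 <- b - Ej - t[i] * (ai - ai_old) * K[i, j] - t[j] * (aj - aj_old) * K[j, j]
          alpha[i] <- ai; alpha[j] <- aj
          b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
          changed <- changed + 1L
        }
      }
      passes <- if (changed == 0L) passes + 1L else 0L
    }
  })
  sv <- alpha > 1e-8
  model <- structure(list(kind = "svm", sv = Z[sv, , drop = FALSE],
                          coef = (alpha * t)[sv], b = b, gamma = gamma, C = C,
                          scaler = scaler, levels = lv$levels,
                          positive = lv$positive), class = c("svm_model", "nc_model"))
  model$train_pred <- predict(model, X, type = "class")
  model
}

label_pm1 <- function(y, positive = NULL) {
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    return(list(t = as.numeric(y), levels = c(-1, 1), positive = 1))
  }
  f <- factor(y)
  check_that(nlevels(f) == 2, "binary labels required")
  pos <- positive %||% levels(f)[2]
  check_that(pos %in% levels(f), "positive label not present")
  list(t = ifelse(as.character(f) == pos, 1, -1), levels = levels(f), positive = pos)
}

pm1_to_labels <- function(t, levels, positive) {
  if (is.numeric(levels)) return(t)
  neg <- setdiff(levels, positive)
  factor(ifelse(t > 0, positive, neg), levels = levels)
}

#' Decision values and class predictions of an SVM model
#'
#' @param object an `svm_model`.
#' @param newdata feature matrix.
#' @param type "class" for labels, "score" for the signed decision value
#'   (distance-like margin, positive = positive class).
#' @param ... unused.
#' @export
predict.svm_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  Z <- apply_scaler(object$scaler, as_feature_matrix(newdata))
  f <- if (nrow(object$sv) == 0) rep(object$b, nrow(Z)) else
    as.vector(rbf_gram(Z, object$sv, object$gamma) %*% object$coef + object$b)
  if (type == "score") return(f)
  pm1_to_labels(sign(f + 1e-300), object$levels, object$positive)
}

#' 5-fold grid search over (gamma, C) for the RBF SVM
#'
#' @param X,y training data.
#' @param gammas,Cs candidate grids.
#' @param k folds.
#' @param seed RNG seed (fold assignment and solver).
#' @return list: best `gamma`, `C`, the fitted model, and the CV table.
#' @export
fit_svm_cv <- function(X, y, gammas = 2^(-4:2) / ncol(as_feature_matrix(X)),
                       Cs = c(0.1, 1, 10), k = 5, seed = 1) {
  X <- as_feature_matrix(X)
  grid <- expand.grid(gamma = gammas, C = Cs)
  folds <- stratified_folds(y, k, seed)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(k), function(f) {
      tr <- folds != f
      m <- fit_svm(X[tr, , drop = FALSE], y[tr], gamma = grid$gamma[g],
                   C = grid$C[g], seed = seed)
      mean(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(acc)
  list(gamma = grid$gamma[best], C = grid$C[best],
       model = fit_svm(X, y, gamma = grid$gamma[best], C = grid$C[best], seed = seed),
       cv = cbind(grid, accuracy = acc))
}
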