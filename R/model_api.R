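#' Declare a model to be fitted by the evaluation harness
#'
#' A lightweight recipe consumed by [fit_model()]. Supported kinds:
#' "svm", "hybrid" (rule + SVM), "pso_lr", "lr" (Newton/IRLS logistic
#' regression via `glm`), "rf", "naive_bayes", "knn", "decision_tree".
#' Any kind can be prefixed by LDA reduction with `use_lda = TRUE`.
#'
#' @param method model kind string. (Named so that no kind-specific parameter
#'   passed through `...`, like KNN's `k`, can partially match it.)
#' @param use_lda reduce features with [fit_lda()] before the classifier.
#' @param ... kind-specific parameters (e.g. `gamma`, `C`, `thresholds`,
#'   `cfg`, `n_trees`, `k`, `max_depth`, `shrinkage`).
#' @export
model_spec <- function(method, ..., use_lda = FALSE) {
  kinds <- c("svm", "hybrid", "pso_lr", "lr", "rf", "naive_bayes", "knn",
             "decision_tree")
  check_that(is.character(method) && method %in% kinds,
             "unknown model kind '%s'", as.character(method)[1])
  structure(list(kind = method, use_lda = isTRUE(use_lda), params = list(...)),
            class = "model_spec")
}

#' Fit a declared model
#'
#' @param spec a [model_spec()].
#' @param X feature matrix.
#' @param y labels.
#' @param descriptors rule descriptors (required for kind "hybrid").
#' @param seed seed passed to stochastic fitters.
#' @return a fitted `nc_model`; if `use_lda`, wrapped with its projection.
#' @export
fit_model <- function(spec, X, y, descriptors = NULL, seed = 1) {
  check_that(inherits(spec, "model_spec"), "spec must be a model_spec")
  X <- as_feature_matrix(X)
  pr <- spec$params
  lda_proj <- NULL
  if (spec$use_lda) {
    lda_proj <- fit_lda(X, y, shrinkage = pr$shrinkage %||% 1e-4)
    X <- lda_transform(lda_proj, X)
  }
  m <- switch(spec$kind,
    svm = fit_svm(X, y, gamma = pr$gamma, C = pr$C %||% 1, seed = seed),
    hybrid = {
      check_that(!is.null(descriptors), "hybrid models need `descriptors`")
      fit_hybrid(X, y, descriptors,
                 thresholds = pr$thresholds %||% default_rule_thresholds(),
                 gamma = pr$gamma, C = pr$C %||% 1, seed = seed)
    },
    pso_lr = {
      cfg <- pr$cfg %||% pso_config(seed = seed)
      fit_pso_lr(X, y, cfg)
    },
    lr = fit_lr_newton(X, y),
    rf = fit_random_forest(X, y, n_trees = pr$n_trees %||% 50,
                           max_depth = pr$max_depth %||% Inf,
                           mtry = pr$mtry, seed = seed),
    naive_bayes = fit_baseline("naive_bayes", X, y),
    knn = fit_baseline("knn", X, y, params = pr),
    decision_tree = fit_baseline("decision_tree", X, y, params = pr))
  structure(list(model = m, lda = lda_proj, spec = spec),
            class = "nc_fitted")
}

#' Predict from a harness-fitted model
#'
#' @param object result of [fit_model()].
#' @param newdata feature matrix (pre-LDA space).
#' @param type "class" or "score".
#' @param descriptors rule descriptors for hybrid models.
#' @param ... unused.
#' @export
predict.nc_fitted <- function(object, newdata, type = c("class", "score"),
                              descriptors = NULL, ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  if (!is.null(object$lda)) X <- lda_transform(object$lda, X)
  if (inherits(object$model, "hybrid_model")) {
    predict(object$model, X, type = type, descriptors = descriptors)
  } else {
    predict(object$model, X, type = type)
  }
}

#' Maximum-likelihood logistic regression (IRLS), the classical reference fit
#'
#' A thin wrapper over `stats::glm(..., binomial)` returning the package's
#' [lr_model()] container, so the PSO-trained and Newton-trained models share
#' one predict contract.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @export
fit_lr_newton <- function(X, y) {
  X <- as_feature_matrix(X)
  y01 <- labels01(y)
  f <- if (is.factor(y)) factor(y) else factor(y01)
  scaler <- fit_scaler(X)
  Z <- apply_scaler(scaler, X)
  df <- data.frame(y = y01, Z)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  co <- stats::coef(fit)
  co[!is.finite(co)] <- 0
  lr_model(alpha = unname(co[1]), beta = unname(co[-1]), scaler = scaler,
           levels = levels(f), positive = levels(f)[2])
}

#' Serialize a fitted model bank entry to versioned JSON
#'
#' Covers the kinds whose parameters are plain numeric blocks (svm, lr /
#' pso_lr, hybrid thresholds). Trees are stored as nested lists.
#'
#' @param fitted an `nc_fitted` or bare `nc_model`.
#' @param path output path.
#' @export
model_to_json <- function(fitted, path) {
  m <- if (inherits(fitted, "nc_fitted")) fitted$model else fitted
  enc <- function(mx) list(shape = dim(mx), data = as.vector(t(mx)))
  obj <- switch(m$kind,
    svm = list(kind = "svm", version = 1L, sv = enc(m$sv), coef = m$coef,
               b = m$b, gamma = m$gamma, C = m$C, scaler = m$scaler,
               levels = as.character(m$levels), positive = as.character(m$positive)),
    lr = list(kind = "lr", version = 1L, alpha = m$alpha, beta = m$beta,
              scaler = m$scaler, levels = as.character(m$levels),
              positive = as.character(m$positive)),
    hybrid = list(kind = "hybrid", version = 1L,
                  thresholds = unclass(m$thresholds),
                  svm = list(sv = enc(m$svm$sv), coef = m$svm$coef, b = m$svm$b,
                             gamma = m$svm$gamma, C = m$svm$C, scaler = m$svm$scaler,
                             levels = as.character(m$svm$levels),
                             positive = as.character(m$svm$positive)),
                  levels = as.character(m$levels),
                  positive = as.character(m$positive)),
    stopf("JSON serialization not supported for kind '%s'", m$kind))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(e) matrix(e$data, e$shape[1], e$shape[2], byrow = TRUE)
  fix_levels <- function(lv) {
    suppressWarnings(num <- as.numeric(lv))
    if (!anyNA(num)) num else lv
  }
  mk_svm <- function(o) {
    structure(list(kind = "svm", sv = dec(o$sv), coef = o$coef, b = o$b,
                   gamma = o$gamma, C = o$C,
                   scaler = list(center = o$scaler$center, scale = o$scaler$scale),
                   levels = fix_levels(o$levels), positive = fix_levels(o$positive)),
              class = c("svm_model", "nc_model"))
  }
  switch(obj$kind,
    svm = mk_svm(obj),
    lr = lr_model(obj$alpha, obj$beta,
                  scaler = list(center = obj$scaler$center, scale = obj$scaler$scale),
                  levels = fix_levels(obj$levels), positive = fix_levels(obj$positive)),
    hybrid = structure(list(kind = "hybrid",
                            thresholds = do.call(rule_thresholds,
                                                 lapply(obj$thresholds, unlist)),
                            svm = mk_svm(obj$svm),
                            levels = fix_levels(obj$levels),
                            positive = fix_levels(obj$positive)),
                       class = c("hybrid_model", "nc_model")),
    stopf("unknown model kind '%s' in %s", obj$kind, path))
}
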