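#' Fit a Fisher linear discriminant projection
#'
#' Solves the generalized eigenproblem Sb w = lambda Sw w (between- vs
#' within-class scatter) via the symmetrized whitened form for numerical
#' stability. Sw is regularized as `(1 - s) Sw + s (tr(Sw)/p) I` with
#' shrinkage `s`: shrinking toward the scaled identity keeps the fit
#' well-posed both when features are collinear and when a feature is
#' constant (zero within-class variance), which real candidate sets produce. The sign
#' of each projection column is fixed so its first nonzero element is
#' positive, making fits deterministic.
#'
#' @param X feature matrix (samples x features).
#' @param y class labels (factor or vector); at least two classes with at
#'   least two samples each.
#' @param n_components number of discriminant directions, at most
#'   `nlevels(y) - 1` (the default).
#' @param shrinkage regularization weight `s` in [0, 1].
#' @return an `lda_projection`: `W` (features x components), `class_means`,
#'   `Sw`, `Sb`, `n_components`, `levels`, `grand_mean`.
#' @export
fit_lda <- function(X, y, n_components = NULL, shrinkage = 1e-4) {
  X <- as_feature_matrix(X)
  y <- factor(y)
  check_that(nlevels(y) >= 2, "need at least 2 classes")
  check_that(all(table(y) >= 2), "each class needs at least 2 samples")
  check_that(shrinkage >= 0 && shrinkage <= 1, "shrinkage must be in [0,1]")
  p <- ncol(X); n <- nrow(X)
  gm <- colMeans(X)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  cm <- matrix(0, nlevels(y), p, dimnames = list(levels(y), colnames(X)))
  for (k in levels(y)) {
    Xi <- X[y == k, , drop = FALSE]
    mu <- colMeans(Xi)
    cm[k, ] <- mu
    D <- sweep(Xi, 2, mu, "-")
    Sw <- Sw + crossprod(D)
    Sb <- Sb + nrow(Xi) * tcrossprod(mu - gm)
  }
  nu <- sum(diag(Sw)) / p
  if (nu <= 0) nu <- 1
  Swr <- (1 - shrinkage) * Sw + shrinkage * nu * diag(p)
  ev <- eigen(Swr, symmetric = TRUE)
  if (min(ev$values) <= 1e-12 * max(ev$values)) {
    stopf("within-class scatter is singular; increase `shrinkage`")
  }
  # whitening: Swr^{-1/2}
  Wh <- ev$vectors %*% diag(1 / sqrt(ev$values), p) %*% t(ev$vectors)
  M <- Wh %*% Sb %*% Wh
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  k_max <- nlevels(y) - 1L
  nc <- min(n_components %||% k_max, k_max, p)
  check_that(nc >= 1, "n_components must be >= 1")
  W <- Wh %*% em$vectors[, seq_len(nc), drop = FALSE]
  # unit-norm columns (sample-size invariant) with a deterministic sign
  for (j in seq_len(nc)) {
    W[, j] <- W[, j] / sqrt(sum(W[, j]^2))
    nz <- which(abs(W[, j]) > 1e-12)[1]
    if (!is.na(nz) && W[nz, j] < 0) W[, j] <- -W[, j]
  }
  structure(list(W = W, class_means = cm, Sw = Sw, Sb = Sb,
                 n_components = nc, levels = levels(y), grand_mean = gm,
                 eigenvalues = em$values[seq_len(nc)]),
            class = "lda_projection")
}

#' Project features through a fitted LDA
#'
#' @param p an `lda_projection`.
#' @param X matrix with the same feature count the projection was fit on.
#' @return matrix with `n_components` columns.
#' @export
lda_transform <- function(p, X) {
  X <- as_feature_matrix(X)
  check_that(ncol(X) == nrow(p$W), "feature count mismatch: got %d, expected %d",
             ncol(X), nrow(p$W))
  X %*% p$W
}

#' Fisher ratio of a projection: tr(W' Sb W) / tr(W' Sw W)
#'
#' @param p an `lda_projection` (supplies Sw, Sb).
#' @param W optional alternative projection matrix to score with the same
#'   scatter matrices (defaults to `p$W`).
#' @export
fisher_ratio <- function(p, W = NULL) {
  W <- W %||% p$W
  sum(diag(t(W) %*% p$Sb %*% W)) / sum(diag(t(W) %*% p$Sw %*% W))
}

#' Save / load an LDA projection as JSON
#'
#' Matrices are stored row-major with shape metadata.
#' @param p an `lda_projection`.
#' @param path file path.
#' @export
lda_to_json <- function(p, path) {
  enc <- function(m) list(shape = dim(m), data = as.vector(t(m)))
  obj <- list(kind = "lda_projection", version = 1L,
              W = enc(p$W), class_means = enc(p$class_means),
              Sw = enc(p$Sw), Sb = enc(p$Sb),
              n_components = p$n_components, levels = p$levels,
              grand_mean = p$grand_mean, eigenvalues = p$eigenvalues)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname lda_to_json
#' @export
lda_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_that(identical(obj$kind, "lda_projection"), "not an lda_projection file")
  dec <- function(e) matrix(e$data, e$shape[1], e$shape[2], byrow = TRUE)
  cm <- dec(obj$class_means)
  rownames(cm) <- obj$levels
  structure(list(W = dec(obj$W), class_means = cm, Sw = dec(obj$Sw),
                 Sb = dec(obj$Sb), n_components = obj$n_components,
                 levels = obj$levels, grand_mean = obj$grand_mean,
                 eigenvalues = obj$eigenvalues),
            class = "lda_projection")
}
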