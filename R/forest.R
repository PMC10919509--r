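# CART-style decision tree (Gini impurity, numeric features, axis-aligned
# splits) used both standalone and inside the random forest.

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

grow_tree <- function(X, yi, n_classes, depth, max_depth, mtry, min_split = 2) {
  counts <- tabulate(yi, n_classes)
  node <- list(counts = counts, pred = which.max(counts))  # ties: lowest index
  if (depth >= max_depth || length(yi) < min_split || gini_impurity(counts) == 0) {
    return(node)
  }
  feats <- if (mtry >= ncol(X)) seq_len(ncol(X)) else sample.int(ncol(X), mtry)
  best <- list(gain = 1e-12)
  parent_imp <- gini_impurity(counts)
  n <- length(yi)
  for (f in feats) {
    v <- X[, f]
    ord <- order(v)
    vs <- v[ord]; ys <- yi[ord]
    # candidate thresholds between distinct consecutive values
    distinct <- which(diff(vs) > 0)
    if (!length(distinct)) next
    left <- matrix(0L, n_classes, 1)
    lc <- integer(n_classes)
    total <- tabulate(ys, n_classes)
    for (cut in distinct) {
      lc <- tabulate(ys[seq_len(cut)], n_classes)
      rc <- total - lc
      imp <- (cut * gini_impurity(lc) + (n - cut) * gini_impurity(rc)) / n
      gain <- parent_imp - imp
      if (gain > best$gain) {
        best <- list(gain = gain, feature = f, threshold = (vs[cut] + vs[cut + 1]) / 2,
                     cut = cut, ord = ord)
      }
    }
  }
  if (is.null(best$feature)) return(node)
  go_left <- X[, best$feature] <= best$threshold
  node$feature <- best$feature
  node$threshold <- best$threshold
  node$left <- grow_tree(X[go_left, , drop = FALSE], yi[go_left], n_classes,
                         depth + 1L, max_depth, mtry, min_split)
  node$right <- grow_tree(X[!go_left, , drop = FALSE], yi[!go_left], n_classes,
                          depth + 1L, max_depth, mtry, min_split)
  node
}

predict_tree_row <- function(node, x) {
  while (!is.null(node$feature)) {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node
}

predict_tree <- function(node, X, n_classes) {
  t(apply(X, 1, function(x) {
    leaf <- predict_tree_row(node, x)
    p <- leaf$counts / max(sum(leaf$counts), 1)
    c(leaf$pred, p)
  }))
}

#' Fit a random forest (bagged Gini trees, majority vote)
#'
#' Each tree is grown on a bootstrap resample of size n with `mtry` randomly
#' drawn candidate features per split. Prediction is the plurality over tree
#' votes with ties broken toward the lowest class index. The out-of-bag
#' error (each sample judged only by trees whose bootstrap excluded it) is
#' stored as the generalization-error estimate `oob_error`.
#'
#' @param X feature matrix.
#' @param y class labels (factor or vector).
#' @param n_trees number of trees.
#' @param max_depth depth cap per tree (Inf = unbounded).
#' @param mtry features tried per split; default floor(sqrt(p)).
#' @param seed RNG seed.
#' @param bootstrap draw bootstrap resamples (TRUE) or train every tree on
#'   the full sample (FALSE; then no OOB estimate).
#' @return a `forest_model`.
#' @export
fit_random_forest <- function(X, y, n_trees = 50, max_depth = Inf, mtry = NULL,
                              seed = 1, bootstrap = TRUE) {
  X <- as_feature_matrix(X)
  f <- factor(y)
  check_that(nlevels(f) >= 2, "need at least 2 classes")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(X))))
  check_that(mtry <= ncol(X), "mtry exceeds feature count")
  check_that(n_trees >= 1, "n_trees must be >= 1")
  yi <- as.integer(f)
  n <- nrow(X); nc <- nlevels(f)
  with_seed(seed, {
    trees <- vector("list", n_trees)
    oob_votes <- matrix(0L, n, nc)
    for (b in seq_len(n_trees)) {
      idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      trees[[b]] <- grow_tree(X[idx, , drop = FALSE], yi[idx], nc, 0L,
                              max_depth, mtry)
      if (bootstrap) {
        oob <- setdiff(seq_len(n), unique(idx))
        if (length(oob)) {
          pr <- predict_tree(trees[[b]], X[oob, , drop = FALSE], nc)[, 1]
          oob_votes[cbind(oob, pr)] <- oob_votes[cbind(oob, pr)] + 1L
        }
      }
    }
    voted <- rowSums(oob_votes) > 0
    oob_err <- if (any(voted)) {
      pred <- apply(oob_votes[voted, , drop = FALSE], 1, which.max)
      mean(pred != yi[voted])
    } else NA_real_
    structure(list(kind = "rf", trees = trees, levels = levels(f),
                   n_classes = nc, mtry = mtry, oob_error = oob_err),
              class = c("forest_model", "nc_model"))
  })
}

#' Predict from a random forest by majority vote
#'
#' @param object a `forest_model`.
#' @param newdata feature matrix.
#' @param type "class", "score" (vote fraction for the last class level, a
#'   useful binary ranking score) or "prob" (vote-fraction matrix).
#' @param ... unused.
#' @export
predict.forest_model <- function(object, newdata, type = c("class", "score", "prob"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  votes <- matrix(0L, nrow(X), object$n_classes)
  for (tr in object$trees) {
    pr <- predict_tree(tr, X, object$n_classes)[, 1]
    votes[cbind(seq_len(nrow(X)), pr)] <- votes[cbind(seq_len(nrow(X)), pr)] + 1L
  }
  frac <- votes / length(object$trees)
  if (type == "prob") {
    colnames(frac) <- object$levels
    return(frac)
  }
  if (type == "score") return(frac[, object$n_classes])
  factor(object$levels[apply(votes, 1, which.max)], levels = object$levels)
}

#' Fit a baseline classifier (Gaussian naive Bayes, KNN, or decision tree)
#'
#' All three expose the same predict contract as the rest of the bank.
#'
#' @param kind "naive_bayes", "knn" or "decision_tree".
#' @param X,y training data.
#' @param params optional list: `k` (KNN neighbours, odd, default 5),
#'   `max_depth` (tree cap, default Inf).
#' @return an `nc_model`.
#' @export
fit_baseline <- function(kind = c("naive_bayes", "knn", "decision_tree"), X, y,
                         params = list()) {
  kind <- match.arg(kind)
  X <- as_feature_matrix(X)
  f <- factor(y)
  check_that(nlevels(f) >= 2, "need at least 2 classes")
  if (kind == "naive_bayes") {
    stats_by_class <- lapply(levels(f), function(k) {
      Xi <- X[f == k, , drop = FALSE]
      list(mean = colMeans(Xi),
           var = pmax(apply(Xi, 2, stats::var), 1e-9),
           prior = nrow(Xi) / nrow(X))
    })
    names(stats_by_class) <- levels(f)
    structure(list(kind = "nb", stats = stats_by_class, levels = levels(f)),
              class = c("nb_model", "nc_model"))
  } else if (kind == "knn") {
    k <- params$k %||% 5L
    check_that(k <= nrow(X), "k exceeds sample count")
    scaler <- fit_scaler(X)
    structure(list(kind = "knn", Z = apply_scaler(scaler, X), y = f, k = as.integer(k),
                   scaler = scaler, levels = levels(f)),
              class = c("knn_model", "nc_model"))
  } else {
    max_depth <- params$max_depth %||% Inf
    tree <- grow_tree(X, as.integer(f), nlevels(f), 0L, max_depth, ncol(X))
    structure(list(kind = "dt", tree = tree, levels = levels(f),
                   n_classes = nlevels(f)), class = c("dt_model", "nc_model"))
  }
}

#' @export
predict.nb_model <- function(object, newdata, type = c("class", "score", "prob"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  ll <- vapply(object$levels, function(k) {
    s <- object$stats[[k]]
    rowSums(-0.5 * log(2 * pi * matrix(s$var, nrow(X), ncol(X), byrow = TRUE)) -
              0.5 * sweep(X, 2, s$mean, "-")^2 /
                matrix(s$var, nrow(X), ncol(X), byrow = TRUE)) + log(s$prior)
  }, numeric(nrow(X)))
  ll <- matrix(ll, nrow = nrow(X))
  post <- exp(ll - apply(ll, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- object$levels
  if (type == "prob") return(post)
  if (type == "score") return(post[, ncol(post)])
  factor(object$levels[apply(post, 1, which.max)], levels = object$levels)
}

#' @export
predict.knn_model <- function(object, newdata, type = c("class", "score", "prob"), ...) {
  type <- match.arg(type)
  Z <- apply_scaler(object$scaler, as_feature_matrix(newdata))
  d2 <- outer(rowSums(Z^2), rowSums(object$Z^2), "+") - 2 * Z %*% t(object$Z)
  lv <- object$levels
  votes <- t(apply(d2, 1, function(row) {
    nb <- object$y[order(row)[seq_len(object$k)]]
    tabulate(as.integer(nb), length(lv))
  }))
  frac <- votes / object$k
  colnames(frac) <- lv
  if (type == "prob") return(frac)
  if (type == "score") return(frac[, length(lv)])
  factor(lv[apply(votes, 1, which.max)], levels = lv)
}

#' @export
predict.dt_model <- function(object, newdata, type = c("class", "score", "prob"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  out <- predict_tree(object$tree, X, object$n_classes)
  prob <- out[, -1, drop = FALSE]
  colnames(prob) <- object$levels
  if (type == "prob") return(prob)
  if (type == "score") return(prob[, object$n_classes])
  factor(object$levels[out[, 1]], levels = object$levels)
}
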