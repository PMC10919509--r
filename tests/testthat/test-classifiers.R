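test_that("rbf kernel closed forms and symmetry", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), gamma = 0.5), 1)
  g <- 0.7
  x1 <- c(0, 0); x2 <- c(sqrt(1 / g), 0)   # ||x1-x2||^2 = 1/gamma
  expect_equal(rbf_kernel(x1, x2, g), exp(-1), tolerance = 1e-12)
  set.seed(1)
  for (k in 1:5) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(rbf_kernel(a, b, 0.3), rbf_kernel(b, a, 0.3))
  }
  expect_error(rbf_kernel(a, b, -1), "gamma")
})

test_that("svm solves symmetric 1D and XOR problems", {
  X <- matrix(c(-1, 1), 2, 1)
  m <- fit_svm(X, c(-1, 1), gamma = 0.5, C = 1e3)
  # boundary at 0 by symmetry: both points classified correctly, scores symmetric
  s <- predict(m, matrix(c(-1, 1), 2, 1), type = "score")
  expect_lt(abs(s[1] + s[2]), 1e-6)
  expect_true(all(predict(m, X) == c(-1, 1)))
  expect_equal(nrow(m$sv), 2)
  # XOR is RBF-solvable
  Xx <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  yx <- c(-1, 1, 1, -1)
  mx <- fit_svm(Xx, yx, gamma = 1, C = 100)
  expect_equal(as.numeric(predict(mx, Xx)), yx)
})

test_that("svm is invariant to duplicating the training set and reproduces stored training predictions", {
  d <- generate_feature_table(40, list(a = list(mean = c(0, 0), cov = diag(2)),
                                       b = list(mean = c(3, 3), cov = diag(2))), seed = 3)
  m1 <- fit_svm(d$X, d$y)
  m2 <- fit_svm(rbind(d$X, d$X), c(d$y, d$y))
  s1 <- predict(m1, d$X, type = "score")
  s2 <- predict(m2, d$X, type = "score")
  expect_gt(stats::cor(s1, s2), 0.99)
  expect_identical(predict(m1, d$X), predict(m2, d$X))
  expect_identical(m1$train_pred, predict(m1, d$X))
  expect_error(fit_svm(d$X, rep("a", 80)), "binary|class")
})

test_that("lr probability and log likelihood match closed forms", {
  m <- lr_model(alpha = 0, beta = c(1))
  expect_equal(lr_probability(m, 0), 0.5)
  expect_equal(lr_probability(m, log(3)), 0.75, tolerance = 1e-12)
  z <- seq(-5, 5, by = 0.5)
  expect_equal(lr_probability(m, z), 1 - lr_probability(m, -z), tolerance = 1e-12)
  # stability at extreme linear predictors
  expect_true(is.finite(lr_probability(m, 700)) && lr_probability(m, 700) < 1)
  # null model: J = -n ln 2
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2)
  y <- rbinom(30, 1, 0.5)
  m0 <- lr_model(0, c(0, 0))
  expect_equal(lr_log_likelihood(m0, X, y), -30 * log(2), tolerance = 1e-10)
  # independent per-sample Bernoulli sum
  mb <- lr_model(0.3, c(0.5, -1))
  p <- lr_probability(mb, X)
  expect_equal(lr_log_likelihood(mb, X, y),
               sum(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-10)
  expect_lte(lr_log_likelihood(mb, X, y), 0)
})

test_that("pso inertia hits its endpoints exactly and steps fix stationary particles", {
  cfg <- pso_config(itermax = 50)
  expect_identical(pso_inertia(cfg, 0), cfg$wmax)
  expect_identical(pso_inertia(cfg, 50), cfg$wmin)
  expect_error(pso_config(wmax = 0.3, wmin = 0.5), "wmax")
  # particle at pb = gb with zero velocity stays put
  state <- list(X = matrix(1, 1, 2), V = matrix(0, 1, 2),
                pbest = matrix(1, 1, 2), pbest_fit = 5,
                gbest = c(1, 1), gbest_fit = 5)
  ns <- pso_step(state, cfg, 0, function(x) -sum(x^2))
  expect_equal(ns$X, state$X)
  expect_error(pso_step(state, cfg, 50, function(x) 0), "itermax")
})

test_that("pso-lr recovers the maximum-likelihood fit on synthetic logistic data", {
  set.seed(5)
  x <- matrix(rnorm(500), 500, 1)
  y <- rbinom(500, 1, 1 / (1 + exp(-(0 + 2 * x))))
  pso <- fit_pso_lr(x, y, pso_config(seed = 9))
  # oracle: IRLS via glm on the same standardized data
  scaler <- pso$scaler
  z <- (x - scaler$center) / scaler$scale
  oracle <- suppressWarnings(stats::glm(y ~ z, family = stats::binomial()))
  co <- unname(stats::coef(oracle))
  expect_lt(abs(pso$alpha - co[1]), 0.5)
  expect_lt(abs(pso$beta - co[2]), 0.5)
  # global best fitness is monotone and beats the null model
  tr <- attr(pso, "trace")
  expect_true(all(diff(tr) >= 0))
  expect_gte(attr(pso, "fitness"), -500 * log(2))
  # determinism
  pso2 <- fit_pso_lr(x, y, pso_config(seed = 9))
  expect_identical(pso$beta, pso2$beta)
  expect_identical(attr(pso, "trace"), attr(pso2, "trace"))
})

test_that("pso-lr and newton-lr generalize alike on separable data", {
  d <- generate_feature_table(150, list(a = list(mean = c(0, 0), cov = diag(2)),
                                        b = list(mean = c(4, 2), cov = diag(2))), seed = 6)
  tr <- stratified_split(d$y, 0.6, seed = 2)
  mp <- fit_pso_lr(d$X[tr, ], d$y[tr], pso_config(seed = 3))
  mn <- fit_lr_newton(d$X[tr, ], d$y[tr])
  acc_p <- mean(predict(mp, d$X[!tr, ]) == d$y[!tr])
  acc_n <- mean(predict(mn, d$X[!tr, ]) == d$y[!tr])
  expect_lte(abs(acc_p - acc_n), 0.02)
})

test_that("random forest honors its contracts", {
  d <- generate_feature_table(40, list(a = list(mean = c(0, 0), cov = diag(2)),
                                       b = list(mean = c(2, 2), cov = diag(2))), seed = 7)
  # single unbounded tree without bootstrap memorizes any consistent labelling
  rf1 <- fit_random_forest(d$X, d$y, n_trees = 1, bootstrap = FALSE, mtry = 2)
  expect_equal(mean(predict(rf1, d$X) == d$y), 1)
  expect_error(fit_random_forest(d$X, d$y, mtry = 5), "mtry")
  # prediction is the plurality over tree votes; ties break to the lowest level
  rf <- fit_random_forest(d$X, d$y, n_trees = 10, seed = 3)
  prob <- predict(rf, d$X, type = "prob")
  cls <- predict(rf, d$X)
  manual <- apply(prob, 1, function(p) colnames(prob)[which.max(p)])
  expect_equal(as.character(cls), manual)
  # determinism under seed
  rf2 <- fit_random_forest(d$X, d$y, n_trees = 10, seed = 3)
  expect_identical(predict(rf, d$X, type = "prob"), predict(rf2, d$X, type = "prob"))
})

test_that("OOB error approximates held-out error on 3-class Gaussian data", {
  d <- generate_feature_table(200, list(
    a = list(mean = c(0, 0, 0), cov = diag(3)),
    b = list(mean = c(2.5, 0, 0), cov = diag(3)),
    c = list(mean = c(0, 2.5, 0), cov = diag(3))), seed = 8)
  tr <- stratified_split(d$y, 0.5, seed = 4)
  rf <- fit_random_forest(d$X[tr, ], d$y[tr], n_trees = 60, seed = 5)
  held <- mean(predict(rf, d$X[!tr, ]) != d$y[!tr])
  expect_lt(abs(rf$oob_error - held), 0.1)
})

test_that("baselines share the predict contract and match closed forms", {
  # NB on two equal-variance 1D Gaussians: boundary at the midpoint
  d <- generate_feature_table(500, list(a = list(mean = 0, cov = 1),
                                        b = list(mean = 4, cov = 1)), seed = 9)
  nb <- fit_baseline("naive_bayes", d$X, d$y)
  probe <- matrix(seq(1.2, 2.8, by = 0.05), ncol = 1)
  pred <- predict(nb, probe)
  flips <- which(diff(as.integer(pred)) != 0)
  expect_lt(abs(probe[flips[1]] - 2), 0.3)
  # KNN k = 1 memorizes distinct points
  knn <- fit_baseline("knn", d$X, d$y, params = list(k = 1))
  expect_equal(mean(predict(knn, d$X) == d$y), 1)
  expect_error(fit_baseline("knn", d$X, d$y, params = list(k = 1e6)), "k exceeds")
  # all kinds runnable through one interface on one table
  for (kind in c("naive_bayes", "knn", "decision_tree")) {
    m <- fit_baseline(kind, d$X, d$y)
    expect_length(predict(m, d$X[1:7, , drop = FALSE]), 7)
    expect_length(predict(m, d$X[1:7, , drop = FALSE], type = "score"), 7)
  }
  sv <- fit_svm(d$X, d$y)
  expect_length(predict(sv, d$X[1:7, , drop = FALSE]), 7)
})

test_that("hybrid rule+svm decides by rules first, with rationale", {
  ds <- phantom_candidate_dataset(n_slices = 5, seed = 301)
  th <- default_rule_thresholds()
  h <- fit_hybrid(ds$X, ds$y, ds$descriptors, thresholds = th)
  out <- predict_hybrid(h, ds$X, ds$descriptors)
  elong_bad <- ds$descriptors$elongation > 3
  expect_true(all(out$label[elong_bad] == "non-nodule"))
  expect_true(all(grepl("^rule:", out$rationale[elong_bad])))
  expect_true(all(out$rationale[!elong_bad &
    ds$descriptors$circularity >= 0.4 &
    ds$descriptors$rectangularity >= 0.3 &
    ds$descriptors$mean_intensity >= 0.3] == "svm"))
})

test_that("hybrid never produces more false positives than the plain svm", {
  fp_h <- 0; fp_s <- 0
  for (seed in 1:10) {
    tr <- phantom_candidate_dataset(4, seed = 400 + seed * 10)
    te <- phantom_candidate_dataset(2, seed = 700 + seed * 10)
    h <- fit_hybrid(tr$X, tr$y, tr$descriptors)
    s <- fit_svm(tr$X, tr$y)
    ph <- predict_hybrid(h, te$X, te$descriptors)$label
    ps <- predict(s, te$X)
    neg <- te$y == "non-nodule"
    fp_h <- fp_h + sum(ph[neg] == "nodule")
    fp_s <- fp_s + sum(ps[neg] == "nodule")
  }
  expect_lte(fp_h, fp_s)
})

test_that("models round-trip through versioned JSON", {
  d <- generate_feature_table(40, list(a = list(mean = c(0, 0), cov = diag(2)),
                                       b = list(mean = c(3, 3), cov = diag(2))), seed = 10)
  f <- withr::local_tempfile(fileext = ".json")
  m <- fit_svm(d$X, d$y)
  model_to_json(m, f)
  m2 <- model_from_json(f)
  expect_equal(predict(m, d$X, type = "score"), predict(m2, d$X, type = "score"),
               tolerance = 1e-10)
  lr <- fit_lr_newton(d$X, d$y)
  model_to_json(lr, f)
  lr2 <- model_from_json(f)
  expect_equal(predict(lr, d$X, type = "score"), predict(lr2, d$X, type = "score"),
               tolerance = 1e-10)
})
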