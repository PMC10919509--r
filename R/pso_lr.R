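#' Logistic regression model container
#'
#' @param alpha intercept.
#' @param beta coefficient vector.
#' @param scaler optional feature standardizer applied before the linear
#'   predictor.
#' @param levels,positive label bookkeeping for prediction.
#' @export
lr_model <- function(alpha, beta, scaler = NULL, levels = c(0, 1), positive = 1) {
  structure(list(kind = "lr", alpha = alpha, beta = beta, scaler = scaler,
                 levels = levels, positive = positive),
            class = c("lr_model", "nc_model"))
}

# numerically stable sigmoid / log(1 + e^z)
sigmoid <- function(z) ifelse(z >= 0, 1 / (1 + exp(-z)), exp(z) / (1 + exp(z)))
log1pexp <- function(z) ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))

lr_linear <- function(m, X) {
  X <- as_feature_matrix(X)
  if (!is.null(m$scaler)) X <- apply_scaler(m$scaler, X)
  as.vector(m$alpha + X %*% m$beta)
}

#' Predicted probability of the logistic model
#'
#' `p = e^z / (1 + e^z)` with `z = alpha + sum_j beta_j x_j`, evaluated in a
#' numerically stable form for |z| up to the double-precision limit.
#'
#' @param m an [lr_model()].
#' @param x feature vector or matrix (rows = samples).
#' @return probability (or vector) in (0, 1).
#' @export
lr_probability <- function(m, x) {
  if (is.null(dim(x))) {
    # vector input: a single sample, unless the model has one feature, in
    # which case it is a vector of scalar samples
    x <- if (length(m$beta) == 1) matrix(x, ncol = 1) else matrix(x, nrow = 1)
  }
  p <- sigmoid(lr_linear(m, x))
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Binomial log-likelihood of a logistic model
#'
#' `J = sum_i [ y_i z_i - ln(1 + e^{z_i}) ]`, the fitness maximized by the
#' swarm. Always <= 0 for labels in {0, 1}, approaching 0 for a saturated
#' perfect separator.
#'
#' @param m an [lr_model()].
#' @param X feature matrix.
#' @param y labels in {0, 1} (or a 2-level factor; second level = 1).
#' @export
lr_log_likelihood <- function(m, X, y) {
  y <- labels01(y)
  z <- lr_linear(m, X)
  sum(y * z - log1pexp(z))
}

labels01 <- function(y) {
  if (is.numeric(y) && all(y %in% c(0, 1))) return(as.numeric(y))
  f <- factor(y)
  check_that(nlevels(f) == 2, "binary labels required")
  as.numeric(f == levels(f)[2])
}

#' Particle swarm configuration
#'
#' Canonical settings: 30 particles, cognitive and social factors
#' c1 = c2 = 2, inertia decaying linearly from wmax = 0.9 to wmin = 0.4 over
#' `itermax` iterations, velocities clamped per dimension.
#'
#' @param swarm_size particles.
#' @param c1,c2 cognitive / social acceleration factors (>= 0).
#' @param wmax,wmin inertia bounds, `wmax >= wmin > 0`.
#' @param itermax iteration cap (>= 1).
#' @param vclamp velocity clamp per (standardized) dimension.
#' @param seed RNG seed.
#' @export
pso_config <- function(swarm_size = 30, c1 = 2, c2 = 2, wmax = 0.9, wmin = 0.4,
                       itermax = 100, vclamp = 1, seed = 1) {
  check_that(wmax >= wmin && wmin > 0, "need wmax >= wmin > 0")
  check_that(itermax >= 1, "itermax must be >= 1")
  check_that(c1 >= 0 && c2 >= 0, "c1 and c2 must be >= 0")
  check_that(swarm_size >= 1, "swarm_size must be >= 1")
  structure(list(swarm_size = as.integer(swarm_size), c1 = c1, c2 = c2,
                 wmax = wmax, wmin = wmin, itermax = as.integer(itermax),
                 vclamp = vclamp, seed = as.integer(seed)), class = "pso_config")
}

#' Linearly decaying inertia weight
#'
#' `w = wmax - ((wmax - wmin) / itermax) * iter`: exactly `wmax` at iter = 0
#' and `wmin` at iter = itermax.
#'
#' @param cfg a [pso_config()].
#' @param iter iteration index in [0, itermax].
#' @export
pso_inertia <- function(cfg, iter) {
  check_that(iter >= 0 && iter <= cfg$itermax, "iter must lie in [0, itermax]")
  if (iter == cfg$itermax) return(cfg$wmin)   # exact endpoint, no roundoff
  cfg$wmax - (cfg$wmax - cfg$wmin) / cfg$itermax * iter
}

#' One synchronous particle-swarm step
#'
#' Velocity update `v <- w v + c1 r1 (pb - x) + c2 r2 (gb - x)` with fresh
#' uniform r1, r2 per particle and dimension, velocity clamping, synchronous
#' position update, then personal/global best refresh against `fitness`
#' (maximized). A particle sitting at its personal best which is also the
#' global best with zero velocity stays put.
#'
#' @param state list with matrices `X` (particles x dims), `V`, `pbest`,
#'   vector `pbest_fit`, vector `gbest`, scalar `gbest_fit`.
#' @param cfg a [pso_config()].
#' @param iter current iteration (0-based; sets the inertia weight).
#' @param fitness function(position) -> scalar to maximize.
#' @return updated state.
#' @export
pso_step <- function(state, cfg, iter, fitness) {
  check_that(iter < cfg$itermax, "iter must be < itermax")
  w <- pso_inertia(cfg, iter)
  np <- nrow(state$X); nd <- ncol(state$X)
  r1 <- matrix(stats::runif(np * nd), np, nd)
  r2 <- matrix(stats::runif(np * nd), np, nd)
  V <- w * state$V +
    cfg$c1 * r1 * (state$pbest - state$X) +
    cfg$c2 * r2 * (matrix(state$gbest, np, nd, byrow = TRUE) - state$X)
  V <- pmin(pmax(V, -cfg$vclamp), cfg$vclamp)
  X <- state$X + V
  fit <- apply(X, 1, fitness)
  improved <- fit > state$pbest_fit
  state$pbest[improved, ] <- X[improved, , drop = FALSE]
  state$pbest_fit[improved] <- fit[improved]
  best <- which.max(state$pbest_fit)
  if (state$pbest_fit[best] > state$gbest_fit) {
    state$gbest <- state$pbest[best, ]
    state$gbest_fit <- state$pbest_fit[best]
  }
  state$X <- X; state$V <- V
  state
}

#' Fit logistic regression by particle-swarm optimization
#'
#' Particles encode (alpha, beta) over standardized features; the fitness is
#' the binomial log-likelihood. One particle is seeded at the zero vector, so
#' the final fitness can never fall below `-n ln 2`, the null model's value.
#' The global-best fitness is non-decreasing across iterations by
#' construction.
#'
#' @param X feature matrix.
#' @param y binary labels ({0,1} or 2-level factor).
#' @param cfg a [pso_config()].
#' @return an [lr_model()] with attribute `"trace"` (global-best fitness per
#'   iteration) and `"fitness"` (final log-likelihood).
#' @export
fit_pso_lr <- function(X, y, cfg = pso_config()) {
  X <- as_feature_matrix(X)
  y01 <- labels01(y)
  check_that(length(unique(y01)) == 2, "need both classes present")
  f <- if (is.factor(y)) factor(y) else factor(y01)
  scaler <- fit_scaler(X)
  Z <- apply_scaler(scaler, X)
  nd <- ncol(Z) + 1L
  fitness <- function(theta) {
    z <- theta[1] + as.vector(Z %*% theta[-1])
    sum(y01 * z - log1pexp(z))
  }
  with_seed(cfg$seed, {
    P <- matrix(stats::runif(cfg$swarm_size * nd, -1, 1), cfg$swarm_size, nd)
    P[1, ] <- 0   # null-model particle
    V <- matrix(stats::runif(cfg$swarm_size * nd, -0.1, 0.1), cfg$swarm_size, nd)
    fit0 <- apply(P, 1, fitness)
    state <- list(X = P, V = V, pbest = P, pbest_fit = fit0,
                  gbest = P[which.max(fit0), ], gbest_fit = max(fit0))
    trace <- numeric(cfg$itermax)
    for (it in seq_len(cfg$itermax)) {
      state <- pso_step(state, cfg, it - 1L, fitness)
      trace[it] <- state$gbest_fit
    }
    m <- lr_model(alpha = state$gbest[1], beta = state$gbest[-1], scaler = scaler,
                  levels = levels(f), positive = levels(f)[2])
    attr(m, "trace") <- trace
    attr(m, "fitness") <- state$gbest_fit
    m
  })
}

#' Predict from a logistic model
#'
#' @param object an [lr_model()].
#' @param newdata feature matrix.
#' @param type "class", "score" (probability of the positive class), or
#'   "prob".
#' @param ... unused.
#' @export
predict.lr_model <- function(object, newdata, type = c("class", "score", "prob"), ...) {
  type <- match.arg(type)
  p <- lr_probability(object, as_feature_matrix(newdata))
  if (type != "class") return(p)
  lv <- object$levels
  neg <- setdiff(lv, object$positive)[1]
  out <- ifelse(p > 0.5, object$positive, neg)
  if (is.character(lv)) factor(out, levels = lv) else out
}
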