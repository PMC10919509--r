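#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring global state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a call is reproducible from its `seed` argument and
#' never perturbs the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Shift a matrix by (dr, dc) with boundary handling
#'
#' @param m numeric matrix.
#' @param dr,dc row/column shift applied to the sampling grid: the result at
#'   (r, c) holds `m[r + dr, c + dc]`.
#' @param boundary "reflect" (Neumann, edge replication) or "zero".
#' @keywords internal
shift_matrix <- function(m, dr, dc, boundary = c("reflect", "zero")) {
  boundary <- match.arg(boundary)
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq_len(nr) + dr
  ci <- seq_len(nc) + dc
  if (boundary == "reflect") {
    ri <- pmin(pmax(ri, 1L), nr)
    ci <- pmin(pmax(ci, 1L), nc)
    m[ri, ci, drop = FALSE]
  } else {
    out <- matrix(0, nr, nc)
    rok <- ri >= 1L & ri <= nr
    cok <- ci >= 1L & ci <= nc
    out[rok, cok] <- m[ri[rok], ci[cok], drop = FALSE]
    out
  }
}

#' Separable Gaussian blur with reflective boundaries
#' @keywords internal
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  acc <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) acc <- acc + k[i] * shift_matrix(m, (-r:r)[i], 0L)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_matrix(acc, 0L, (-r:r)[i])
  out
}

#' Local mean over a square window (uniform box filter, reflective edges)
#' @keywords internal
box_filter <- function(m, radius) {
  n <- (2L * radius + 1L)^2
  acc <- matrix(0, nrow(m), ncol(m))
  for (dr in -radius:radius) {
    row <- shift_matrix(m, dr, 0L)
    for (dc in -radius:radius) acc <- acc + shift_matrix(row, 0L, dc)
  }
  acc / n
}

#' Sobel gradient magnitude
#'
#' @param pixels numeric matrix.
#' @return matrix of gradient magnitudes (same shape, reflective boundary).
#' @export
sobel_magnitude <- function(pixels) {
  s <- function(dr, dc) shift_matrix(pixels, dr, dc)
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) - (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) - (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Standardizer learned on training data (z-score per column)
#' @keywords internal
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(center = mu, scale = sd)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  check_that(is.matrix(X) && is.numeric(X), "expected a numeric feature matrix")
  check_that(all(is.finite(X)), "feature matrix contains non-finite values")
  X
}
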