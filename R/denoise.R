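#' Denoising configuration
#'
#' @param method one of "gaussian", "perona_malik", "catte", "mean_shift".
#' @param hs spatial bandwidth in pixels (mean shift).
#' @param hr range bandwidth in gray units (mean shift).
#' @param iterations iteration count (diffusion steps / mean-shift cap).
#' @param kappa conductance scale for Perona-Malik / Catte diffusion: gradients
#'   well below kappa diffuse freely, gradients above are preserved as edges.
#' @param dt explicit diffusion time step; must satisfy the 2D stability bound
#'   0 < dt <= 0.25.
#' @param presmooth_sigma Gaussian pre-smoothing scale (pixels) used by the
#'   Catte variant when estimating gradients for the conductance.
#' @return a `denoise_config`.
#' @export
denoise_config <- function(method = c("catte", "perona_malik", "gaussian", "mean_shift"),
                           hs = 2, hr = 0.2, iterations = 10, kappa = 0.1,
                           dt = 0.2, presmooth_sigma = 0.8) {
  method <- match.arg(method)
  check_that(hs > 0 && hr > 0, "bandwidths hs and hr must be > 0")
  check_that(dt > 0 && dt <= 0.25, "dt must satisfy 0 < dt <= 0.25 (explicit-scheme stability)")
  check_that(iterations >= 1, "iterations must be >= 1")
  check_that(kappa > 0, "kappa must be > 0")
  structure(list(method = method, hs = hs, hr = hr, iterations = as.integer(iterations),
                 kappa = kappa, dt = dt, presmooth_sigma = presmooth_sigma),
            class = "denoise_config")
}

#' Mean-shift mode filtering
#'
#' Each pixel is moved to the mode of the local joint (spatial, range) kernel
#' density of the original samples: the estimate u is iterated as the
#' Gaussian-weighted mean of neighbourhood intensities, with range weights
#' centred on the current estimate, until the maximum change drops below 1e-4
#' or the iteration cap is hit. A constant image is a fixed point; an isolated
#' impulse whose amplitude lies within the range bandwidth is pulled onto the
#' background mode.
#'
#' @param img [image_slice()] or numeric matrix.
#' @param cfg [denoise_config()] with method "mean_shift".
#' @return denoised `image_slice`.
#' @export
mean_shift_filter <- function(img, cfg = denoise_config("mean_shift")) {
  check_that(identical(cfg$method, "mean_shift"), "cfg$method must be 'mean_shift'")
  I0 <- as_pixel_matrix(img)
  r <- max(1L, ceiling(2 * cfg$hs))
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  ws <- exp(-0.5 * (offs$dr^2 + offs$dc^2) / cfg$hs^2)
  shifted <- lapply(seq_len(nrow(offs)),
                    function(i) shift_matrix(I0, offs$dr[i], offs$dc[i]))
  U <- I0
  for (iter in seq_len(min(cfg$iterations, 20L))) {
    num <- matrix(0, nrow(I0), ncol(I0)); den <- num
    for (i in seq_len(nrow(offs))) {
      wq <- ws[i] * exp(-0.5 * ((shifted[[i]] - U) / cfg$hr)^2)
      num <- num + wq * shifted[[i]]
      den <- den + wq
    }
    Unew <- num / den
    delta <- max(abs(Unew - U))
    U <- Unew
    if (delta < 1e-4) break
  }
  out <- as_image_slice(img)
  out$pixels <- clamp01(U)
  out
}

pm_conductance <- function(d, kappa) 1 / (1 + (d / kappa)^2)

#' Iterated explicit diffusion (linear, Perona-Malik, or Catte)
#'
#' All variants use a conservative 4-neighbour explicit scheme with
#' reflective (Neumann) boundaries, so linear diffusion preserves the image
#' mean. "gaussian" is linear diffusion; "perona_malik" modulates each
#' neighbour flux by g(|d|) = 1 / (1 + (|d|/kappa)^2); "catte" uses the same
#' conductance but evaluates the gradient on a Gaussian-presmoothed copy of
#' the current image, which makes the edge-stopping robust to noise.
#'
#' @inheritParams mean_shift_filter
#' @return diffused `image_slice`.
#' @export
diffuse <- function(img, cfg = denoise_config("catte")) {
  check_that(cfg$method %in% c("gaussian", "perona_malik", "catte"),
             "cfg$method must be gaussian, perona_malik or catte")
  I <- as_pixel_matrix(img)
  dirs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (iter in seq_len(cfg$iterations)) {
    G <- if (cfg$method == "catte") gauss_blur(I, cfg$presmooth_sigma) else I
    upd <- matrix(0, nrow(I), ncol(I))
    for (d in dirs) {
      dI <- shift_matrix(I, d[1], d[2]) - I
      cnd <- switch(cfg$method,
        gaussian = 1,
        perona_malik = pm_conductance(abs(dI), cfg$kappa),
        catte = pm_conductance(abs(shift_matrix(G, d[1], d[2]) - G), cfg$kappa))
      upd <- upd + cnd * dI
    }
    I <- I + cfg$dt * upd
  }
  out <- as_image_slice(img)
  out$pixels <- clamp01(I)
  out
}

#' Denoise an image with any configured method
#'
#' @inheritParams mean_shift_filter
#' @export
denoise <- function(img, cfg) {
  if (cfg$method == "mean_shift") mean_shift_filter(img, cfg) else diffuse(img, cfg)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 * log10(MAX^2 / MSE)` with MAX = 1 on the normalized gray scale.
#' Identical images have zero MSE and return `Inf`.
#'
#' @param reference,test images of identical shape.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(reference, test) {
  a <- as_pixel_matrix(reference); b <- as_pixel_matrix(test)
  check_that(all(dim(a) == dim(b)), "images must have the same shape")
  mse <- mean((a - b)^2)
  if (mse == 0) Inf else 10 * log10(1 / mse)
}

#' Binary edge map by thresholded Sobel magnitude
#'
#' @param img image slice or matrix.
#' @param threshold gradient-magnitude cutoff; if NULL, Otsu's threshold on
#'   the magnitudes is used.
#' @return logical matrix of edge pixels.
#' @export
sobel_edges <- function(img, threshold = NULL) {
  g <- sobel_magnitude(as_pixel_matrix(img))
  if (is.null(threshold)) threshold <- otsu_threshold(g)
  g > threshold
}

#' Pratt's figure of merit for edge preservation
#'
#' `FOM = (1 / max(Nr, Nt)) * sum_t 1 / (1 + alpha * d_t^2)` where `d_t` is
#' the Euclidean distance from each test edge pixel to the nearest reference
#' edge pixel. Equals 1 for identical edge maps; displaced or spurious edges
#' lower the score.
#'
#' @param reference_edges,test_edges logical matrices of edge pixels.
#' @param alpha distance penalty scaling (default 1/9, the customary value).
#' @return score in (0, 1] (0 if the test map is empty).
#' @export
fom <- function(reference_edges, test_edges, alpha = 1 / 9) {
  check_that(any(reference_edges), "reference edge map is empty")
  check_that(all(dim(reference_edges) == dim(test_edges)),
             "edge maps must have the same shape")
  nr <- sum(reference_edges); nt <- sum(test_edges)
  if (nt == 0) return(0)
  ref <- which(reference_edges, arr.ind = TRUE)
  tst <- which(test_edges, arr.ind = TRUE)
  # nearest-reference distance per test pixel, chunked to bound memory
  d2 <- vapply(seq_len(nrow(tst)), function(i) {
    min((ref[, 1] - tst[i, 1])^2 + (ref[, 2] - tst[i, 2])^2)
  }, numeric(1))
  sum(1 / (1 + alpha * d2)) / max(nr, nt)
}

#' Mean structural similarity (SSIM)
#'
#' Local means, variances and covariance are computed over a uniform square
#' window (default 7x7); constants C1 = (0.01)^2 and C2 = (0.03)^2 on the
#' [0,1] dynamic range.
#'
#' @param reference,test images of identical shape.
#' @param window odd window side length in pixels.
#' @return mean SSIM in [-1, 1].
#' @export
ssim <- function(reference, test, window = 7) {
  a <- as_pixel_matrix(reference); b <- as_pixel_matrix(test)
  check_that(all(dim(a) == dim(b)), "images must have the same shape")
  check_that(window %% 2 == 1 && window >= 3, "window must be odd and >= 3")
  check_that(window <= min(dim(a)), "window larger than image")
  r <- (window - 1L) %/% 2L
  C1 <- 0.01^2; C2 <- 0.03^2
  mu_a <- box_filter(a, r); mu_b <- box_filter(b, r)
  va <- box_filter(a^2, r) - mu_a^2
  vb <- box_filter(b^2, r) - mu_b^2
  cab <- box_filter(a * b, r) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}
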