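#' Noisy step-edge phantom for denoiser benchmarking
#'
#' A two-level vertical step corrupted by mixed noise: additive Gaussian
#' noise (quantum / electronic noise) plus a small fraction of salt-and-pepper
#' impulses (detector artifacts). The impulsive component is what separates
#' the diffusion variants: a raw-gradient conductance (Perona-Malik) locks
#' onto impulses as if they were edges, while the Catte variant's presmoothed
#' gradient does not.
#'
#' @param seed RNG seed.
#' @param size image side length.
#' @param levels the two step gray levels.
#' @param sigma Gaussian noise sd.
#' @param impulse_frac fraction of pixels replaced by 0/1 impulses.
#' @return list with `clean` and `noisy` matrices.
#' @export
noisy_step_phantom <- function(seed, size = 64, levels = c(0.3, 0.7),
                               sigma = 0.15, impulse_frac = 0.02) {
  with_seed(seed, {
    img <- matrix(levels[1], size, size)
    img[, (size %/% 2 + 1):size] <- levels[2]
    n <- img + matrix(stats::rnorm(size^2, 0, sigma), size, size)
    if (impulse_frac > 0) {
      idx <- sample(size^2, round(impulse_frac * size^2))
      n[idx] <- ifelse(stats::runif(length(idx)) < 0.5, 0, 1)
    }
    list(clean = img, noisy = clamp01(n))
  })
}

#' Sample textured background patches from a labelled slice
#'
#' Disk-shaped masks placed on object-free background, used to compare
#' nodule gray/texture statistics against parenchyma texture.
#'
#' @param ls a `labelled_slice`.
#' @param n number of patches to attempt.
#' @param radius patch radius in pixels.
#' @param seed RNG seed.
#' @return list of logical masks (possibly fewer than `n`).
#' @export
background_patches <- function(ls, n = 10, radius = 7, seed = 1) {
  h <- nrow(ls$image$pixels); w <- ncol(ls$image$pixels)
  occ <- if (length(ls$truth_masks)) Reduce(`|`, ls$truth_masks) else
    matrix(FALSE, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  with_seed(seed, {
    out <- list()
    for (k in seq_len(4 * n)) {
      if (length(out) >= n) break
      cy <- stats::runif(1, radius + 2, h - radius - 2)
      cx <- stats::runif(1, radius + 2, w - radius - 2)
      m <- (rows - cy)^2 + (cols - cx)^2 <= radius^2
      if (!any(m & occ)) out[[length(out) + 1L]] <- m
    }
    out
  })
}

#' Benchmark the diffusion denoisers on noisy step-edge phantoms
#'
#' Matched iteration budgets across methods; one row of PSNR values (dB)
#' per seed.
#'
#' @param seeds integer vector of phantom seeds.
#' @param iterations diffusion iterations for every method.
#' @param kappa conductance scale for PM / Catte.
#' @param dt time step.
#' @param ... forwarded to [noisy_step_phantom()].
#' @return matrix seeds x methods (gaussian, perona_malik, catte) of PSNR.
#' @export
denoise_benchmark <- function(seeds, iterations = 25, kappa = 0.1, dt = 0.2, ...) {
  methods <- c("gaussian", "perona_malik", "catte")
  out <- matrix(NA_real_, length(seeds), length(methods),
                dimnames = list(NULL, methods))
  for (i in seq_along(seeds)) {
    st <- noisy_step_phantom(seeds[i], ...)
    for (m in methods) {
      cfg <- denoise_config(m, iterations = iterations, kappa = kappa, dt = dt)
      out[i, m] <- psnr(st$clean, diffuse(st$noisy, cfg))
    }
  }
  out
}
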