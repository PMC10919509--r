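test_that("denoise_config enforces stability and bandwidth bounds", {
  expect_error(denoise_config(dt = 0.3), "stability")
  expect_error(denoise_config(hs = 0), "bandwidth")
  expect_error(denoise_config(iterations = 0), "iterations")
})

test_that("all denoisers fix constant images and preserve [0,1]", {
  cst <- matrix(0.37, 24, 24)
  for (m in c("gaussian", "perona_malik", "catte")) {
    out <- diffuse(cst, denoise_config(m, iterations = 5))
    expect_equal(out$pixels, cst, tolerance = 1e-12)
  }
  ms <- mean_shift_filter(cst, denoise_config("mean_shift"))
  expect_equal(ms$pixels, cst, tolerance = 1e-12)
  noisy <- matrix(runif(24 * 24), 24, 24)
  for (m in c("gaussian", "perona_malik", "catte")) {
    out <- diffuse(noisy, denoise_config(m, iterations = 10))
    expect_true(all(out$pixels >= 0 & out$pixels <= 1))
  }
})

test_that("linear diffusion conserves the image mean (Neumann boundary)", {
  set.seed(1)
  img <- matrix(runif(32 * 32, 0.2, 0.8), 32, 32)
  out <- diffuse(img, denoise_config("gaussian", iterations = 200, dt = 0.25))
  expect_lt(abs(mean(out$pixels) - mean(img)), 1e-6)
})

test_that("catte keeps a step edge sharper than linear diffusion at equal budgets", {
  img <- matrix(0.3, 32, 32); img[, 17:32] <- 0.7
  it <- 20
  g <- diffuse(img, denoise_config("gaussian", iterations = it))
  ct <- diffuse(img, denoise_config("catte", iterations = it, kappa = 0.1))
  grad_at_edge <- function(p) max(abs(p[, 17] - p[, 16]))
  expect_gt(grad_at_edge(ct$pixels), grad_at_edge(g$pixels))
})

test_that("mean shift keeps a two-level step in place when hr is below the step", {
  img <- matrix(0.2, 20, 20); img[, 11:20] <- 0.8
  out <- mean_shift_filter(img, denoise_config("mean_shift", hs = 2, hr = 0.1,
                                               iterations = 20))
  # each side converges within its own mode: edge column unchanged
  expect_true(all(out$pixels[, 10] < 0.5) && all(out$pixels[, 11] > 0.5))
  # brute-force mode seek on the 1-D profile agrees at a mid-row pixel
  prof <- img[10, ]
  u <- prof[10]
  for (iter in 1:20) {
    wq <- exp(-0.5 * ((1:20 - 10) / 2)^2) * exp(-0.5 * ((prof - u) / 0.1)^2)
    u <- sum(wq * prof) / sum(wq)
  }
  expect_lt(abs(u - 0.2), 0.02)
  expect_lt(abs(out$pixels[10, 10] - u), 0.05)
})

test_that("mean shift suppresses an isolated impulse by >= 90% when hr covers it", {
  img <- matrix(0.2, 31, 31); img[16, 16] <- 0.7
  out <- mean_shift_filter(img, denoise_config("mean_shift", hs = 3, hr = 0.6,
                                               iterations = 20))
  expect_lt((out$pixels[16, 16] - 0.2) / 0.5, 0.1)
})

test_that("psnr matches its closed forms and is symmetric in MSE", {
  a <- matrix(0, 10, 10); b <- matrix(0.1, 10, 10)
  expect_equal(psnr(a, b), 20)           # MSE = 0.01
  expect_identical(psnr(a, a), Inf)      # zero MSE sentinel
  set.seed(2)
  x <- matrix(runif(100), 10, 10); y <- matrix(runif(100), 10, 10)
  expect_equal(psnr(x, y), psnr(y, x))
})

test_that("psnr of uniform noise matches the analytic variance", {
  set.seed(3)
  ref <- matrix(0.5, 256, 256)
  tst <- ref + matrix(runif(256^2, -0.05, 0.05), 256, 256)
  expect_lt(abs(psnr(ref, tst) - 10 * log10(1 / (0.1^2 / 12))), 0.2)
})

test_that("fom closed forms and brute-force oracle agree", {
  e <- matrix(FALSE, 20, 20); e[10, ] <- TRUE
  expect_equal(fom(e, e), 1)
  shifted <- matrix(FALSE, 20, 20); shifted[11, ] <- TRUE
  expect_equal(fom(e, shifted), 1 / (1 + 1 / 9))
  expect_error(fom(matrix(FALSE, 5, 5), e[1:5, 1:5]), "empty")
  set.seed(4)
  for (k in 1:5) {
    tst <- matrix(runif(400) < 0.1, 20, 20)
    if (!any(tst)) next
    expect_close(fom(e, tst), fom_bruteforce(e, tst))
  }
})

test_that("ssim matches closed forms", {
  set.seed(5)
  a <- matrix(runif(64 * 64), 64, 64)
  expect_equal(ssim(a, a), 1)
  # constant vs constant: luminance term only
  c1 <- matrix(0.3, 16, 16); c2 <- matrix(0.6, 16, 16)
  C1 <- 0.01^2
  expect_equal(ssim(c1, c2), (2 * 0.3 * 0.6 + C1) / (0.3^2 + 0.6^2 + C1),
               tolerance = 1e-12)
  # anti-correlated bimodal structure
  b <- matrix(0.05, 32, 32); b[, seq(1, 32, 2)] <- 0.95
  expect_lt(ssim(b, 1 - b), 0)
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 4, 4), window = 7), "window")
})

test_that("segmentation recovers phantom objects and fills holes", {
  ls <- generate_phantom(phantom_spec(n_nodules = 3, n_vessels = 0, noise_sigma = 0,
                                      background_texture = 0, seed = 9))
  mask <- segment_foreground(ls$image)
  truth <- Reduce(`|`, ls$truth_masks)
  expect_gte(sum(mask & truth) / sum(mask | truth), 0.95)
  # all-background phantom: degenerate histogram warns, empty mask
  flat <- generate_phantom(phantom_spec(n_nodules = 0, n_vessels = 0,
                                        noise_sigma = 0, background_texture = 0))
  expect_warning(m0 <- segment_foreground(flat$image), "degenerate")
  expect_false(any(m0))
  # a darker core pixel is filled: mask simply connected
  img <- matrix(0.2, 32, 32)
  img[raster_disk(32, 32, 16, 16, 6)] <- 0.8
  img[16, 16] <- 0.3
  m <- segment_foreground(img)
  expect_true(m[16, 16])
})

test_that("thresholding is monotone: raising the threshold never adds pixels", {
  set.seed(6)
  img <- matrix(runif(32 * 32), 32, 32)
  cfgs <- lapply(c(0.3, 0.5, 0.7), function(t)
    segment_config(threshold = t, fill_holes = FALSE, closing_radius = 0))
  masks <- lapply(cfgs, function(cf) segment_foreground(img, cf))
  expect_true(all(masks[[2]] | !masks[[2]] | TRUE))
  expect_true(!any(masks[[2]] & !masks[[1]]))
  expect_true(!any(masks[[3]] & !masks[[2]]))
})

test_that("denoising benchmark reproduces the qualitative PSNR ordering", {
  psnrs <- denoise_benchmark(1:10)
  m <- colMeans(psnrs)
  expect_gte(m[["catte"]], m[["perona_malik"]])
  expect_gte(m[["perona_malik"]], m[["gaussian"]])
})
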