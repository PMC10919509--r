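test_that("gray histogram normalizes and quantizes as specified", {
  h <- gray_histogram(rep(0.5, 20), L = 8)
  expect_equal(sum(h$H), 1)
  expect_equal(sum(h$H > 0), 1)
  h2 <- gray_histogram(c(rep(0.1, 10), rep(0.9, 10)), L = 2)
  expect_equal(h2$H, c(0.5, 0.5))
  set.seed(1)
  expect_equal(sum(gray_histogram(runif(100), 16)$H), 1)
  expect_error(gray_histogram(numeric(0), 8), "empty")
})

test_that("energy and entropy match closed forms", {
  single <- structure(list(H = c(1, rep(0, 15)), L = 16L), class = "gray_histogram")
  expect_equal(gray_energy(single), 1)
  expect_equal(gray_entropy(single), 0)
  unif <- structure(list(H = rep(1 / 16, 16), L = 16L), class = "gray_histogram")
  expect_equal(gray_energy(unif), 0.0625)
  expect_equal(gray_entropy(unif), 4)          # log2(16) bits
  expect_equal(gray_energy(c(0.5, 0.3, 0.2)), 0.38)
  expect_equal(gray_entropy(c(0.5, 0.5)), 1)
})

test_that("calcification is the masked fraction above threshold", {
  patch <- c(rep(0.5, 9), rep(0.95, 3))    # 3 of 12 above 0.9
  expect_equal(calcification(patch, 0.9), 0.25)
  expect_equal(calcification(rep(0.1, 5), 0.9), 0)
  expect_equal(calcification(rep(0.99, 5), 0.9), 1)
  expect_error(calcification(patch, 1.5), "\\[0,1\\]")
})

test_that("glcm matches enumeration on toy rasters", {
  # vertical 1-px stripes of levels {0, 1}: horizontal pairs always differ
  img <- matrix(rep(c(0.01, 0.99), 8), 4, 4, byrow = TRUE)[, 1:4]
  img <- matrix(rep(c(0.01, 0.99), length.out = 16), 4, 4, byrow = TRUE)
  mask <- matrix(TRUE, 4, 4)
  g <- glcm(img, mask, L = 2, d = 1, theta = 0, symmetric = TRUE)
  expect_equal(g$S[1, 2], 0.5)
  expect_equal(g$S[2, 1], 0.5)
  expect_equal(g$S[1, 1] + g$S[2, 2], 0)
  expect_equal(glcm_contrast(g), 1)
  expect_equal(glcm_homogeneity(g), 0.5)
  # constant region: all mass on the diagonal, contrast 0, homogeneity 1
  gc <- glcm(matrix(0.4, 5, 5), matrix(TRUE, 5, 5), L = 16, d = 1, theta = 0)
  expect_equal(glcm_contrast(gc), 0)
  expect_equal(glcm_homogeneity(gc), 1)
  expect_error(glcm(img, matrix(FALSE, 4, 4), 2, 1, 0), "mask")
})

test_that("glcm equals the brute-force pair counter over a parameter grid", {
  set.seed(7)
  img <- matrix(runif(15 * 15), 15, 15)
  mask <- raster_disk(15, 15, 8, 8, 6)
  for (L in c(4, 16)) for (d in 1:2) for (th in c(0, 45, 90, 135)) for (sym in c(TRUE, FALSE)) {
    g <- glcm(img, mask, L, d, th, sym)
    expect_equal(g$S, glcm_bruteforce(img, mask, L, d, th, sym), tolerance = 1e-12)
  }
})

test_that("checkerboard contrast is exactly 1 at d = 1", {
  img <- outer(1:6, 1:6, function(r, c) (r + c) %% 2) * 0.98 + 0.01
  g <- glcm(img, matrix(TRUE, 6, 6), L = 2, d = 1, theta = 0)
  expect_equal(glcm_contrast(g), 1)
})

test_that("3D shape features match closed forms for voxel and cube", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  f <- shape3d_features(one)
  expect_equal(f[["volume"]], 1)
  expect_equal(f[["surface_area"]], 6)
  expect_equal(f[["equivalent_diameter"]], (6 / pi)^(1 / 3), tolerance = 1e-12)
  expect_equal(f[["sphericity"]], pi^(1 / 3) * 6^(2 / 3) / 6, tolerance = 1e-3)
  cube <- array(TRUE, c(10, 10, 10))
  fc <- shape3d_features(cube)
  expect_equal(fc[["volume"]], 1000)
  expect_equal(fc[["surface_area"]], 600)
  expect_equal(fc[["compactness"]], 600^3 / (36 * pi * 1e6), tolerance = 1e-12)
})

test_that("a digital ball is more spherical than a spiculated blob of similar volume", {
  dims <- c(24, 24, 24)
  grid <- expand.grid(x = 1:24, y = 1:24, z = 1:24)
  rad <- sqrt((grid$x - 12.5)^2 + (grid$y - 12.5)^2 + (grid$z - 12.5)^2)
  ball <- array(rad <= 8, dims)
  theta <- atan2(grid$y - 12.5, grid$x - 12.5)
  spik <- array(rad <= 8 * (1 + 0.25 * sin(6 * theta)), dims)
  expect_gt(shape3d_features(ball)[["sphericity"]],
            shape3d_features(spik)[["sphericity"]])
})

test_that("the default feature vector has exactly 17 named entries", {
  ls <- generate_phantom(phantom_spec(seed = 13))
  img <- ls$image
  cands <- label_candidates(segment_foreground(img), img, 10)
  fv <- extract_features(cands[[1]], img)
  expect_length(fv, 17)
  expect_identical(names(fv), feature_names())
  X <- extract_feature_matrix(cands, img)
  expect_equal(dim(X), c(length(cands), 17L))
  expect_true(all(is.finite(X)))
})

test_that("feature vectors are translation invariant and separate shape from gray", {
  img <- matrix(0.2, 80, 80)
  m1 <- raster_disk(80, 80, 20, 20, 8)
  m2 <- raster_disk(80, 80, 55, 50, 8)
  img[m1] <- 0.8; img[m2] <- 0.8
  cands <- label_candidates(m1 | m2, img, 10)
  f1 <- extract_features(cands[[1]], img)
  f2 <- extract_features(cands[[2]], img)
  expect_equal(f1, f2, tolerance = 1e-9)
  # disk vs bar with identical pixel multisets: gray block equal, shape differs
  img2 <- matrix(0.2, 80, 80)
  bar <- raster_bar(80, 80, 60, 10, 4, 49)   # area 196
  disk <- raster_disk(80, 80, 25, 40, 7.9)   # area ~196
  img2[bar] <- 0.8; img2[disk] <- 0.8
  cands2 <- label_candidates(disk | bar, img2, 10)
  fd <- extract_features(cands2[[1]], img2)
  fb <- extract_features(cands2[[2]], img2)
  gray <- c("mean", "variance", "energy", "entropy", "calcification")
  expect_equal(fd[gray], fb[gray], tolerance = 0.05)
  expect_gt(abs(fd[["elongation"]] - fb[["elongation"]]), 3)
})

test_that("energy/entropy are inversely ordered under majorization", {
  # (0.7, 0.2, 0.1) majorizes (0.5, 0.3, 0.2)
  a <- c(0.7, 0.2, 0.1); b <- c(0.5, 0.3, 0.2)
  expect_gt(gray_energy(a), gray_energy(b))
  expect_lt(gray_entropy(a), gray_entropy(b))
})
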