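test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec(width = 16), "32")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(nodule_radius_range = c(40, 80)), "fit")
  expect_s3_class(phantom_spec(), "phantom_spec")
})

test_that("degenerate phantom is a uniform background with empty truth", {
  ls <- generate_phantom(phantom_spec(n_nodules = 0, n_vessels = 0,
                                      noise_sigma = 0, background_texture = 0))
  expect_equal(length(ls$truth_masks), 0)
  expect_true(all(ls$image$pixels == 0.2))
})

test_that("phantom generation is bit-identical under a fixed seed and leaves the RNG alone", {
  set.seed(123); before <- runif(1)
  sp <- phantom_spec(seed = 7)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth_masks, b$truth_masks)
  expect_identical(a$truth_labels, b$truth_labels)
  set.seed(123); expect_identical(runif(1), before)
})

test_that("smooth nodule masks are compact disks; labels follow spiculation", {
  ls <- generate_phantom(phantom_spec(n_nodules = 3, n_vessels = 0,
                                      spiculation = FALSE, noise_sigma = 0, seed = 3))
  expect_length(ls$truth_masks, 3)
  expect_true(all(ls$truth_labels == "benign"))
  for (m in ls$truth_masks) {
    d <- rule_descriptors(m, ls$image$pixels)
    expect_gte(d[["circularity"]], 0.7)
    # connectivity: one component
    expect_equal(max(label_components(m)), 1)
  }
  mal <- generate_phantom(phantom_spec(n_nodules = 2, n_vessels = 0,
                                       spiculation = TRUE, seed = 4))
  expect_true(all(mal$truth_labels == "malignant"))
})

test_that("rasterized disk areas match the analytic area within the discretization bound", {
  # |A - pi r^2| <= 4 pi r for a digital disk; smooth phantom nodules are
  # exactly such disks, so check the raster primitive across radii and centres
  for (r in c(4, 5.5, 7, 9, 11)) {
    for (off in list(c(0, 0), c(0.3, 0.7), c(0.5, 0.5))) {
      m <- raster_disk(40, 40, 20 + off[1], 20 + off[2], r)
      expect_lt(abs(sum(m) - pi * r^2), 4 * pi * r)
    }
  }
})

test_that("vessel distractors are elongated (>= 3) and nodules are not (< 2)", {
  for (seed in 1:5) {
    ls <- generate_phantom(phantom_spec(n_nodules = 2, n_vessels = 3,
                                        spiculation = FALSE, noise_sigma = 0,
                                        seed = seed))
    for (i in seq_along(ls$truth_masks)) {
      e <- rule_descriptors(ls$truth_masks[[i]], ls$image$pixels)[["elongation"]]
      if (ls$truth_labels[i] == "non-nodule") expect_gte(e, 3) else expect_lt(e, 2)
    }
  }
})

test_that("noise-free untextured phantom attains only the stated plateau levels", {
  ls <- generate_phantom(phantom_spec(n_nodules = 2, n_vessels = 0,
                                      noise_sigma = 0, background_texture = 0,
                                      seed = 2))
  px <- ls$image$pixels
  expect_true(all(px >= 0.2 - 1e-9 & px <= 0.8 + 1e-9))
  # interior (2 px inside the truth boundary, past the 1-px feather band)
  # sits exactly at the nodule plateau; far background exactly at 0.2
  occ <- Reduce(`|`, ls$truth_masks)
  sq <- expand.grid(dr = -2:2, dc = -2:2)  # the feather kernel's support
  interior <- !nodulecad:::dilate_mask(!occ, sq)
  expect_true(any(interior))
  expect_true(all(abs(px[interior] - 0.8) < 1e-9))
  far <- !nodulecad:::dilate_mask(occ, sq)
  expect_true(all(abs(px[far] - 0.2) < 1e-9))
})

test_that("generate_feature_table builds reproducible Gaussian mixtures and rejects bad input", {
  cp <- list(a = list(mean = c(0, 0), cov = diag(2)),
             b = list(mean = c(6, 0), cov = diag(2)))
  d1 <- generate_feature_table(200, cp, seed = 5)
  d2 <- generate_feature_table(200, cp, seed = 5)
  expect_identical(d1$X, d2$X)
  expect_equal(table(d1$y)[["a"]], 200)
  # 6-sigma separated classes: a linear rule at the midpoint is near-perfect
  pred <- ifelse(d1$X[, 1] > 3, "b", "a")
  expect_gte(mean(pred == d1$y), 0.99)
  bad <- list(a = list(mean = c(0, 0), cov = matrix(c(1, 2, 2, 1), 2)))
  expect_error(generate_feature_table(10, bad, seed = 1), "positive semi-definite")
})

test_that("indistinguishable classes yield chance-level accuracy", {
  cp <- list(a = list(mean = c(0, 0), cov = diag(2)),
             b = list(mean = c(0, 0), cov = diag(2)))
  d <- generate_feature_table(300, cp, seed = 8)
  tr <- stratified_split(d$y, 0.5, seed = 1)
  m <- fit_baseline("naive_bayes", d$X[tr, ], d$y[tr])
  acc <- mean(predict(m, d$X[!tr, ]) == d$y[!tr])
  expect_lt(abs(acc - 0.5), 0.12)  # ~3 binomial sd at n = 300
})

test_that("labelled slices round-trip to disk as PNG + CSV manifest", {
  dir <- withr::local_tempdir()
  ls <- generate_phantom(phantom_spec(n_nodules = 2, n_vessels = 1, seed = 6))
  manifest <- write_labelled_slice(ls, dir, "s1")
  expect_equal(nrow(manifest), 3)
  expect_true(file.exists(file.path(dir, "s1.png")))
  back <- read_image_slice(file.path(dir, "s1.png"))
  expect_equal(dim(back$pixels), dim(ls$image$pixels))
  # 8-bit PNG quantization error is bounded by half a gray step
  rng <- diff(range(ls$image$pixels))
  expect_lt(max(abs(back$pixels * rng + min(ls$image$pixels) - ls$image$pixels)),
            1 / 255)
  # PGM round-trip is 16-bit
  pgm <- file.path(dir, "s1.pgm")
  write_image_slice(ls$image, pgm)
  back2 <- read_image_slice(pgm)
  expect_lt(max(abs(back2$pixels * rng + min(ls$image$pixels) - ls$image$pixels)),
            1e-4)
})
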