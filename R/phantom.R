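#' Specification for a synthetic phantom CT slice
#'
#' The phantom emulates the statistical structure the downstream pipeline
#' assumes: bright, roughly circular nodules (smooth margins for benign-like,
#' radially perturbed margins for malignant-like) against a darker background,
#' elongated vessel-like distractors, and additive Gaussian noise.
#'
#' @param width,height image size in pixels (>= 32).
#' @param n_nodules number of nodules to embed.
#' @param n_vessels number of elongated vessel-like distractors.
#' @param nodule_radius_range two radii (pixels) bounding nodule size.
#' @param nodule_intensity gray level of nodules/vessels, in [0,1].
#' @param background_intensity background gray level, in [0,1].
#' @param noise_sigma standard deviation of additive Gaussian noise (gray units).
#' @param background_texture standard deviation of the parenchyma speckle
#'   field: a spatially rough texture applied to the background only (solid
#'   nodules replace parenchyma, so their cores stay homogeneous). This is
#'   what makes non-nodule patches textured relative to nodules.
#' @param spiculation if TRUE nodules get irregular, spiculated margins
#'   (malignant-like); if FALSE smooth disks (benign-like).
#' @param n_vessel_xsections number of vessel cross-sections: small bright
#'   disks mimicking a vessel imaged end-on, the classic compact non-nodule
#'   false positive whose shape overlaps small true nodules.
#' @param xsection_radius_range radii (pixels) of the vessel cross-sections.
#' @param seed RNG seed; the phantom is bit-reproducible from it.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 128, height = 128, n_nodules = 3, n_vessels = 5,
                         nodule_radius_range = c(5, 11), nodule_intensity = 0.8,
                         background_intensity = 0.2, noise_sigma = 0.05,
                         background_texture = 0.08,
                         spiculation = FALSE, n_vessel_xsections = 0,
                         xsection_radius_range = c(2.5, 5), seed = 1) {
  check_that(width >= 32 && height >= 32, "width and height must be >= 32")
  check_that(length(nodule_radius_range) == 2 &&
               nodule_radius_range[1] <= nodule_radius_range[2] &&
               nodule_radius_range[1] >= 1, "invalid nodule_radius_range")
  check_that(2 * nodule_radius_range[2] + 4 < min(width, height),
             "radii do not fit inside the image")
  check_that(nodule_intensity >= 0 && nodule_intensity <= 1 &&
               background_intensity >= 0 && background_intensity <= 1,
             "intensities must lie in [0,1]")
  check_that(noise_sigma >= 0, "noise_sigma must be >= 0")
  check_that(background_texture >= 0, "background_texture must be >= 0")
  check_that(n_nodules >= 0 && n_vessels >= 0 && n_vessel_xsections >= 0,
             "counts must be >= 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_nodules = as.integer(n_nodules), n_vessels = as.integer(n_vessels),
                 nodule_radius_range = nodule_radius_range,
                 nodule_intensity = nodule_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma,
                 background_texture = background_texture,
                 spiculation = isTRUE(spiculation),
                 n_vessel_xsections = as.integer(n_vessel_xsections),
                 xsection_radius_range = xsection_radius_range,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Rasterize one nodule: hard truth mask plus a spiculation radius profile.
# Spiculated margins follow r(theta) = r0 * (1 + a * sum_h sin(k_h theta + phi_h))
# with a in [0.1, 0.3] and k in {5..9} -- low sphericity, as malignant nodules show.
rasterize_nodule <- function(h, w, cy, cx, r0, spiculated) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- rows - cy; dx <- cols - cx
  rad <- sqrt(dy^2 + dx^2)
  if (!spiculated) return(rad <= r0)
  a <- stats::runif(1, 0.1, 0.3)
  k <- sample(5:9, 2, replace = TRUE)
  phi <- stats::runif(2, 0, 2 * pi)
  theta <- atan2(dy, dx)
  rb <- r0 * (1 + (a / 2) * (sin(k[1] * theta + phi[1]) + sin(k[2] * theta + phi[2])))
  rad <= rb
}

# Rotated-rectangle streak: length/width >= 3 by construction, so its
# elongation violates the nodule shape rules the cropper applies. Returns the
# mask plus the along-axis coordinate, used to modulate vessel intensity
# (vessels show caliber/partial-volume texture that nodule cores do not).
rasterize_vessel <- function(h, w, cy, cx, len, wid, angle) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- rows - cy; dx <- cols - cx
  u <- dx * cos(angle) + dy * sin(angle)     # along the vessel
  v <- -dx * sin(angle) + dy * cos(angle)    # across
  list(mask = abs(u) <= len / 2 & abs(v) <= wid / 2, u = u)
}

#' Generate a labelled synthetic phantom slice
#'
#' Nodules are hard disks (or spiculated disks) with 1-pixel Gaussian edge
#' feathering in the rendered image (mimicking partial-volume blur); truth
#' masks stay hard. Vessels share the nodule intensity so that thresholding
#' alone cannot reject them. Objects are placed without overlap, with bounded
#' retries.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `labelled_slice`: list with `image`
#'   (an [image_slice()]), `truth_masks` (list of logical matrices) and
#'   `truth_labels` (character, in benign / malignant / non-nodule).
#' @export
generate_phantom <- function(spec) {
  check_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    canvas <- matrix(spec$background_intensity, h, w)
    occupied <- matrix(FALSE, h, w)
    amp <- matrix(0, h, w)   # per-pixel foreground amplitude (texture lives here)
    masks <- list(); labels <- character(0)

    place <- function(make_mask, margin) {
      for (try in 1:500) {
        cy <- stats::runif(1, margin + 1, h - margin)
        cx <- stats::runif(1, margin + 1, w - margin)
        m <- make_mask(cy, cx)
        if (!any(m) || any(m & occupied)) next
        # 5-pixel clearance: distinct objects must stay distinct components
        # even after edge feathering and a rolling-ball closing of radius 2
        if (any(dilate_mask(m, disk_offsets(5)) & occupied)) next
        return(m)
      }
      stopf("placement error: could not place object without overlap after 500 retries")
    }

    for (i in seq_len(spec$n_nodules)) {
      r0 <- stats::runif(1, spec$nodule_radius_range[1], spec$nodule_radius_range[2])
      m <- place(function(cy, cx) rasterize_nodule(h, w, cy, cx, r0, spec$spiculation),
                 margin = ceiling(r0 * 1.4) + 2)
      occupied <- occupied | m
      amp[m] <- 1
      masks[[length(masks) + 1L]] <- m
      labels <- c(labels, if (spec$spiculation) "malignant" else "benign")
    }
    for (i in seq_len(spec$n_vessels)) {
      len <- stats::runif(1, 18, 36); wid <- stats::runif(1, 2, 3.2)
      ang <- stats::runif(1, 0, pi)
      last_u <- NULL
      m <- place(function(cy, cx) {
        rv <- rasterize_vessel(h, w, cy, cx, len, wid, ang)
        last_u <<- rv$u
        rv$mask
      }, margin = ceiling(len / 2) + 2)
      occupied <- occupied | m
      # caliber texture: intensity undulates along the vessel axis
      phi <- stats::runif(1, 0, 2 * pi)
      amp[m] <- 0.85 + 0.15 * sin(2 * pi * last_u[m] / 6 + phi)
      masks[[length(masks) + 1L]] <- m
      labels <- c(labels, "non-nodule")
    }
    for (i in seq_len(spec$n_vessel_xsections %||% 0L)) {
      r0 <- stats::runif(1, spec$xsection_radius_range[1], spec$xsection_radius_range[2])
      m <- place(function(cy, cx) rasterize_nodule(h, w, cy, cx, r0, FALSE),
                 margin = ceiling(r0) + 2)
      occupied <- occupied | m
      amp[m] <- 1
      masks[[length(masks) + 1L]] <- m
      labels <- c(labels, "non-nodule")
    }

    fg <- spec$nodule_intensity - spec$background_intensity
    # 1-pixel partial-volume feather: sigma 0.5 gives a ~1 px transition band
    feathered <- gauss_blur(amp, 0.5)
    if (length(masks)) {
      canvas <- canvas + fg * feathered
    }
    if ((spec$background_texture %||% 0) > 0) {
      tex <- gauss_blur(matrix(stats::rnorm(h * w), h, w), 0.5)
      tex <- tex / stats::sd(tex) * spec$background_texture
      canvas <- canvas + tex * (1 - clamp01(feathered))
    }
    if (spec$noise_sigma > 0) {
      canvas <- canvas + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
    }
    structure(list(image = image_slice(clamp01(canvas),
                                       source_id = sprintf("phantom(seed=%d)", spec$seed)),
                   truth_masks = masks, truth_labels = labels, spec = spec),
              class = "labelled_slice")
  })
}

#' @export
print.labelled_slice <- function(x, ...) {
  cat(sprintf("<labelled_slice %dx%d, %d objects (%s)>\n",
              nrow(x$image$pixels), ncol(x$image$pixels), length(x$truth_masks),
              paste(table(x$truth_labels), names(table(x$truth_labels)), collapse = ", ")))
  invisible(x)
}

#' Write a labelled slice to disk (PNG image + mask PNGs + CSV manifest)
#'
#' @param ls a `labelled_slice`.
#' @param dir output directory (created if needed).
#' @param slice_id identifier used in file names and the manifest.
#' @return invisibly, the manifest data frame.
#' @export
write_labelled_slice <- function(ls, dir, slice_id = "slice") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image_slice(ls$image, file.path(dir, paste0(slice_id, ".png")))
  rows <- lapply(seq_along(ls$truth_masks), function(i) {
    m <- ls$truth_masks[[i]]
    write_image_slice(m * 1.0, file.path(dir, sprintf("%s_mask%02d.png", slice_id, i)))
    idx <- which(m, arr.ind = TRUE)
    data.frame(slice_id = slice_id, region_id = i, label = ls$truth_labels[i],
               row0 = min(idx[, 1]), col0 = min(idx[, 2]),
               row1 = max(idx[, 1]) + 1L, col1 = max(idx[, 2]) + 1L)
  })
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(manifest)) {
    manifest <- data.frame(slice_id = character(0), region_id = integer(0),
                           label = character(0), row0 = integer(0), col0 = integer(0),
                           row1 = integer(0), col1 = integer(0))
  }
  utils::write.csv(manifest, file.path(dir, paste0(slice_id, "_labels.csv")),
                   row.names = FALSE)
  invisible(manifest)
}

#' Generate a labelled Gaussian-mixture feature table
#'
#' Supports classifier-only tests with known class structure: each class is a
#' multivariate Gaussian with the supplied mean and covariance.
#'
#' @param n_per_class samples per class (scalar or one per class).
#' @param class_params named list; each element a list with `mean` (numeric)
#'   and `cov` (positive semi-definite matrix, or a scalar for isotropic).
#' @param seed RNG seed.
#' @return list with `X` (matrix) and `y` (factor of class names).
#' @export
generate_feature_table <- function(n_per_class, class_params, seed = 1) {
  check_that(length(class_params) >= 1 && !is.null(names(class_params)),
             "class_params must be a named list")
  p <- length(class_params[[1]]$mean)
  n_per_class <- rep_len(n_per_class, length(class_params))
  with_seed(seed, {
    blocks <- lapply(seq_along(class_params), function(i) {
      cp <- class_params[[i]]
      check_that(length(cp$mean) == p, "all class means must have equal length")
      S <- cp$cov
      if (is.null(S)) S <- diag(p)
      if (length(S) == 1) S <- diag(as.numeric(S), p)
      ev <- eigen(S, symmetric = TRUE)
      check_that(all(ev$values > -1e-8 * max(abs(ev$values), 1)),
                 "covariance for class '%s' is not positive semi-definite",
                 names(class_params)[i])
      A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
      n <- n_per_class[i]
      Z <- matrix(stats::rnorm(n * p), n, p)
      sweep(Z %*% t(A), 2, cp$mean, "+")
    })
    X <- do.call(rbind, blocks)
    colnames(X) <- paste0("f", seq_len(p))
    y <- factor(rep(names(class_params), n_per_class), levels = names(class_params))
    list(X = X, y = y)
  })
}
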