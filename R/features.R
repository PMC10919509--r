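#' Feature extraction configuration
#'
#' The default roster spans three feature categories and yields exactly 17
#' values: 5 gray (mean, variance, energy, entropy, calcification), 6 shape
#' (area, perimeter, circularity, flatness, elongation, rectangularity), 4
#' texture (GLCM contrast and homogeneity at offsets d = 1 and d = 2, each
#' averaged over the four standard angles), and 2 gradient (mean and sd of
#' the Sobel magnitude under the mask).
#'
#' @param L gray-level quantization for histogram and GLCM.
#' @param d GLCM pixel offsets (vector).
#' @param angles GLCM angles in degrees, from {0, 45, 90, 135}.
#' @param calcification_T gray threshold above which a pixel counts as
#'   calcified (normalized scale).
#' @param entropy_base logarithm base for entropy (2 = bits).
#' @param symmetric symmetrize the GLCM by adding its transpose.
#' @export
feature_config <- function(L = 16, d = c(1, 2), angles = c(0, 45, 90, 135),
                           calcification_T = 0.9, entropy_base = 2,
                           symmetric = TRUE) {
  check_that(L >= 2, "L must be >= 2")
  check_that(all(d >= 1), "offsets must be >= 1")
  check_that(all(angles %in% c(0, 45, 90, 135)), "angles must be in {0,45,90,135}")
  check_that(calcification_T >= 0 && calcification_T <= 1,
             "calcification_T must be in [0,1]")
  structure(list(L = as.integer(L), d = as.integer(d), angles = angles,
                 calcification_T = calcification_T, entropy_base = entropy_base,
                 symmetric = isTRUE(symmetric)), class = "feature_config")
}

quantize_levels <- function(v, L) pmin(floor(v * L), L - 1L)

#' Normalized gray-level histogram of masked pixels
#'
#' Uniform quantization of [0,1] into `L` bins.
#'
#' @param values numeric vector of masked intensities in [0,1].
#' @param L number of levels (>= 2).
#' @return a `gray_histogram`: list with `H` (probabilities, length L) and `L`.
#' @export
gray_histogram <- function(values, L = 16) {
  check_that(length(values) >= 1, "empty mask: no pixels to histogram")
  check_that(L >= 2, "L must be >= 2")
  q <- quantize_levels(values, L)
  H <- tabulate(q + 1L, L)
  structure(list(H = H / sum(H), L = as.integer(L)), class = "gray_histogram")
}

#' Histogram energy: sum of squared bin probabilities
#'
#' `Ex = sum_k H(k)^2`; 1 for a single-level region, 1/L for a uniform one.
#'
#' @param h a [gray_histogram()] or bare probability vector.
#' @export
gray_energy <- function(h) {
  H <- if (inherits(h, "gray_histogram")) h$H else h
  sum(H^2)
}

#' Histogram entropy
#'
#' `Hx = -sum_k H(k) log H(k)` with the 0 log 0 = 0 convention; base 2 by
#' default so the value is in bits.
#'
#' @inheritParams gray_energy
#' @param base logarithm base.
#' @export
gray_entropy <- function(h, base = 2) {
  H <- if (inherits(h, "gray_histogram")) h$H else h
  H <- H[H > 0]
  -sum(H * log(H, base = base))
}

#' Degree of calcification
#'
#' Fraction of masked pixels whose intensity exceeds the threshold `T`.
#'
#' @param values masked intensities in [0,1].
#' @param T gray threshold in [0,1].
#' @export
calcification <- function(values, T = 0.9) {
  check_that(length(values) >= 1, "empty mask")
  check_that(T >= 0 && T <= 1, "T must be in [0,1]")
  mean(values > T)
}

glcm_offset <- function(d, theta) {
  switch(as.character(theta),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d),
         stopf("theta must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix under a mask
#'
#' Counts quantized gray-level pairs (i, j) at offset (d, theta); pairs whose
#' second pixel leaves the mask are skipped. Optionally symmetrized by adding
#' the transpose; always normalized to sum 1.
#'
#' @param pixels image matrix in [0,1].
#' @param mask logical matrix (the region of interest).
#' @param L quantization levels.
#' @param d pixel distance of the offset.
#' @param theta angle in degrees: 0, 45, 90 or 135.
#' @param symmetric add the transpose before normalizing.
#' @return a `glcm`: list with `S` (L x L probabilities), `d`, `theta`,
#'   `symmetric`.
#' @export
glcm <- function(pixels, mask, L = 16, d = 1, theta = 0, symmetric = TRUE) {
  check_that(all(dim(pixels) == dim(mask)), "pixels/mask shape mismatch")
  off <- glcm_offset(as.integer(d), theta)
  q <- matrix(quantize_levels(pixels, L), nrow(pixels), ncol(pixels))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  r2 <- idx[, 1] + off[1]; c2 <- idx[, 2] + off[2]
  ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
  if (any(ok)) ok[ok] <- mask[cbind(r2[ok], c2[ok])]
  check_that(any(ok), "mask admits no pixel pair at this offset")
  i <- q[idx[ok, , drop = FALSE]]
  j <- q[cbind(r2[ok], c2[ok])]
  S <- matrix(0, L, L)
  tab <- table(factor(i, levels = 0:(L - 1)), factor(j, levels = 0:(L - 1)))
  S <- matrix(as.numeric(tab), L, L)
  if (symmetric) S <- S + t(S)
  structure(list(S = S / sum(S), d = as.integer(d), theta = theta,
                 symmetric = isTRUE(symmetric), L = as.integer(L)),
            class = "glcm")
}

#' GLCM contrast
#'
#' `SLx = sum_ij (i - j)^2 S(i, j)`: large for regions whose co-occurring
#' gray levels differ (fine or noisy texture), 0 for constant regions.
#'
#' @param g a [glcm()].
#' @export
glcm_contrast <- function(g) {
  L <- nrow(g$S)
  ij <- outer(0:(L - 1), 0:(L - 1), "-")
  sum(ij^2 * g$S)
}

#' GLCM homogeneity (uniformity)
#'
#' `SPx = sum_ij S(i, j) / (1 + (i - j)^2)`: 1 for constant regions, lower
#' for contrasty texture. Always in (0, 1].
#'
#' @param g a [glcm()].
#' @export
glcm_homogeneity <- function(g) {
  L <- nrow(g$S)
  ij <- outer(0:(L - 1), 0:(L - 1), "-")
  sum(g$S / (1 + ij^2))
}

glcm_texture_block <- function(pixels, mask, cfg) {
  out <- numeric(0)
  for (d in cfg$d) {
    co <- 0; ho <- 0; nang <- 0
    for (th in cfg$angles) {
      g <- tryCatch(glcm(pixels, mask, cfg$L, d, th, cfg$symmetric),
                    error = function(e) NULL)
      if (is.null(g)) next
      co <- co + glcm_contrast(g); ho <- ho + glcm_homogeneity(g); nang <- nang + 1
    }
    if (nang == 0) { co <- 0; ho <- 1 } else { co <- co / nang; ho <- ho / nang }
    out <- c(out, stats::setNames(c(co, ho),
                                  paste0(c("contrast_d", "homogeneity_d"), d)))
  }
  out
}

#' 3D shape features of a voxel mask
#'
#' Volume by voxel counting, surface area by exposed-face counting,
#' equivalent diameter `(6V/pi)^(1/3)`, sphericity
#' `pi^(1/3) (6V)^(2/3) / A`, compactness `A^3 / (36 pi V^2)`, and a
#' curvature proxy (sd of boundary-voxel distance to the centroid, normalized
#' by its mean). A single voxel is a valid degenerate input (sphericity
#' about 0.806 under face counting).
#'
#' @param stack_mask 3D logical array.
#' @param spacing voxel spacing, length 3.
#' @return named numeric vector of the six features.
#' @export
shape3d_features <- function(stack_mask, spacing = c(1, 1, 1)) {
  check_that(length(dim(stack_mask)) == 3, "stack_mask must be a 3D array")
  idx <- which(stack_mask, arr.ind = TRUE)
  check_that(nrow(idx) >= 1, "empty 3D mask")
  vox <- prod(spacing)
  V <- nrow(idx) * vox
  dims <- dim(stack_mask)
  # exposed faces per axis
  A <- 0
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3], spacing[1] * spacing[2])
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- idx
      nb[, ax] <- nb[, ax] + s
      outside <- nb[, ax] < 1 | nb[, ax] > dims[ax]
      inside <- !outside
      exposed <- outside
      if (any(inside)) exposed[inside] <- !stack_mask[nb[inside, , drop = FALSE]]
      A <- A + sum(exposed) * face_area[ax]
    }
  }
  # boundary voxels: at least one exposed face
  ctr <- colMeans(idx)
  bnd <- rep(FALSE, nrow(idx))
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- idx
      nb[, ax] <- nb[, ax] + s
      outside <- nb[, ax] < 1 | nb[, ax] > dims[ax]
      ex <- outside
      if (any(!outside)) ex[!outside] <- !stack_mask[nb[!outside, , drop = FALSE]]
      bnd <- bnd | ex
    }
  }
  bd <- sqrt(colSums((t(idx[bnd, , drop = FALSE]) - ctr)^2 * spacing^2))
  curv <- if (length(bd) > 1 && mean(bd) > 0) stats::sd(bd) / mean(bd) else 0
  c(equivalent_diameter = (6 * V / pi)^(1 / 3),
    surface_area = A,
    volume = V,
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    compactness = A^3 / (36 * pi * V^2),
    curvature_proxy = curv)
}

#' Names of the default 17-feature vector, in order
#' @param cfg a [feature_config()].
#' @export
feature_names <- function(cfg = feature_config()) {
  c("mean", "variance", "energy", "entropy", "calcification",
    "area", "perimeter", "circularity", "flatness", "elongation", "rectangularity",
    as.vector(vapply(cfg$d, function(d) paste0(c("contrast_d", "homogeneity_d"), d),
                     character(2))),
    "gradient_mean", "gradient_sd")
}

#' Extract the hybrid feature vector of a candidate
#'
#' Assembles gray, shape, texture and gradient features in a fixed order;
#' with the default configuration the vector has exactly 17 entries.
#'
#' @param cand a `nodule_candidate` from [label_candidates()].
#' @param img image slice or matrix.
#' @param cfg a [feature_config()].
#' @param grad optional precomputed Sobel magnitude of `img` (saves repeated
#'   work when featurizing many candidates of one slice).
#' @return named numeric vector.
#' @export
extract_features <- function(cand, img, cfg = feature_config(), grad = NULL) {
  p <- as_pixel_matrix(img)
  m <- cand$region_mask
  vals <- p[m]
  h <- gray_histogram(vals, cfg$L)
  if (is.null(grad)) grad <- sobel_magnitude(p)
  gv <- grad[m]
  out <- c(mean = mean(vals),
           variance = if (length(vals) > 1) stats::var(vals) else 0,
           energy = gray_energy(h),
           entropy = gray_entropy(h, cfg$entropy_base),
           calcification = calcification(vals, cfg$calcification_T),
           area = cand$area,
           perimeter = trace_perimeter(m),
           circularity = unname(cand$descriptors["circularity"]),
           flatness = unname(cand$descriptors["flatness"]),
           elongation = unname(cand$descriptors["elongation"]),
           rectangularity = unname(cand$descriptors["rectangularity"]),
           glcm_texture_block(p, m, cfg),
           gradient_mean = mean(gv),
           gradient_sd = if (length(gv) > 1) stats::sd(gv) else 0)
  check_that(all(is.finite(out)), "non-finite feature value")
  out[feature_names(cfg)]
}

#' Featurize a whole candidate list into a matrix
#'
#' @param cands candidate list.
#' @param img image slice or matrix.
#' @param cfg a [feature_config()].
#' @return numeric matrix, one row per candidate, named columns.
#' @export
extract_feature_matrix <- function(cands, img, cfg = feature_config()) {
  nms <- feature_names(cfg)
  if (!length(cands)) {
    return(matrix(numeric(0), 0, length(nms), dimnames = list(NULL, nms)))
  }
  grad <- sobel_magnitude(as_pixel_matrix(img))
  t(vapply(cands, extract_features, numeric(length(nms)),
           img = img, cfg = cfg, grad = grad))
}
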