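#' Otsu's threshold on a 256-bin histogram
#'
#' Maximizes between-class variance of the two-level split. Used both for
#' foreground segmentation ("adaptive threshold") and for default edge-map
#' binarization.
#'
#' @param v numeric values (any array).
#' @param bins histogram bin count.
#' @return the threshold (a value strictly between the two classes), or `NA`
#'   if the histogram is degenerate (a single occupied level).
#' @export
otsu_threshold <- function(v, bins = 256) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(NA_real_)
  edges <- seq(lo, hi, length.out = bins + 1)
  h <- tabulate(pmin(findInterval(v, edges, all.inside = TRUE), bins), bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[bins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)
  edges[k + 1]
}

# Offsets of a disk structuring element of the given radius.
disk_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
}

dilate_mask <- function(mask, offsets) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  m <- mask
  storage.mode(m) <- "logical"
  for (i in seq_len(nrow(offsets))) {
    out <- out | shift_matrix_logical(m, offsets$dr[i], offsets$dc[i])
  }
  out
}

erode_mask <- function(mask, offsets) {
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offsets))) {
    out <- out & shift_matrix_logical(mask, offsets$dr[i], offsets$dc[i], pad = FALSE)
  }
  out
}

# Logical shift with constant padding (pad = value used outside the frame).
shift_matrix_logical <- function(m, dr, dc, pad = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(pad, nr, nc)
  ri <- seq_len(nr) + dr
  ci <- seq_len(nc) + dc
  rok <- ri >= 1L & ri <= nr
  cok <- ci >= 1L & ci <= nc
  out[rok, cok] <- m[ri[rok], ci[cok], drop = FALSE]
  out
}

#' Morphological closing with a disk ("rolling ball") structuring element
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels.
#' @return closed logical matrix.
#' @export
close_mask <- function(mask, radius = 2) {
  if (radius <= 0) return(mask)
  offs <- disk_offsets(radius)
  erode_mask(dilate_mask(mask, offs), offs)
}

#' Fill holes (background components not connected to the border)
#'
#' Background connectivity is 4-connected, the standard dual of 8-connected
#' foreground.
#'
#' @param mask logical matrix.
#' @return logical matrix with interior cavities filled.
#' @export
fill_holes <- function(mask) {
  bg <- !mask
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  reach[1, ] <- bg[1, ]; reach[nrow(mask), ] <- bg[nrow(mask), ]
  reach[, 1] <- bg[, 1]; reach[, ncol(mask)] <- bg[, ncol(mask)]
  repeat {
    grown <- (reach |
                shift_matrix_logical(reach, 1L, 0L) |
                shift_matrix_logical(reach, -1L, 0L) |
                shift_matrix_logical(reach, 0L, 1L) |
                shift_matrix_logical(reach, 0L, -1L)) & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | (bg & !reach)
}

#' Segmentation configuration
#'
#' @param threshold fixed threshold in [0,1], or NULL for Otsu's adaptive
#'   threshold on the 256-bin global histogram.
#' @param fill_holes fill internal cavities after thresholding.
#' @param closing_radius radius of the rolling-ball (disk) closing; 0 disables.
#' @export
segment_config <- function(threshold = NULL, fill_holes = TRUE, closing_radius = 2) {
  check_that(is.null(threshold) || (threshold >= 0 && threshold <= 1),
             "threshold must be in [0,1] or NULL")
  check_that(closing_radius >= 0, "closing_radius must be >= 0")
  structure(list(threshold = threshold, fill_holes = isTRUE(fill_holes),
                 closing_radius = closing_radius), class = "segment_config")
}

#' Adaptive foreground segmentation
#'
#' Threshold (Otsu unless fixed), then cavity filling, then rolling-ball
#' closing. A degenerate single-level histogram yields an empty mask with a
#' warning rather than an error.
#'
#' @param img image slice or matrix in [0,1].
#' @param cfg a [segment_config()].
#' @return logical foreground mask.
#' @export
segment_foreground <- function(img, cfg = segment_config()) {
  p <- as_pixel_matrix(img)
  t <- cfg$threshold %||% otsu_threshold(p)
  if (is.na(t)) {
    warning("degenerate histogram (single gray level); returning empty mask")
    return(matrix(FALSE, nrow(p), ncol(p)))
  }
  mask <- p > t
  if (cfg$fill_holes) mask <- fill_holes(mask)
  if (cfg$closing_radius > 0) mask <- close_mask(mask, cfg$closing_radius)
  mask
}
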