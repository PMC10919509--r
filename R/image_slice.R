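#' Construct an image slice
#'
#' The package's basic image container: a 2D grayscale matrix with values in
#' [0, 1], optional pixel spacing in millimetres, and a provenance id.
#'
#' @param pixels numeric matrix with finite values in [0, 1].
#' @param spacing optional numeric length-2 (row mm, col mm) per-pixel spacing.
#' @param source_id free-text provenance string.
#' @return an object of class `image_slice`.
#' @export
image_slice <- function(pixels, spacing = NULL, source_id = "") {
  check_that(is.matrix(pixels) && is.numeric(pixels), "pixels must be a numeric matrix")
  check_that(all(is.finite(pixels)), "pixels must be finite")
  check_that(min(pixels) >= 0 && max(pixels) <= 1,
             "pixels must lie in [0,1]; use normalize_pixels() first")
  if (!is.null(spacing)) {
    check_that(is.numeric(spacing) && length(spacing) == 2 && all(spacing > 0),
               "spacing must be two positive numbers")
  }
  structure(list(pixels = pixels, spacing = spacing, source_id = source_id),
            class = "image_slice")
}

#' @export
print.image_slice <- function(x, ...) {
  cat(sprintf("<image_slice %dx%d [%.3f, %.3f]%s>\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels),
              if (nzchar(x$source_id)) paste0(" ", x$source_id) else ""))
  invisible(x)
}

as_image_slice <- function(x) {
  if (inherits(x, "image_slice")) return(x)
  image_slice(as_pixel_matrix(x))
}

as_pixel_matrix <- function(x) {
  if (inherits(x, "image_slice")) x$pixels else x
}

#' Min-max normalize raw intensities to [0, 1]
#'
#' @param v numeric array of raw intensities.
#' @return list with `pixels` in [0,1] and the applied `window` (min, max),
#'   recorded so the transform is invertible.
#' @export
normalize_pixels <- function(v) {
  check_that(all(is.finite(v)), "intensities must be finite")
  lo <- min(v); hi <- max(v)
  p <- if (hi > lo) (v - lo) / (hi - lo) else array(0, dim(v) %||% length(v))
  list(pixels = p, window = c(lo, hi))
}

#' Read a grayscale image (PNG or plain-text PGM) as an image slice
#'
#' Multichannel PNGs are collapsed by channel averaging. Intensities are
#' min-max normalized; the original window is stored in the source id.
#'
#' @param path file path ending in .png or .pgm.
#' @return an `image_slice`.
#' @export
read_image_slice <- function(path) {
  check_that(file.exists(path), "no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3) apply(a[, , seq_len(min(3, dim(a)[3])), drop = FALSE], c(1, 2), mean) else a
    },
    pgm = read_pgm(path),
    stopf("unsupported image format: .%s (use png or pgm)", ext))
  nm <- normalize_pixels(raw)
  image_slice(nm$pixels, source_id = sprintf("%s window=[%g,%g]", basename(path),
                                             nm$window[1], nm$window[2]))
}

#' Write an image slice as grayscale PNG (8-bit) or ASCII PGM (16-bit)
#'
#' @param img `image_slice` or numeric matrix in [0,1].
#' @param path destination ending in .png or .pgm.
#' @export
write_image_slice <- function(img, path) {
  p <- as_pixel_matrix(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(p, target = path, dpi = NULL)
  } else if (ext == "pgm") {
    write_pgm(p, path)
  } else {
    stopf("unsupported image format: .%s", ext)
  }
  invisible(path)
}

# Plain (ASCII, P2) PGM: a text format handy for versionable fixtures.
read_pgm <- function(path) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  check_that(identical(tok[1], "P2"), "only plain (P2) PGM is supported")
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); mx <- as.numeric(tok[4])
  v <- as.numeric(tok[-(1:4)])
  check_that(length(v) == w * h, "PGM pixel count mismatch")
  matrix(v, nrow = h, ncol = w, byrow = TRUE) / mx
}

write_pgm <- function(pixels, path, maxval = 65535L) {
  q <- round(clamp01(pixels) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), as.character(maxval)), con)
  apply(q, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
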