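#' 8-connected component labelling
#'
#' Iterative minimum-label propagation; adequate for the compact regions this
#' pipeline produces.
#'
#' @param mask logical matrix.
#' @return integer matrix: 0 for background, 1..n for components.
#' @export
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  shifts <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                 c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  big <- sum(mask) + 1L
  repeat {
    cur <- lab
    m <- lab
    m[!mask] <- big
    for (s in shifts) {
      sh <- shift_matrix_logical_int(m, s[1], s[2], pad = big)
      m <- pmin(m, sh)
    }
    lab[mask] <- m[mask]
    if (identical(lab, cur)) break
  }
  # densify labels to 1..n
  u <- sort(unique(lab[lab > 0L]))
  if (length(u)) lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

shift_matrix_logical_int <- function(m, dr, dc, pad) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(pad, nr, nc)
  ri <- seq_len(nr) + dr; ci <- seq_len(nc) + dc
  rok <- ri >= 1L & ri <= nr; cok <- ci >= 1L & ci <= nc
  out[rok, cok] <- m[ri[rok], ci[cok], drop = FALSE]
  out
}

# Moore boundary tracing: chain-code perimeter with sqrt(2) diagonal weights.
# Reduces the raster bias that pushes disk circularity above 1.
trace_perimeter <- function(mask) {
  area <- sum(mask)
  if (area <= 2) return(2 * sqrt(pi * area))  # too small to trace; circle-equivalent
  idx <- which(mask, arr.ind = TRUE)
  start <- idx[order(idx[, 1], idx[, 2])[1], ]      # topmost, then leftmost
  # neighbours clockwise starting from W
  nb <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                 0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L), ncol = 2, byrow = TRUE)
  inside <- function(r, c) r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) && mask[r, c]
  per <- 0
  cur <- start; dir <- 5L  # pretend we arrived moving East (came from W)
  steps <- 0L; cap <- 8L * area + 16L
  repeat {
    found <- FALSE
    for (k in 0:7) {
      # scan clockwise starting just after the backtrack direction
      d <- ((dir - 1L + 5L + k) %% 8L) + 1L
      r2 <- cur[1] + nb[d, 1]; c2 <- cur[2] + nb[d, 2]
      if (inside(r2, c2)) {
        w <- if (nb[d, 1] != 0 && nb[d, 2] != 0) sqrt(2) else 1
        per <- per + w
        cur <- c(r2, c2); dir <- d; found <- TRUE
        break
      }
    }
    if (!found) return(2 * sqrt(pi * area))  # isolated pixel, nothing to trace
    steps <- steps + 1L
    if ((steps > 1L && all(cur == start)) || steps >= cap) break
  }
  max(per, 2 * sqrt(pi * area) * 0.5)
}

# Shape descriptors from second central moments (image-moment ellipse).
moment_axes <- function(rows, cols) {
  # +1/12: variance of the unit-pixel extent; keeps 1-px-wide lines non-degenerate
  mu20 <- stats::var(rows) * (length(rows) - 1) / length(rows) + 1 / 12
  mu02 <- stats::var(cols) * (length(cols) - 1) / length(cols) + 1 / 12
  mu11 <- stats::cov(rows, cols) * (length(rows) - 1) / length(rows)
  if (length(rows) == 1) { mu20 <- mu02 <- 1 / 12; mu11 <- 0 }
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-12)
  c(major = sqrt(l1), minor = sqrt(l2))
}

#' Rule descriptors for one candidate region
#'
#' mean and variance of intensities under the mask; circularity 4*pi*A/P^2
#' (chain-code perimeter); flatness = minor/major axis ratio; elongation =
#' major/minor; rectangularity = A / bounding-box area.
#'
#' @param mask logical matrix of the region (full-frame).
#' @param pixels image matrix.
#' @return named numeric vector of the six descriptors.
#' @export
rule_descriptors <- function(mask, pixels) {
  idx <- which(mask, arr.ind = TRUE)
  check_that(nrow(idx) >= 1, "empty region mask")
  vals <- pixels[mask]
  a <- nrow(idx)
  per <- trace_perimeter(mask)
  axes <- moment_axes(idx[, 1], idx[, 2])
  bbox_area <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
  c(mean_intensity = mean(vals),
    intensity_variance = if (a > 1) stats::var(vals) else 0,
    circularity = 4 * pi * a / per^2,
    flatness = unname(axes["minor"] / axes["major"]),
    elongation = unname(axes["major"] / axes["minor"]),
    rectangularity = a / bbox_area)
}

#' Extract nodule candidates from a foreground mask
#'
#' 8-connected components with area >= `min_area`, each carrying its mask,
#' tight half-open bounding box (1-based, row0:row1-1 x col0:col1-1),
#' centroid, area and rule descriptors.
#'
#' @param mask logical foreground mask.
#' @param img image slice or matrix aligned to the mask.
#' @param min_area minimum component area in pixels.
#' @return list of `nodule_candidate` objects (possibly empty).
#' @export
label_candidates <- function(mask, img, min_area = 10) {
  p <- as_pixel_matrix(img)
  check_that(all(dim(mask) == dim(p)), "mask and image must be aligned")
  lab <- label_components(mask)
  n <- max(lab)
  out <- list()
  for (i in seq_len(n)) {
    m <- lab == i
    a <- sum(m)
    if (a < min_area) next
    idx <- which(m, arr.ind = TRUE)
    cand <- structure(list(
      region_mask = m,
      bbox = c(row0 = min(idx[, 1]), col0 = min(idx[, 2]),
               row1 = max(idx[, 1]) + 1L, col1 = max(idx[, 2]) + 1L),
      centroid = c(row = mean(idx[, 1]), col = mean(idx[, 2])),
      area = a,
      descriptors = rule_descriptors(m, p)), class = "nodule_candidate")
    out[[length(out) + 1L]] <- cand
  }
  out
}

#' @export
print.nodule_candidate <- function(x, ...) {
  cat(sprintf("<nodule_candidate area=%d centroid=(%.1f,%.1f) circ=%.2f elong=%.2f>\n",
              x$area, x$centroid[1], x$centroid[2],
              x$descriptors["circularity"], x$descriptors["elongation"]))
  invisible(x)
}

#' Per-descriptor pruning bounds
#'
#' Each descriptor may carry an optional lower and/or upper bound. A candidate
#' is dropped as soon as any active bound is violated.
#'
#' @param ... named arguments, each `c(lower, upper)` with `NA` for an
#'   inactive side, e.g. `elongation = c(NA, 3)`.
#' @return a `rule_thresholds` object.
#' @export
rule_thresholds <- function(...) {
  th <- list(...)
  known <- c("mean_intensity", "intensity_variance", "circularity",
             "flatness", "elongation", "rectangularity")
  for (nm in names(th)) {
    check_that(nm %in% known, "unknown descriptor '%s'", nm)
    b <- th[[nm]]
    check_that(length(b) == 2, "bounds for '%s' must be c(lower, upper)", nm)
    if (!is.na(b[1]) && !is.na(b[2])) {
      check_that(b[1] <= b[2], "lower bound exceeds upper bound for '%s'", nm)
    }
  }
  structure(th, class = "rule_thresholds")
}

#' Default pruning rules for phantom-like data
#'
#' Chosen so that compact bright nodules survive while elongated vessel-like
#' distractors and faint noise blobs are rejected; every bound is overridable.
#'
#' @param background background gray level.
#' @param noise_sigma noise standard deviation; the intensity rule requires
#'   mean >= background + 2 * noise_sigma.
#' @export
default_rule_thresholds <- function(background = 0.2, noise_sigma = 0.05) {
  rule_thresholds(mean_intensity = c(background + 2 * noise_sigma, NA),
                  circularity = c(0.4, NA),
                  elongation = c(NA, 3.0),
                  rectangularity = c(0.3, NA))
}

#' Rule-based candidate pruning
#'
#' @param cands list of candidates from [label_candidates()].
#' @param thresholds a [rule_thresholds()].
#' @return list with `kept` and `dropped` candidate lists and `reasons`, a
#'   list (parallel to `dropped`) of violated rule names.
#' @export
rule_crop <- function(cands, thresholds = default_rule_thresholds()) {
  check_that(inherits(thresholds, "rule_thresholds"), "thresholds must be rule_thresholds")
  kept <- list(); dropped <- list(); reasons <- list()
  for (cand in cands) {
    viol <- violated_rules(cand$descriptors, thresholds)
    if (length(viol)) {
      dropped[[length(dropped) + 1L]] <- cand
      reasons[[length(reasons) + 1L]] <- viol
    } else {
      kept[[length(kept) + 1L]] <- cand
    }
  }
  list(kept = kept, dropped = dropped, reasons = reasons)
}

violated_rules <- function(desc, thresholds) {
  viol <- character(0)
  for (nm in names(thresholds)) {
    b <- thresholds[[nm]]
    v <- desc[[nm]]
    if (!is.na(b[1]) && v < b[1]) viol <- c(viol, nm)
    else if (!is.na(b[2]) && v > b[2]) viol <- c(viol, nm)
  }
  viol
}

#' Serialize candidates to a data frame (one row per candidate)
#'
#' @param cands candidate list.
#' @param slice_id id recorded in the table.
#' @param kept optional logical vector; `reasons` optional parallel list.
#' @export
candidates_to_table <- function(cands, slice_id = "slice", kept = NULL, reasons = NULL) {
  if (!length(cands)) {
    return(data.frame(slice_id = character(0), region_id = integer(0)))
  }
  rows <- lapply(seq_along(cands), function(i) {
    cand <- cands[[i]]
    d <- as.list(cand$descriptors)
    data.frame(slice_id = slice_id, region_id = i,
               row0 = cand$bbox[1], col0 = cand$bbox[2],
               row1 = cand$bbox[3], col1 = cand$bbox[4],
               area = cand$area, d,
               kept = if (is.null(kept)) NA else kept[i],
               reasons = if (is.null(reasons) || !length(reasons[[i]])) ""
                         else paste(reasons[[i]], collapse = ";"))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
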