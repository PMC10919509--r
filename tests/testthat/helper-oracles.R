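# Analytic rasters and independent brute-force oracles used across tests.

raster_disk <- function(h, w, cy, cx, r) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

raster_bar <- function(h, w, r0, c0, height, width) {
  m <- matrix(FALSE, h, w)
  m[r0:(r0 + height - 1), c0:(c0 + width - 1)] <- TRUE
  m
}

# O(N) brute-force GLCM pair counter: explicit loop over every pixel.
glcm_bruteforce <- function(pixels, mask, L, d, theta, symmetric) {
  off <- switch(as.character(theta),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
  q <- floor(pmin(pixels * L, L - 1e-9))
  S <- matrix(0, L, L)
  for (r in seq_len(nrow(mask))) {
    for (cc in seq_len(ncol(mask))) {
      if (!mask[r, cc]) next
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 < 1 || r2 > nrow(mask) || c2 < 1 || c2 > ncol(mask)) next
      if (!mask[r2, c2]) next
      S[q[r, cc] + 1, q[r2, c2] + 1] <- S[q[r, cc] + 1, q[r2, c2] + 1] + 1
    }
  }
  if (symmetric) S <- S + t(S)
  S / sum(S)
}

# O(Nr * Nt) double-loop Pratt figure of merit.
fom_bruteforce <- function(ref, tst, alpha = 1 / 9) {
  ri <- which(ref, arr.ind = TRUE)
  ti <- which(tst, arr.ind = TRUE)
  if (nrow(ti) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(ti))) {
    best <- Inf
    for (j in seq_len(nrow(ri))) {
      d2 <- (ti[i, 1] - ri[j, 1])^2 + (ti[i, 2] - ri[j, 2])^2
      if (d2 < best) best <- d2
    }
    tot <- tot + 1 / (1 + alpha * best)
  }
  tot / max(nrow(ri), nrow(ti))
}

# O(n^2) concordant-pair AUC (ties count half).
auc_bruteforce <- function(y, s, positive) {
  pos <- which(as.character(y) == as.character(positive))
  neg <- which(as.character(y) != as.character(positive))
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

expect_close <- function(a, b, tol = 1e-10) expect_lt(abs(a - b), tol)
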