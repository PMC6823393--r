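# Brute-force reference implementations used as independent oracles.
# Deliberately written as plain double loops over pixels so they share no
# code path with the package internals they check.

# Disk structuring element: Euclidean distance <= radius (same definition
# the package documents for its morphology front-ends).
oracle_disk <- function(radius) {
  r <- round(radius)
  outer(-r:r, -r:r, function(a, b) (a^2 + b^2 <= radius^2) * 1)
}

# Grayscale erosion/dilation ignoring out-of-bounds neighbors.
oracle_morph <- function(x, kern, op) {
  r <- (nrow(kern) - 1) / 2
  nr <- nrow(x); nc <- ncol(x)
  out <- x * 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (a in -r:r) for (b in -r:r) {
      if (kern[a + r + 1, b + r + 1] == 0) next
      ii <- i + a; jj <- j + b
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      vals <- c(vals, x[ii, jj])
    }
    out[i, j] <- if (op == "erode") min(vals) else max(vals)
  }
  out
}

oracle_tophat <- function(x, radius) {
  k <- oracle_disk(radius)
  x - oracle_morph(oracle_morph(x, k, "erode"), k, "dilate")
}

# Binary erosion with EBImage's semantics for interior objects (out-of-
# bounds irrelevant as long as the mask stays off the border).
oracle_binary_erode <- function(mask, radius) {
  k <- oracle_disk(radius)
  r <- (nrow(k) - 1) / 2
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    keep <- TRUE
    for (a in -r:r) for (b in -r:r) {
      if (k[a + r + 1, b + r + 1] == 0) next
      ii <- i + a; jj <- j + b
      inside <- ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && mask[ii, jj]
      if (!inside) { keep <- FALSE; break }
    }
    out[i, j] <- keep
  }
  out
}

# Direct 2-D correlation with replicate padding (matches the package's
# convolution front-end for the symmetric kernels it uses).
oracle_convolve <- function(x, kern) {
  r <- (nrow(kern) - 1) / 2
  nr <- nrow(x); nc <- ncol(x)
  out <- x * 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (a in -r:r) for (b in -r:r) {
      ii <- min(max(i + a, 1), nr); jj <- min(max(j + b, 1), nc)
      s <- s + x[ii, jj] * kern[a + r + 1, b + r + 1]
    }
    out[i, j] <- s
  }
  out
}

# Piecewise-linear resampling of a profile to n points, from the formula.
oracle_resample <- function(vals, n) {
  m <- length(vals)
  pos <- seq(1, m, length.out = n)
  sapply(pos, function(p) {
    lo <- floor(p); hi <- ceiling(p)
    if (lo == hi) vals[lo] else vals[lo] * (hi - p) + vals[hi] * (p - lo)
  })
}

# Moment-ellipse axis ratio from explicit pixel sums (+1/12 correction).
oracle_elongation <- function(mask) {
  pts <- which(mask > 0, arr.ind = TRUE)
  n <- nrow(pts)
  my <- mean(pts[, 1]); mx <- mean(pts[, 2])
  syy <- sum((pts[, 1] - my)^2) / n + 1 / 12
  sxx <- sum((pts[, 2] - mx)^2) / n + 1 / 12
  sxy <- sum((pts[, 1] - my) * (pts[, 2] - mx)) / n
  tr <- syy + sxx
  det <- syy * sxx - sxy^2
  l1 <- tr / 2 + sqrt(tr^2 / 4 - det)
  l2 <- tr / 2 - sqrt(tr^2 / 4 - det)
  sqrt(l1 / l2)
}
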