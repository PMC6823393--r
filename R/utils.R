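#' @useDynLib minwave, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef cor fft lm median mvfft nextn quantile rnorm
#'   rpois runif sd setNames vcov
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic generators in the package go
# through this so a spec + seed pair is fully reproducible.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Odd-sized binary disk structuring element: pixels within `radius` (in px,
# Euclidean) of the center. Shared by the morphology front-ends and by the
# brute-force oracles in the test suite.
disk_kernel <- function(radius) {
  stopifnot(radius >= 1)
  r <- as.integer(round(radius))
  n <- 2L * r + 1L
  u <- matrix(rep(-r:r, n), n, n)
  (u^2 + t(u)^2 <= radius^2) * 1
}

# Odd-sized normalized 2-D Gaussian kernel. `size` is the nominal support;
# even requests are rounded up to the nearest odd size so the kernel is
# centered on a pixel.
gaussian_kernel <- function(size, sigma) {
  stopifnot(size >= 1, sigma > 0)
  n <- as.integer(size)
  if (n %% 2L == 0L) n <- n + 1L
  h <- (n - 1L) %/% 2L
  u <- matrix(rep(-h:h, n), n, n)
  k <- exp(-(u^2 + t(u)^2) / (2 * sigma^2))
  k / sum(k)
}

# 2-D convolution with replicate (nearest-pixel) boundary padding.
convolve2d <- function(x, kernel) {
  EBImage::filter2(x, kernel, boundary = "replicate")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Grayscale morphology with a binary structuring element. Out-of-bounds
# neighbors are ignored (equivalent to padding with +Inf for erosion and
# -Inf for dilation), so the opening never exceeds the image anywhere,
# including at the border. Vectorized as a running min/max over the
# structuring-element offsets.
gray_morph <- function(x, kern, op = c("erode", "dilate")) {
  op <- match.arg(op)
  kh <- (nrow(kern) - 1L) %/% 2L
  kw <- (ncol(kern) - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  pad <- matrix(if (op == "erode") Inf else -Inf,
                nr + 2L * kh, nc + 2L * kw)
  pad[kh + seq_len(nr), kw + seq_len(nc)] <- x
  out <- NULL
  agg <- if (op == "erode") pmin else pmax
  for (a in seq_len(nrow(kern))) for (b in seq_len(ncol(kern))) {
    if (kern[a, b] == 0) next
    v <- pad[(a - 1L) + seq_len(nr), (b - 1L) + seq_len(nc)]
    out <- if (is.null(out)) v else agg(out, v)
  }
  out
}

gray_opening <- function(x, kern)
  gray_morph(gray_morph(x, kern, "erode"), kern, "dilate")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Intersection-over-union of two binary masks.
iou <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}
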