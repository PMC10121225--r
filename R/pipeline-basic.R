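#' Maximum projection of a single-channel z-stack
#'
#' Collapses an \code{n_slices x height x width} stack into one plane by
#' the per-pixel maximum over slices.
#'
#' @param stack numeric array \code{n_slices x height x width} (a matrix is
#'   treated as a single slice).
#' @return A height x width matrix with
#'   \code{out[y, x] == max_z stack[z, y, x]}.
#' @export
maxProject <- function(stack) {
  if (is.matrix(stack)) return(stack)
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L || d[1] < 1L)
    stop("stack must be a non-empty n_slices x height x width array")
  out <- matrix(stack[1, , ], d[2], d[3])
  for (s in seq_len(d[1])[-1]) out <- pmax(out, matrix(stack[s, , ], d[2], d[3]))
  out
}

#' Rescale a plane to the full [0, 1] intensity range
#'
#' Affine stretch mapping the plane minimum to 0 and maximum to 1. A
#' constant plane maps to all zeros (declared degenerate-case convention).
#' The operation is idempotent.
#'
#' @param plane numeric matrix.
#' @return Matrix with values in [0, 1].
#' @export
rescaleIntensity <- function(plane) {
  rng <- range(plane)
  if (diff(rng) == 0) return(matrix(0, nrow(plane), ncol(plane)))
  (plane - rng[1]) / diff(rng)
}

#' Multi-class Otsu thresholds on a quantized histogram
#'
#' Computes the \code{classes - 1} thresholds maximizing the between-class
#' variance of the histogram of \code{values} quantized to \code{bins}
#' equal-width bins on [0, 1] (values are clipped into that range). The
#' search is exhaustive over all threshold placements, so the result equals
#' the brute-force maximum by construction; ties are broken toward the
#' smallest thresholds. Returned thresholds are bin boundaries
#' \code{k / bins}: a pixel belongs to the class above a threshold iff its
#' value is \code{>=} that threshold.
#'
#' If the histogram occupies fewer distinct bins than \code{classes}, the
#' method falls back to two-class thresholding (or, failing that, a single
#' degenerate threshold) with a warning.
#'
#' @param values numeric vector or matrix of intensities in [0, 1].
#' @param classes 2 or 3.
#' @param bins histogram bins (default 256).
#' @return Numeric vector of \code{classes - 1} thresholds (attributes:
#'   \code{between_variance}, \code{fallback}).
#' @examples
#' x <- c(rnorm(300, .1, .01), rnorm(300, .5, .01), rnorm(300, .9, .01))
#' otsuThresholds(x, classes = 3)
#' @export
otsuThresholds <- function(values, classes = 2L, bins = 256L) {
  stopifnot(classes %in% c(2L, 3L))
  v <- pmin(pmax(as.numeric(values), 0), 1)
  idx <- pmin(as.integer(floor(v * bins)) + 1L, bins)
  counts <- tabulate(idx, bins)
  occupied <- sum(counts > 0)
  fallback <- FALSE
  if (occupied < classes) {
    if (classes == 3L && occupied >= 2L) {
      warning("histogram has fewer than 3 distinct levels; ",
              "falling back to two-class Otsu")
      classes <- 2L; fallback <- TRUE
    } else if (occupied < 2L) {
      warning("histogram is degenerate; returning trivial threshold(s)")
      thr <- rep(which.max(counts) / bins, classes - 1L)
      attr(thr, "between_variance") <- 0
      attr(thr, "fallback") <- TRUE
      return(thr)
    }
  }
  n <- sum(counts)
  w <- counts / n
  mids <- (seq_len(bins) - 0.5) / bins
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  ## between-class variance = sum_k w_k mu_k^2 - mu^2; maximize sum w_k mu_k^2
  cw0 <- c(0, cw); cm0 <- c(0, cm)
  seg <- function(lo, hi) {      # class over bins (lo, hi]; lo/hi vectors ok
    ww <- cw0[hi + 1L] - cw0[lo + 1L]
    mm <- cm0[hi + 1L] - cm0[lo + 1L]
    ifelse(ww > 0, mm^2 / ww, 0)
  }
  if (classes == 2L) {
    ts <- seq_len(bins - 1L)
    crit <- vapply(ts, function(t) seg(0L, t) + seg(t, bins), numeric(1))
    best <- ts[which.max(crit)]
    thr <- best / bins
    bv <- max(crit) - (cm[bins])^2
  } else {
    best <- c(1L, 2L); best_crit <- -Inf
    for (i in seq_len(bins - 2L)) {
      js <- (i + 1L):(bins - 1L)
      crit <- seg(0L, i) + seg(i, js) + seg(js, bins)
      j <- js[which.max(crit)]
      if (max(crit) > best_crit) { best_crit <- max(crit); best <- c(i, j) }
    }
    thr <- best / bins
    bv <- best_crit - (cm[bins])^2
  }
  attr(thr, "between_variance") <- bv
  attr(thr, "fallback") <- fallback
  thr
}

#' Gaussian smoothing with an explicit filter size
#'
#' Separable Gaussian filter parameterized the way high-content analysis
#' tools state it: by a filter size in pixels, with
#' \code{sigma = size / 2.355} (size = FWHM) unless given explicitly.
#' Borders are handled by replication; the kernel is clamped to the image
#' size when the requested filter is larger than the plane.
#'
#' @param plane numeric matrix.
#' @param size filter size in pixels.
#' @param sigma Gaussian sigma in pixels (overrides \code{size}-derived
#'   sigma when given).
#' @param boundary "replicate" (default) or "linear": antisymmetric
#'   reflection padding that preserves linear intensity ramps exactly,
#'   used for illumination-gradient estimation where replicate padding
#'   would flatten the ramp near the borders.
#' @return Smoothed matrix of the same shape.
#' @export
gaussianSmooth <- function(plane, size = NULL, sigma = NULL,
                           boundary = c("replicate", "linear")) {
  boundary <- match.arg(boundary)
  if (is.null(sigma)) {
    stopifnot(!is.null(size))
    sigma <- size / 2.355
  }
  if (sigma <= 0) return(plane)
  half <- ceiling(if (is.null(size)) 3 * sigma else size / 2)
  half <- min(half, min(dim(plane)) - 1L)
  k1 <- exp(-((-half):half)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k <- outer(k1, k1)
  if (boundary == "linear") {
    p <- .padLinear(plane, half)
    sm <- .asMat(EBImage::filter2(EBImage::Image(p), k,
                                  boundary = "replicate"))
    return(sm[(half + 1):(half + nrow(plane)),
              (half + 1):(half + ncol(plane))])
  }
  half2 <- min(half, floor((min(dim(plane)) - 1) / 2))
  if (half2 < half) {
    k1 <- exp(-((-half2):half2)^2 / (2 * sigma^2))
    k1 <- k1 / sum(k1)
    k <- outer(k1, k1)
  }
  .asMat(EBImage::filter2(EBImage::Image(plane), k,
                             boundary = "replicate"))
}

## pad by antisymmetric (odd) reflection: f(-t) = 2 f(0) - f(t); linear
## functions extend exactly
.padLinear <- function(m, h) {
  padv <- function(x) {
    n <- length(x)
    hh <- min(h, n - 1L)
    pre <- 2 * x[1] - x[(hh + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - hh)]
    c(rep(pre[1], h - hh), pre, x, post, rep(post[length(post)], h - hh))
  }
  m2 <- apply(m, 2, padv)              # pad rows (y)
  t(apply(m2, 1, padv))                # pad cols (x)
}
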