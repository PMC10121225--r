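## Translational channel registration. The nuclear (reference) and dendrite
## planes carry mutual structure (neuronal somata appear in both), so the
## integer translation maximizing their mutual information registers the
## camera misalignment; the identical translation is then applied to the
## presynaptic channel, which shares the dendrite channel's optics.

.quantizePlane <- function(plane, bins) {
  rng <- range(plane)
  if (diff(rng) == 0) return(matrix(1L, nrow(plane), ncol(plane)))
  q <- pmin(as.integer(floor((plane - rng[1]) / diff(rng) * bins)) + 1L, bins)
  matrix(q, nrow(plane), ncol(plane))
}

#' Mutual information between two planes
#'
#' Shannon mutual information (natural log) of the joint histogram of two
#' equally shaped planes, each quantized to \code{bins} equal-width levels
#' over its own intensity range.
#'
#' @param a,b numeric matrices of identical shape.
#' @param bins histogram bins per channel (default 64).
#' @return Mutual information in nats.
#' @export
mutualInformation <- function(a, b, bins = 64L) {
  stopifnot(identical(dim(a), dim(b)))
  .miQuantized(.quantizePlane(a, bins), .quantizePlane(b, bins), bins)
}

.miQuantized <- function(qa, qb, bins) {
  joint <- tabulate(qa + bins * (qb - 1L), bins * bins)
  n <- length(qa)
  jm <- matrix(joint, bins, bins) / n
  pa <- rowSums(jm); pb <- colSums(jm)
  nz <- jm > 0
  sum(jm[nz] * log(jm[nz] / (pa[row(jm)[nz]] * pb[col(jm)[nz]])))
}

#' Align the dendrite and presynaptic channels to the nuclear reference
#'
#' Exhaustively searches integer translations within
#' \code{alignment_search_radius} for the shift of the dendrite plane
#' maximizing its mutual information with the nuclear plane, then applies
#' that same shift to both the dendrite and presynaptic planes (revealed
#' edges padded at the plane minimum). Every candidate shift is scored on
#' the fixed central window inset by the search radius, so all candidates
#' see the same number of pixels; scoring on the variable overlap region
#' instead would bias the finite-sample MI estimate upward for large
#' shifts (smaller overlap, larger estimator bias). Ties on the MI
#' surface are broken toward the smaller shift magnitude, then
#' lexicographically on (dy, dx). A constant (degenerate) plane yields
#' offset (0, 0) with a warning.
#'
#' @param nuclear,dendrite,presynaptic 2-D planes of identical shape.
#' @param config a [PipelineConfig-class] (search radius, MI bins).
#' @return A [ProjectedField-class] with aligned planes, the recovered
#'   \code{alignment_offset} (dy, dx) and the degenerate flag.
#' @export
alignChannels <- function(nuclear, dendrite, presynaptic,
                          config = pipelineConfig()) {
  stopifnot(identical(dim(nuclear), dim(dendrite)),
            identical(dim(nuclear), dim(presynaptic)))
  bins <- config@mi_histogram_bins
  r <- config@alignment_search_radius
  degenerate <- diff(range(nuclear)) == 0 || diff(range(dendrite)) == 0
  if (degenerate) {
    warning("constant plane: alignment skipped, offset (0, 0)")
    best <- c(0L, 0L)
  } else {
    qa <- .quantizePlane(nuclear, bins)
    qb <- .quantizePlane(dendrite, bins)
    H <- nrow(qa); W <- ncol(qa)
    if (min(H, W) <= 2L * r + 4L)
      stop("alignment_search_radius too large for the image")
    ys <- (1L + r):(H - r); xs <- (1L + r):(W - r)
    qa_core <- qa[ys, xs]
    cand <- expand.grid(dy = -r:r, dx = -r:r)
    cand <- cand[order(cand$dy^2 + cand$dx^2, cand$dy, cand$dx), ]
    best <- c(0L, 0L); best_mi <- -Inf
    for (k in seq_len(nrow(cand))) {
      dy <- cand$dy[k]; dx <- cand$dx[k]
      mi <- .miQuantized(qa_core, qb[ys - dy, xs - dx], bins)
      if (mi > best_mi + 1e-12) { best_mi <- mi; best <- c(dy, dx) }
    }
  }
  pad_d <- min(dendrite); pad_p <- min(presynaptic)
  new("ProjectedField",
      planes = list(
        nuclear = nuclear,
        dendrite = .shiftMatrix(dendrite, best[1], best[2], pad_d),
        presynaptic = .shiftMatrix(presynaptic, best[1], best[2], pad_p)),
      alignment_offset = as.integer(best),
      alignment_degenerate = degenerate)
}

#' Build a plate-wide illumination correction surface
#'
#' Averages every pixel across all fields of a plate for one channel and
#' smooths the mean image with a large Gaussian filter (default filter
#' size 100 x 100 px). The surface is normalized to mean 1; dividing a
#' plane by it defines the correction.
#'
#' @param planes list of 2-D planes (all fields of one plate, one channel).
#' @param config a [PipelineConfig-class] (illumination filter size).
#' @return The normalized correction surface (matrix, mean 1).
#' @export
buildIlluminationFunction <- function(planes, config = pipelineConfig()) {
  stopifnot(length(planes) >= 1L)
  d <- dim(planes[[1]])
  if (!all(vapply(planes, function(p) identical(dim(p), d), logical(1))))
    stop("all planes must share shape")
  m <- Reduce(`+`, planes) / length(planes)
  s <- gaussianSmooth(m, size = config@illumination_filter_size,
                      boundary = "linear")
  mu <- mean(s)
  if (mu <= 0) stop("degenerate illumination surface")
  s / mu
}

#' Apply an illumination correction surface
#'
#' @param plane 2-D plane.
#' @param surface surface from [buildIlluminationFunction()].
#' @return \code{plane / surface}.
#' @export
correctIllumination <- function(plane, surface) {
  stopifnot(identical(dim(plane), dim(surface)))
  plane / surface
}
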