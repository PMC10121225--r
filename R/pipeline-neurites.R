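#' Tubeness enhancement of the dendrite channel
#'
#' Ridge (curvilinear-structure) measure at Gaussian scale
#' \code{tubeness_sigma} (default 2): the plane is Gaussian-smoothed at the
#' scale, the 2-D Hessian is formed by finite differences, and the response
#' is the magnitude of the negative principal curvature
#' (\code{max(0, -lambda_min)}, scale-normalized by sigma^2), which is
#' large across a thin bright neurite and small on flat background or broad
#' blobs. A morphological white tophat (disk radius
#' \code{tubeness_tophat_radius}) then suppresses any residual wide
#' background structure.
#'
#' @param plane rescaled dendrite plane in [0, 1].
#' @param config a [PipelineConfig-class].
#' @return Non-negative enhanced plane.
#' @export
enhanceNeurites <- function(plane, config = pipelineConfig()) {
  s <- config@tubeness_sigma
  sm <- gaussianSmooth(plane, sigma = s)
  im <- EBImage::Image(sm)
  dxx <- .asMat(EBImage::filter2(im, matrix(c(1, -2, 1), 1, 3),
                                    boundary = "replicate"))
  dyy <- .asMat(EBImage::filter2(im, matrix(c(1, -2, 1), 3, 1),
                                    boundary = "replicate"))
  dx1 <- .asMat(EBImage::filter2(im, matrix(c(-0.5, 0, 0.5), 1, 3),
                                    boundary = "replicate"))
  dxy <- .asMat(EBImage::filter2(EBImage::Image(dx1),
                                    matrix(c(-0.5, 0, 0.5), 3, 1),
                                    boundary = "replicate"))
  tr <- dxx + dyy
  disc <- sqrt(pmax((dxx - dyy)^2 + 4 * dxy^2, 0))
  lam_min <- (tr - disc) / 2
  resp <- pmax(-lam_min, 0) * s^2
  th <- .asMat(EBImage::whiteTopHat(EBImage::Image(resp),
                                       .discBrush(config@tubeness_tophat_radius)))
  pmax(th, 0)
}

#' Segment the neurite mask by multi-class Otsu thresholding
#'
#' Rescales the enhanced plane to [0, 1], computes the three-class Otsu
#' thresholds (lower and upper bound) and forms the mask from the classes
#' at or above the configured foreground bound: the union of the middle
#' and upper classes by default, or the upper class only.
#'
#' @param enhanced plane from [enhanceNeurites()].
#' @param config a [PipelineConfig-class].
#' @return list with \code{mask} (logical matrix), \code{area} (pixel
#'   count), \code{thresholds} and \code{fallback} flag.
#' @export
segmentNeurites <- function(enhanced, config = pipelineConfig()) {
  v <- rescaleIntensity(enhanced)
  thr <- otsuThresholds(v, classes = config@neurite_otsu_classes,
                        bins = config@otsu_bins)
  bound <- if (config@neurite_foreground == "upper" || length(thr) == 1L)
    thr[length(thr)] else thr[1]
  mask <- v >= bound
  list(mask = mask, area = sum(mask), thresholds = as.numeric(thr),
       fallback = isTRUE(attr(thr, "fallback")))
}
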