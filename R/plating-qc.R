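#' Detect nuclei in a projected nuclear-stain plane
#'
#' Gaussian smoothing, two-class Otsu thresholding, hole filling and a
#' watershed split on the distance transform, followed by a minimum
#' equivalent-diameter filter in micrometers (default 20, the plating-QC
#' criterion). Per-object morphology and intensity features are computed
#' for downstream classification.
#'
#' @param plane 2-D nuclear plane (any intensity scale; rescaled
#'   internally).
#' @param pixel_size micrometers per pixel.
#' @param thresholds a [QCThresholds-class]; its
#'   \code{min_nucleus_diameter} is used unless \code{min_diameter_um}
#'   overrides it.
#' @param min_diameter_um minimum equivalent diameter in micrometers.
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @return data.frame with one row per retained nucleus: \code{y, x}
#'   (0-based centroid), \code{area} (px), \code{diameter} (px),
#'   \code{diameter_um}, \code{mean_intensity}, \code{contrast},
#'   \code{roundness}, \code{class} ("unclassified"). The label image is
#'   attached as attribute \code{"labels"}.
#' @export
detectNuclei <- function(plane, pixel_size, thresholds = qcThresholds(),
                         min_diameter_um = thresholds@min_nucleus_diameter,
                         smooth_sigma = 2) {
  stopifnot(pixel_size > 0)
  v <- rescaleIntensity(plane)
  empty <- data.frame(y = numeric(0), x = numeric(0), area = integer(0),
                      diameter = numeric(0), diameter_um = numeric(0),
                      mean_intensity = numeric(0), contrast = numeric(0),
                      roundness = numeric(0), class = character(0),
                      stringsAsFactors = FALSE)
  if (all(v == 0)) {
    attr(empty, "labels") <- matrix(0L, nrow(plane), ncol(plane))
    return(empty)
  }
  sm <- gaussianSmooth(v, sigma = smooth_sigma)
  thr <- otsuThresholds(sm, classes = 2L)
  bw <- sm >= thr
  if (!any(bw)) {
    attr(empty, "labels") <- matrix(0L, nrow(plane), ncol(plane))
    return(empty)
  }
  bwi <- EBImage::fillHull(EBImage::Image(bw * 1))
  dm <- EBImage::distmap(bwi)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labm <- matrix(as.integer(EBImage::imageData(lab)),
                 nrow(plane), ncol(plane))
  n <- max(labm)
  if (n == 0L) { attr(empty, "labels") <- labm; return(empty) }
  areas <- tabulate(labm, n)
  ed_px <- 2 * sqrt(areas / pi)
  keep <- which(ed_px * pixel_size >= min_diameter_um)
  if (!length(keep)) {
    attr(empty, "labels") <- matrix(0L, nrow(plane), ncol(plane))
    return(empty)
  }
  idx <- which(labm > 0)
  yy <- ((idx - 1L) %% nrow(plane)) + 1L
  xx <- ((idx - 1L) %/% nrow(plane)) + 1L
  g <- labm[idx]
  bg_mean <- mean(v[labm == 0L])
  per_mean <- as.numeric(tapply(v[idx], factor(g, levels = seq_len(n)), mean))
  cy <- as.numeric(tapply(yy, factor(g, levels = seq_len(n)), mean))
  cx <- as.numeric(tapply(xx, factor(g, levels = seq_len(n)), mean))
  ## perimeter-based roundness 4*pi*A / P^2, clipped to [0, 1]
  perim <- .labelPerimeter(labm, n)
  roundness <- pmin(4 * pi * areas / pmax(perim, 1)^2, 1)
  contrast <- (per_mean - bg_mean) / pmax(per_mean + bg_mean, 1e-12)
  out <- data.frame(y = cy[keep] - 1, x = cx[keep] - 1,
                    area = as.integer(areas[keep]), diameter = ed_px[keep],
                    diameter_um = ed_px[keep] * pixel_size,
                    mean_intensity = per_mean[keep],
                    contrast = contrast[keep], roundness = roundness[keep],
                    class = "unclassified", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  relab <- integer(n); relab[keep] <- seq_along(keep)
  lab2 <- matrix(0L, nrow(plane), ncol(plane))
  nz <- labm > 0
  lab2[nz] <- relab[labm[nz]]
  attr(out, "labels") <- lab2
  out
}

## boundary pixel count per label (4-neighbour)
.labelPerimeter <- function(labm, n) {
  H <- nrow(labm); W <- ncol(labm)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- labm
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  border <- (pad[1:H, 2:(W + 1L)] != core) |
    (pad[3:(H + 2L), 2:(W + 1L)] != core) |
    (pad[2:(H + 1L), 1:W] != core) |
    (pad[2:(H + 1L), 3:(W + 2L)] != core)
  sel <- core > 0L & border
  tabulate(core[sel], n)
}

#' Default gates for neuronal-nucleus classification
#'
#' Rule-based gates calibrated on the synthetic simulator: a nucleus is
#' called neuronal when it is bright, high-contrast, of plausible size,
#' round, and surrounded by a dendrite-marker-positive soma (mean
#' dendrite signal in a perinuclear annulus above the soma gate).
#'
#' @param min_intensity,min_contrast,area_band_um2,min_roundness,min_soma,ring_width
#'   gate values; intensities are on rescaled [0, 1] planes, the area band
#'   in square micrometers, the annulus width in pixels.
#' @return Named list of gates.
#' @export
neuronalGates <- function(min_intensity = 0.5, min_contrast = 0.3,
                          area_band_um2 = c(150, 1500),
                          min_roundness = 0.7, min_soma = 0.12,
                          ring_width = 3) {
  list(min_intensity = min_intensity, min_contrast = min_contrast,
       area_band_um2 = area_band_um2, min_roundness = min_roundness,
       min_soma = min_soma, ring_width = ring_width)
}

#' Classify nuclei as neuronal or astrocytic
#'
#' Applies the rule-based gates of [neuronalGates()] to each detected
#' nucleus: intensity, contrast, area band, roundness, and the
#' dendrite-channel mean in a perinuclear ring (the "distinct
#' dendrite-positive soma" criterion). A nucleus is neuronal iff all gates
#' pass, otherwise astrocytic. With no dendrite plane all nuclei stay
#' unclassified (with a warning).
#'
#' @param nuclei data.frame from [detectNuclei()].
#' @param dendrite_plane rescaled dendrite plane of the same field, or
#'   NULL.
#' @param pixel_size micrometers per pixel.
#' @param gates list from [neuronalGates()].
#' @return \code{nuclei} with the \code{class} column set and a
#'   \code{soma_intensity} column appended.
#' @export
classifyNeuronal <- function(nuclei, dendrite_plane, pixel_size,
                             gates = neuronalGates()) {
  if (nrow(nuclei) == 0L) return(nuclei)
  if (is.null(dendrite_plane)) {
    warning("no dendrite plane: nuclei left unclassified")
    nuclei$class <- "unclassified"
    nuclei$soma_intensity <- NA_real_
    return(nuclei)
  }
  H <- nrow(dendrite_plane); W <- ncol(dendrite_plane)
  soma <- vapply(seq_len(nrow(nuclei)), function(i) {
    cy <- nuclei$y[i] + 1; cx <- nuclei$x[i] + 1
    r <- nuclei$diameter[i] / 2
    ro <- r + gates$ring_width
    ys <- max(1, floor(cy - ro)):min(H, ceiling(cy + ro))
    xs <- max(1, floor(cx - ro)):min(W, ceiling(cx + ro))
    dy <- ys - cy
    d2 <- outer(dy^2, (xs - cx)^2, `+`)
    ring <- d2 > r^2 & d2 <= ro^2
    if (!any(ring)) return(0)
    mean(dendrite_plane[ys, xs][ring])
  }, numeric(1))
  area_um2 <- nuclei$area * pixel_size^2
  neuronal <- nuclei$mean_intensity >= gates$min_intensity &
    nuclei$contrast >= gates$min_contrast &
    area_um2 >= gates$area_band_um2[1] & area_um2 <= gates$area_band_um2[2] &
    nuclei$roundness >= gates$min_roundness &
    soma >= gates$min_soma
  nuclei$class <- ifelse(neuronal, "neuronal", "astrocytic")
  nuclei$soma_intensity <- soma
  nuclei
}

#' Plate-level plating-consistency report
#'
#' Computes the intra-plate covariance (100 * SD / mean, sample SD) of the
#' per-well neuronal nuclei counts and checks the two acceptance rules:
#' the per-well count band (4000-12,000 by default, with at least
#' \code{band_fraction} of wells inside) and the covariance ceiling
#' (below 8\% by default).
#'
#' @param per_well_counts numeric vector of per-well neuronal nuclei
#'   counts (optionally named by well).
#' @param thresholds a [QCThresholds-class].
#' @return list with \code{counts, mean, sd, covariance_pct,
#'   frac_in_band, count_rule, covariance_rule, pass, degenerate}.
#' @examples
#' plateConsistency(rep(8000, 60))$pass           # CV 0, pass
#' plateConsistency(c(rep(6000, 58), 3000, 9000)) # band violation
#' @export
plateConsistency <- function(per_well_counts, thresholds = qcThresholds()) {
  x <- as.numeric(per_well_counts)
  stopifnot(length(x) >= 2L)
  mu <- mean(x)
  if (mu == 0) {
    return(list(counts = per_well_counts, mean = 0, sd = sd(x),
                covariance_pct = NA_real_, frac_in_band = 0,
                count_rule = FALSE, covariance_rule = FALSE, pass = FALSE,
                degenerate = TRUE))
  }
  s <- sd(x)
  cv <- 100 * s / mu
  inb <- x >= thresholds@min_nuclei_per_well &
    x <= thresholds@max_nuclei_per_well
  frac <- mean(inb)
  count_rule <- frac >= thresholds@band_fraction
  cov_rule <- cv < thresholds@max_covariance_pct
  list(counts = per_well_counts, mean = mu, sd = s, covariance_pct = cv,
       frac_in_band = frac, count_rule = count_rule,
       covariance_rule = cov_rule, pass = count_rule && cov_rule,
       degenerate = FALSE)
}

#' Write a plating-consistency report
#'
#' Writes the per-well counts as CSV (well, count) and a one-line JSON
#' verdict \code{\{mean, sd, covariance_pct, pass\}}.
#'
#' @param report list from [plateConsistency()].
#' @param csv_path,json_path output paths (NULL skips either).
#' @return Invisibly, the JSON string.
#' @export
writePlateReport <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    counts <- report$counts
    wells <- names(counts)
    if (is.null(wells)) wells <- sprintf("W%02d", seq_along(counts))
    write.csv(data.frame(well = wells, count = as.numeric(counts)),
              csv_path, row.names = FALSE)
  }
  js <- jsonlite::toJSON(list(mean = report$mean, sd = report$sd,
                              covariance_pct = report$covariance_pct,
                              pass = report$pass),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(json_path)) writeLines(js, json_path)
  invisible(js)
}
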