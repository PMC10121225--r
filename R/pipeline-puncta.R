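#' Detect presynaptic puncta
#'
#' Speckle enhancement by morphological white tophat with a disk
#' structuring element (radius \code{speckle_radius}; the default 5 fully
#' suppresses objects of diameter 10 px and larger while passing every
#' valid punctum), two-class Otsu binarization with a robust noise gate
#' (see [PipelineConfig-class]), watershed de-clumping of touching puncta
#' at intensity saddle points, and an equivalent-diameter filter retaining
#' objects with \code{1 <= 2*sqrt(area/pi) <= 6} pixels at the default
#' configuration.
#'
#' @param plane rescaled presynaptic plane in [0, 1].
#' @param config a [PipelineConfig-class].
#' @return list with \code{table} — a data.frame (label, area,
#'   equivalent_diameter, y, x, on_neurite) with 0-based centroids and
#'   \code{on_neurite} unset (NA) until [colocalize()] — and \code{labels},
#'   the relabelled object image (0 = background).
#' @export
detectPuncta <- function(plane, config = pipelineConfig()) {
  th <- .asMat(EBImage::whiteTopHat(EBImage::Image(plane),
                                       .discBrush(config@speckle_radius)))
  v <- pmin(pmax(th, 0), 1)
  empty <- list(
    table = data.frame(label = integer(0), area = integer(0),
                       equivalent_diameter = numeric(0), y = numeric(0),
                       x = numeric(0), on_neurite = logical(0)),
    labels = matrix(0L, nrow(plane), ncol(plane)))
  if (diff(range(v)) == 0) return(empty)
  thr <- otsuThresholds(v, classes = config@puncta_otsu_classes,
                        bins = config@otsu_bins)
  cut <- thr[length(thr)]
  ## robust noise gate: ignore the Otsu split when it falls inside the
  ## shot-noise distribution of a signal-free plane
  if (config@speckle_noise_floor > 0)
    cut <- max(cut, median(v) + config@speckle_noise_floor * mad(v))
  bw <- v >= cut
  if (!any(bw)) return(empty)
  lab <- EBImage::watershed(EBImage::Image(v * bw),
                            tolerance = config@declump_tolerance,
                            ext = config@declump_ext)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(plane), ncol(plane))
  n <- max(lab)
  if (n == 0L) return(empty)
  lab <- .splitOversize(lab, config@puncta_diameter_range[2])
  n <- max(lab)
  areas <- tabulate(lab, n)
  ed <- 2 * sqrt(areas / pi)
  keep <- which(ed >= config@puncta_diameter_range[1] &
                ed <= config@puncta_diameter_range[2] & areas > 0)
  if (!length(keep)) return(empty)
  relab <- integer(n); relab[keep] <- seq_along(keep)
  lab2 <- matrix(0L, nrow(plane), ncol(plane))
  nz <- lab > 0
  lab2[nz] <- relab[lab[nz]]
  idx <- which(lab2 > 0)
  yy <- ((idx - 1L) %% nrow(plane)) + 1L
  xx <- ((idx - 1L) %/% nrow(plane)) + 1L
  g <- factor(lab2[idx], levels = seq_along(keep))
  tab <- data.frame(
    label = seq_along(keep),
    area = as.integer(areas[keep]),
    equivalent_diameter = ed[keep],
    y = as.numeric(tapply(yy, g, mean)) - 1,
    x = as.numeric(tapply(xx, g, mean)) - 1,
    on_neurite = NA)
  rownames(tab) <- NULL
  list(table = tab, labels = lab2)
}

## second de-clump stage: clusters of nearly coincident puncta have no
## intensity saddle for the first watershed to cut, so objects exceeding
## the diameter ceiling are re-split by a watershed on their distance
## transform (shape-based splitting); objects that remain over-size after
## this (genuine large structures) fall to the diameter filter
.splitOversize <- function(lab, ed_hi) {
  n <- max(lab)
  areas <- tabulate(lab, n)
  big <- which(2 * sqrt(areas / pi) > ed_hi)
  if (!length(big)) return(lab)
  out <- lab
  nxt <- n
  for (l in big) {
    idx <- which(lab == l)
    ys <- range((idx - 1L) %% nrow(lab) + 1L)
    xs <- range((idx - 1L) %/% nrow(lab) + 1L)
    sub <- lab[ys[1]:ys[2], xs[1]:xs[2], drop = FALSE] == l
    dm <- EBImage::distmap(EBImage::Image(sub * 1))
    ws <- EBImage::watershed(dm, tolerance = 0.5, ext = 1)
    wsm <- matrix(as.integer(EBImage::imageData(ws)), nrow(sub), ncol(sub))
    if (max(wsm) > 1L) {
      piece <- wsm[cbind((idx - 1L) %% nrow(lab) + 1L - ys[1] + 1L,
                         (idx - 1L) %/% nrow(lab) + 1L - xs[1] + 1L)]
      out[idx] <- nxt + piece
      nxt <- nxt + max(wsm)
    }
  }
  ## compact label ids
  u <- sort(unique(out[out > 0L]))
  map <- integer(max(u)); map[u] <- seq_along(u)
  out[out > 0L] <- map[out[out > 0L]]
  out
}

#' Colocalize puncta with the neurite mask
#'
#' A punctum is on-neurite iff its pixel set overlaps the mask in at least
#' one pixel (contained within or only partly touching). Adding mask
#' pixels can never un-flag a punctum, so the on-neurite count is monotone
#' in the mask.
#'
#' @param puncta result of [detectPuncta()].
#' @param mask logical neurite mask of the same frame.
#' @return \code{puncta} with the \code{on_neurite} column filled in.
#' @export
colocalize <- function(puncta, mask) {
  stopifnot(identical(dim(puncta$labels), dim(mask)))
  n <- nrow(puncta$table)
  if (n == 0L) return(puncta)
  hit <- tabulate(puncta$labels[mask & puncta$labels > 0L], n) > 0L
  puncta$table$on_neurite <- hit
  puncta
}

#' Assemble the four per-field measurements
#'
#' Emits the field-level readout of the assay: (1) the area covered by
#' dendrite-marker-positive neurites; (2) the number of presynaptic puncta
#' localized on those neurites; (3) the number of nuclei; (4) the total
#' area covered by presynaptic puncta (all retained puncta).
#'
#' @param neurite result of [segmentNeurites()] (or a bare logical mask).
#' @param puncta colocalized result of [colocalize()].
#' @param nuclei_count integer count of detected nuclei.
#' @return One-row data.frame (map2_area, syn_on_map2_count, nuclei_count,
#'   syn_total_area).
#' @export
measureField <- function(neurite, puncta, nuclei_count) {
  mask_area <- if (is.list(neurite)) neurite$area else sum(neurite > 0)
  tab <- puncta$table
  data.frame(
    map2_area = as.integer(mask_area),
    syn_on_map2_count = as.integer(sum(tab$on_neurite %in% TRUE)),
    nuclei_count = as.integer(nuclei_count),
    syn_total_area = as.integer(sum(tab$area)))
}

#' Process one field stack into its per-field measurements
#'
#' Chains the full pipeline for one field: maximum projection of each
#' channel, mutual-information alignment (dendrite vs. nuclear, same shift
#' applied to the presynaptic channel), optional plate-level illumination
#' correction, rescale to [0, 1], tubeness enhancement + three-class Otsu
#' neurite segmentation, speckle tophat + two-class Otsu + de-clump +
#' diameter-filtered puncta detection, colocalization and nucleus counting.
#'
#' @param stack a [FieldStack-class].
#' @param config a [PipelineConfig-class].
#' @param illumination optional named list of correction surfaces (nuclear,
#'   dendrite, presynaptic) from [buildIlluminationFunction()].
#' @param details return intermediate objects alongside the measurement row.
#' @return One-row data.frame (plate_id, well, field, map2_area,
#'   syn_on_map2_count, nuclei_count, syn_total_area, align_dy, align_dx),
#'   or with \code{details = TRUE} a list carrying the projected field,
#'   neurite segmentation and puncta set as well.
#' @export
processField <- function(stack, config = pipelineConfig(),
                         illumination = NULL, details = FALSE) {
  proj <- lapply(stack@channels, maxProject)
  pf <- alignChannels(proj$nuclear, proj$dendrite, proj$presynaptic, config)
  pl <- pf@planes
  if (!is.null(illumination))
    pl <- mapply(correctIllumination, pl, illumination[names(pl)],
                 SIMPLIFY = FALSE)
  pl <- lapply(pl, rescaleIntensity)
  res <- .measureAlignedPlanes(pl, stack@pixel_size, config)
  row <- cbind(data.frame(plate_id = stack@plate_id, well = stack@well,
                          field = stack@field_index,
                          stringsAsFactors = FALSE),
               res$measurement,
               data.frame(align_dy = pf@alignment_offset[1],
                          align_dx = pf@alignment_offset[2]))
  if (!details) return(row)
  list(measurement = row, field = pf, neurite = res$neurite,
       puncta = res$puncta)
}

## segmentation + measurement on already aligned/corrected/rescaled planes
.measureAlignedPlanes <- function(pl, pixel_size, config) {
  enh <- enhanceNeurites(pl$dendrite, config)
  neu <- segmentNeurites(enh, config)
  pun <- detectPuncta(pl$presynaptic, config)
  pun <- colocalize(pun, neu$mask)
  nuc <- detectNuclei(pl$nuclear, pixel_size,
                      min_diameter_um = config@nuclei_min_diameter_um,
                      smooth_sigma = config@nuclei_smooth_sigma)
  list(measurement = measureField(neu, pun, nrow(nuc)),
       neurite = neu, puncta = pun)
}

#' Process all fields of a plate
#'
#' Two-pass plate processing: every field is projected and aligned, the
#' plate-wide illumination functions are built per channel from the
#' aligned planes, and each field is then corrected, rescaled and
#' measured. Fields may be given as a list of [FieldStack-class] objects
#' or as a directory of per-field TIFFs written by [writeFieldTIFF()];
#' unreadable files are skipped and logged.
#'
#' @param fields list of [FieldStack-class] objects, or a directory path.
#' @param config a [PipelineConfig-class].
#' @param illumination_correction apply plate-level illumination
#'   correction (default TRUE).
#' @param pixel_size micrometers per pixel used when reading TIFFs.
#' @return list with \code{measurements} (data.frame, one row per
#'   processed field) and \code{skipped} (character vector of unreadable
#'   inputs).
#' @export
processPlate <- function(fields, config = pipelineConfig(),
                         illumination_correction = TRUE, pixel_size = 0.6) {
  skipped <- character(0)
  if (is.character(fields)) {
    paths <- sort(list.files(fields, pattern = "\\.tiff?$",
                             full.names = TRUE))
    loader <- function(p) tryCatch(readFieldTIFF(p, pixel_size = pixel_size),
                                   error = function(e) NULL)
  } else {
    paths <- seq_along(fields)
    loader <- function(i) fields[[i]]
  }
  aligned <- vector("list", length(paths))
  meta <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    st <- loader(paths[[i]])
    if (is.null(st)) { skipped <- c(skipped, as.character(paths[[i]])); next }
    proj <- lapply(st@channels, maxProject)
    pf <- alignChannels(proj$nuclear, proj$dendrite, proj$presynaptic, config)
    aligned[[i]] <- pf@planes
    meta[[i]] <- list(plate_id = st@plate_id, well = st@well,
                      field = st@field_index, px = st@pixel_size,
                      off = pf@alignment_offset)
  }
  ok <- which(!vapply(meta, is.null, logical(1)))
  illum <- NULL
  if (illumination_correction && length(ok)) {
    illum <- lapply(c("nuclear", "dendrite", "presynaptic"), function(ch)
      buildIlluminationFunction(lapply(aligned[ok], `[[`, ch), config))
    names(illum) <- c("nuclear", "dendrite", "presynaptic")
  }
  rows <- lapply(ok, function(i) {
    pl <- aligned[[i]]
    if (!is.null(illum))
      pl <- mapply(correctIllumination, pl, illum[names(pl)],
                   SIMPLIFY = FALSE)
    pl <- lapply(pl, rescaleIntensity)
    m <- meta[[i]]
    res <- .measureAlignedPlanes(pl, m$px, config)
    cbind(data.frame(plate_id = m$plate_id, well = m$well, field = m$field,
                     stringsAsFactors = FALSE),
          res$measurement,
          data.frame(align_dy = m$off[1], align_dx = m$off[2]))
  })
  list(measurements = do.call(rbind, rows), skipped = skipped)
}
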