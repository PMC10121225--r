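## Field TIFF convention: one multi-page 16-bit grayscale TIFF per field,
## pages ordered channel-major (all nuclear slices, then dendrite, then
## presynaptic), file name <plate>_<well>_f<field>.tif. Intensities are
## photon counts stored as value / 65535.

.TIFF_SCALE <- 65535

#' Write a field stack as a multi-page TIFF
#'
#' @param stack a [FieldStack-class].
#' @param dir output directory (created if needed).
#' @return The file path, invisibly.
#' @export
writeFieldTIFF <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s_f%02d.tif", stack@plate_id,
                                 stack@well, stack@field_index))
  pages <- list()
  for (ch in names(stack@channels)) {
    arr <- stack@channels[[ch]]
    for (s in seq_len(dim(arr)[1]))
      pages[[length(pages) + 1L]] <-
        pmin(matrix(arr[s, , ], dim(arr)[2], dim(arr)[3]) / .TIFF_SCALE, 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a field stack written by [writeFieldTIFF()]
#'
#' The well, plate and field index are recovered from the file name; the
#' page count must be divisible by the three channels.
#'
#' @param path TIFF path.
#' @param pixel_size micrometers per pixel (not stored in the TIFF).
#' @return A [FieldStack-class].
#' @export
readFieldTIFF <- function(path, pixel_size = 0.6) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% 3L != 0L)
    stop("page count not divisible by 3 channels: ", path)
  nz <- length(pages) %/% 3L
  nm <- sub("\\.tiff?$", "", basename(path))
  parts <- strsplit(nm, "_")[[1]]
  if (length(parts) < 3L) stop("unparseable field file name: ", path)
  stacks <- lapply(0:2, function(c0) {
    arr <- array(0, dim = c(nz, nrow(pages[[1]]), ncol(pages[[1]])))
    for (s in seq_len(nz)) arr[s, , ] <- pages[[c0 * nz + s]] * .TIFF_SCALE
    arr
  })
  names(stacks) <- c("nuclear", "dendrite", "presynaptic")
  new("FieldStack",
      plate_id = paste(parts[seq_len(length(parts) - 2L)], collapse = "_"),
      well = parts[length(parts) - 1L],
      field_index = as.integer(sub("^f", "", parts[length(parts)])),
      channels = stacks, pixel_size = pixel_size)
}

#' Ground truth as a flat CSV table
#'
#' One row per planted object (field_id, well, object_type, y, x,
#' equivalent_diameter, on_neurite, class).
#'
#' @param truth a [GroundTruth-class].
#' @param well,field_id identifiers stamped on the rows.
#' @return data.frame.
#' @export
groundTruthTable <- function(truth, well = "B02", field_id = 1L) {
  p <- truth@puncta; n <- truth@nuclei
  rbind(
    if (nrow(p)) data.frame(field_id = field_id, well = well,
                            object_type = "punctum", y = p$y, x = p$x,
                            equivalent_diameter = p$equivalent_diameter,
                            on_neurite = p$on_neurite, class = NA_character_,
                            stringsAsFactors = FALSE),
    if (nrow(n)) data.frame(field_id = field_id, well = well,
                            object_type = "nucleus", y = n$y, x = n$x,
                            equivalent_diameter = n$diameter,
                            on_neurite = NA, class = n$class,
                            stringsAsFactors = FALSE))
}

.FIELD_CSV_MAP <- c(
  map2_area = "AreaOccupied_MAP2PositiveNeurites",
  syn_on_map2_count = "Count_SYNAPSIN1PunctaOnMAP2PositiveNeurites",
  nuclei_count = "Count_Nuclei",
  syn_total_area = "AreaOccupied_SYNAPSIN1")

#' Write / read the field-level measurement CSV
#'
#' The external schema mirrors the pipeline's output naming: plate_id,
#' well, field, AreaOccupied_MAP2PositiveNeurites,
#' Count_SYNAPSIN1PunctaOnMAP2PositiveNeurites, Count_Nuclei,
#' AreaOccupied_SYNAPSIN1 (plus batch_id when present). A manifest comment
#' line (tool version, config hash, seed) is written first and skipped on
#' read.
#'
#' @param records data.frame in canonical column names.
#' @param path CSV path.
#' @param manifest optional manifest string for the leading comment line.
#' @return \code{path} invisibly / the canonical records data.frame.
#' @export
writeFieldCSV <- function(records, path, manifest = NULL) {
  out <- records
  for (nm in names(.FIELD_CSV_MAP))
    names(out)[names(out) == nm] <- .FIELD_CSV_MAP[[nm]]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(manifest)) writeLines(paste0("# ", manifest), con)
  write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFieldCSV
#' @export
readFieldCSV <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (nm in names(.FIELD_CSV_MAP))
    names(df)[names(df) == .FIELD_CSV_MAP[[nm]]] <- nm
  df
}
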