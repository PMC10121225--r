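## 96-well plate geometry: rows A-H (1-8), columns 1-12; the assay occupies
## the 60 inner wells (rows B-G, columns 2-11). Well labels are "B02" style.

#' Well labels for a 96-well plate
#'
#' @param row,col integer vectors (1-8, 1-12), recycled.
#' @return Character labels like \code{"B02"}.
#' @export
wellLabel <- function(row, col) sprintf("%s%02d", LETTERS[row], col)

#' Parse well labels
#'
#' @param well character labels like \code{"B02"}.
#' @return data.frame with integer \code{row} and \code{col}.
#' @export
parseWell <- function(well) {
  data.frame(row = match(substr(well, 1, 1), LETTERS),
             col = as.integer(substr(well, 2, 3)))
}

#' Construct a 96-well plate layout
#'
#' Builds the standard screening layout: 60 inner assay wells with two
#' designated vehicle-control columns, an outer ring excluded from the
#' assay, and an optional all-vehicle sentinel flag. Treated compounds are
#' assigned to the remaining inner wells in replicate blocks, filled
#' column-major.
#'
#' @param plate_id,batch_id identifiers.
#' @param control_cols two inner columns (within 2-11) of vehicle wells.
#' @param treatments \code{NULL}, or a character vector of compound ids, or
#'   a data.frame with columns \code{compound_id} and optionally
#'   \code{concentration}.
#' @param concentration default concentration attached to treatments
#'   (micromolar; the primary screen used 3).
#' @param n_replicates wells per condition on this plate (default 3,
#'   conditions in triplicate).
#' @param sentinel TRUE for an all-vehicle sentinel plate (treatments must
#'   then be NULL).
#' @return A [PlateLayout-class] object.
#' @examples
#' lay <- plateLayout96("P1", treatments = sprintf("cmpd%02d", 1:16))
#' length(assayWells(lay))    # 48 treated wells
#' length(controlWells(lay))  # 12 vehicle wells
#' @export
plateLayout96 <- function(plate_id, batch_id = "batch1",
                          control_cols = c(2L, 11L), treatments = NULL,
                          concentration = 3, n_replicates = 3L,
                          sentinel = FALSE) {
  stopifnot(length(control_cols) == 2L, all(control_cols %in% 2:11))
  grid <- expand.grid(row = 1:8, col = 1:12)
  grid <- grid[order(grid$col, grid$row), ]
  inner <- grid$row %in% 2:7 & grid$col %in% 2:11
  role <- ifelse(!inner, "excluded",
                 ifelse(grid$col %in% control_cols, "control", "assay"))
  w <- data.frame(well = wellLabel(grid$row, grid$col), row = grid$row,
                  col = grid$col, role = role,
                  compound_id = NA_character_, concentration = NA_real_,
                  replicate = NA_integer_, stringsAsFactors = FALSE)
  if (!is.null(treatments) && !sentinel) {
    if (is.character(treatments))
      treatments <- data.frame(compound_id = treatments,
                               concentration = concentration,
                               stringsAsFactors = FALSE)
    if (is.null(treatments$concentration))
      treatments$concentration <- concentration
    slots <- which(w$role == "assay")
    need <- nrow(treatments) * n_replicates
    if (need > length(slots))
      stop("too many treatments for the available assay wells")
    for (i in seq_len(nrow(treatments))) {
      idx <- slots[((i - 1L) * n_replicates + 1L):(i * n_replicates)]
      w$compound_id[idx] <- treatments$compound_id[i]
      w$concentration[idx] <- treatments$concentration[i]
      w$replicate[idx] <- seq_len(n_replicates)
    }
  }
  new("PlateLayout", plate_id = as.character(plate_id),
      batch_id = as.character(batch_id), wells = w, sentinel = sentinel)
}

#' Write / read a plate layout as YAML
#'
#' The YAML block stores plate and batch ids, the sentinel flag, the
#' control wells and the treatment map, and round-trips losslessly through
#' [layoutFromYAML()].
#'
#' @param layout a [PlateLayout-class].
#' @param path file path.
#' @return \code{layoutToYAML} returns \code{path} invisibly;
#'   \code{layoutFromYAML} returns a [PlateLayout-class].
#' @export
layoutToYAML <- function(layout, path) {
  w <- layout@wells
  tr <- w[!is.na(w$compound_id), ]
  treatments <- lapply(split(tr, tr$compound_id), function(g) list(
    compound_id = g$compound_id[1], concentration = g$concentration[1],
    wells = as.list(g$well), replicates = as.list(g$replicate)))
  names(treatments) <- NULL
  obj <- list(plate_id = layout@plate_id, batch_id = layout@batch_id,
              sentinel = layout@sentinel,
              control_wells = as.list(w$well[w$role == "control"]),
              assay_wells = as.list(w$well[w$role == "assay"]),
              treatments = treatments)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname layoutToYAML
#' @export
layoutFromYAML <- function(path) {
  obj <- yaml::read_yaml(path)
  grid <- expand.grid(row = 1:8, col = 1:12)
  grid <- grid[order(grid$col, grid$row), ]
  w <- data.frame(well = wellLabel(grid$row, grid$col), row = grid$row,
                  col = grid$col, role = "excluded",
                  compound_id = NA_character_, concentration = NA_real_,
                  replicate = NA_integer_, stringsAsFactors = FALSE)
  w$role[w$well %in% unlist(obj$control_wells)] <- "control"
  w$role[w$well %in% unlist(obj$assay_wells)] <- "assay"
  for (tr in obj$treatments) {
    idx <- match(unlist(tr$wells), w$well)
    w$compound_id[idx] <- tr$compound_id
    w$concentration[idx] <- tr$concentration
    w$replicate[idx] <- unlist(tr$replicates)
  }
  new("PlateLayout", plate_id = obj$plate_id, batch_id = obj$batch_id,
      wells = w, sentinel = isTRUE(obj$sentinel))
}
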