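#' Accessors for synaptoscreen containers
#'
#' Small accessor layer over the S4 slots: channel planes/stacks, image
#' geometry, layout well tables and ground-truth inventories.
#'
#' @param object a synaptoscreen S4 object.
#' @param name channel name (nuclear, dendrite, presynaptic).
#' @return The accessed component; see individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("getChannel", function(object, name) standardGeneric("getChannel"))
#' @rdname accessors
#' @export
setGeneric("imageShape", function(object) standardGeneric("imageShape"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("wellTable", function(object) standardGeneric("wellTable"))
#' @rdname accessors
#' @export
setGeneric("controlWells", function(object) standardGeneric("controlWells"))
#' @rdname accessors
#' @export
setGeneric("assayWells", function(object) standardGeneric("assayWells"))
#' @rdname accessors
#' @export
setGeneric("punctaTable", function(object) standardGeneric("punctaTable"))
#' @rdname accessors
#' @export
setGeneric("nucleiTable", function(object) standardGeneric("nucleiTable"))
#' @rdname accessors
#' @export
setGeneric("neuriteMask", function(object) standardGeneric("neuriteMask"))
#' @rdname accessors
#' @export
setGeneric("plantedDensity", function(object) standardGeneric("plantedDensity"))
#' @rdname accessors
#' @export
setGeneric("alignmentOffset",
           function(object) standardGeneric("alignmentOffset"))
#' @rdname accessors
#' @export
setGeneric("planes", function(object) standardGeneric("planes"))

#' @rdname accessors
setMethod("channelNames", "FieldStack", function(object) names(object@channels))
#' @rdname accessors
setMethod("getChannel", "FieldStack", function(object, name) {
  stopifnot(name %in% names(object@channels))
  object@channels[[name]]
})
#' @rdname accessors
setMethod("imageShape", "FieldStack",
          function(object) dim(object@channels[[1]])[2:3])
#' @rdname accessors
setMethod("pixelSize", "FieldStack", function(object) object@pixel_size)
#' @rdname accessors
setMethod("planes", "ProjectedField", function(object) object@planes)
#' @rdname accessors
setMethod("alignmentOffset", "ProjectedField",
          function(object) object@alignment_offset)
#' @rdname accessors
setMethod("wellTable", "PlateLayout", function(object) object@wells)
#' @rdname accessors
setMethod("controlWells", "PlateLayout", function(object)
  object@wells$well[object@wells$role == "control"])
#' @rdname accessors
setMethod("assayWells", "PlateLayout", function(object)
  object@wells$well[object@wells$role == "assay"])
#' @rdname accessors
setMethod("punctaTable", "GroundTruth", function(object) object@puncta)
#' @rdname accessors
setMethod("nucleiTable", "GroundTruth", function(object) object@nuclei)
#' @rdname accessors
setMethod("neuriteMask", "GroundTruth", function(object) object@neurite_mask)
#' @rdname accessors
setMethod("plantedDensity", "GroundTruth",
          function(object) object@planted_density)

setMethod("show", "FieldStack", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("FieldStack %s/%s field %d: 3 channels, %d slices, %d x %d px (%.2f um/px)\n",
              object@plate_id, object@well, object@field_index,
              d[1], d[2], d[3], object@pixel_size))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d puncta (%d on-neurite), %d nuclei, neurite area %d px, planted density %.4g\n",
              nrow(object@puncta), sum(object@puncta$on_neurite),
              nrow(object@nuclei), sum(object@neurite_mask > 0),
              object@planted_density))
})

setMethod("show", "PlateLayout", function(object) {
  w <- object@wells
  cat(sprintf("PlateLayout %s (batch %s)%s: %d assay, %d control wells, %d conditions\n",
              object@plate_id, object@batch_id,
              if (object@sentinel) " [sentinel]" else "",
              sum(w$role == "assay"), sum(w$role == "control"),
              length(unique(stats::na.omit(w$compound_id)))))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n",
      sprintf("  tubeness sigma %.3g px, tophat radius %.3g px\n",
              object@tubeness_sigma, object@tubeness_tophat_radius),
      sprintf("  illumination filter %.3g px; Otsu %d/%d classes (%d bins)\n",
              object@illumination_filter_size, object@neurite_otsu_classes,
              object@puncta_otsu_classes, object@otsu_bins),
      sprintf("  puncta diameter [%.3g, %.3g] px, speckle radius %.3g px\n",
              object@puncta_diameter_range[1], object@puncta_diameter_range[2],
              object@speckle_radius),
      sprintf("  alignment search +/-%d px, %d MI bins\n",
              object@alignment_search_radius, object@mi_histogram_bins))
})
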