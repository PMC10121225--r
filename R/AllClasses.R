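## Central S4 containers. Image planes are numeric matrices indexed [y, x]
## (row-major, 0-based coordinates in all reported centroids/offsets);
## z-stacks are n_slices x height x width arrays; intensities are
## photon-scale non-negative values until rescaleIntensity() maps to [0, 1].

#' FieldSpec: geometry and content of one synthetic field
#'
#' Describes a simulated microscope field: image geometry, stack depth,
#' neurite network, presynaptic puncta on and off the neurites, and nuclei
#' of the two cell classes (neuronal, astrocytic). Defaults emulate the
#' assay's acquisition: 5-8 z-slices per field, puncta of 1-6 px equivalent
#' diameter on clearly defined dendritic neurites, at 0.6 um/px.
#'
#' @slot image_shape integer (height, width) in pixels.
#' @slot n_slices integer number of z-slices (1-8).
#' @slot pixel_size micrometers per pixel.
#' @slot n_neurite_segments number of random-walk neurite polylines.
#' @slot neurite_width neurite width in pixels (dilation diameter).
#' @slot n_on_puncta,n_off_puncta puncta planted on / off the neurite mask.
#' @slot punctum_diameter_range (low, high) equivalent diameter in pixels.
#' @slot n_neuronal_nuclei,n_astrocyte_nuclei nucleus counts per class.
#' @slot neuronal_nucleus_diameter,astrocyte_nucleus_diameter mean diameter
#'   in micrometers for each class.
#' @slot background_level additive background (photons).
#' @slot punctum_amplitude peak punctum intensity above background (photons).
#' @slot neurite_amplitude,nucleus_amplitude channel signal amplitudes.
#' @slot noise_sd additive Gaussian read-noise SD (photons); Poisson shot
#'   noise is always applied on top of the signal.
#' @slot seed integer RNG seed; identical spec implies identical output.
#' @exportClass FieldSpec
setClass("FieldSpec", representation(
  image_shape = "integer", n_slices = "integer", pixel_size = "numeric",
  n_neurite_segments = "integer", neurite_width = "numeric",
  n_on_puncta = "integer", n_off_puncta = "integer",
  punctum_diameter_range = "numeric",
  n_neuronal_nuclei = "integer", n_astrocyte_nuclei = "integer",
  neuronal_nucleus_diameter = "numeric", astrocyte_nucleus_diameter = "numeric",
  background_level = "numeric", punctum_amplitude = "numeric",
  neurite_amplitude = "numeric", nucleus_amplitude = "numeric",
  noise_sd = "numeric", seed = "integer"))

setValidity("FieldSpec", function(object) {
  msg <- character()
  if (length(object@image_shape) != 2L || any(object@image_shape < 8L))
    msg <- c(msg, "image_shape must be two positive dimensions (>= 8 px)")
  if (object@n_slices < 1L || object@n_slices > 8L)
    msg <- c(msg, "n_slices must lie in [1, 8]")
  if (any(c(object@n_on_puncta, object@n_off_puncta,
            object@n_neuronal_nuclei, object@n_astrocyte_nuclei) < 0L))
    msg <- c(msg, "object counts must be non-negative")
  if (length(object@punctum_diameter_range) != 2L ||
      diff(object@punctum_diameter_range) < 0)
    msg <- c(msg, "punctum_diameter_range must be (low, high) with low <= high")
  if (object@pixel_size <= 0) msg <- c(msg, "pixel_size must be positive")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a FieldSpec
#'
#' @param image_shape integer (height, width) in pixels.
#' @param n_slices number of z-slices (default 6).
#' @param pixel_size micrometers per pixel (default 0.6).
#' @param n_neurite_segments number of neurite polylines (default 6).
#' @param neurite_width neurite width in pixels (default 4).
#' @param n_on_puncta,n_off_puncta planted puncta counts (defaults 60 / 20).
#' @param punctum_diameter_range equivalent-diameter range in pixels.
#' @param n_neuronal_nuclei,n_astrocyte_nuclei nucleus counts.
#' @param neuronal_nucleus_diameter,astrocyte_nucleus_diameter mean nucleus
#'   diameter per class, micrometers.
#' @param background_level,punctum_amplitude,neurite_amplitude,nucleus_amplitude
#'   photon-scale intensities.
#' @param noise_sd Gaussian read-noise SD.
#' @param seed integer RNG seed.
#' @return A [FieldSpec-class] object.
#' @examples
#' spec <- fieldSpec(image_shape = c(128L, 128L), n_on_puncta = 20L, seed = 3L)
#' @export
fieldSpec <- function(image_shape = c(256L, 256L), n_slices = 6L,
                      pixel_size = 0.6, n_neurite_segments = 6L,
                      neurite_width = 4, n_on_puncta = 60L, n_off_puncta = 20L,
                      punctum_diameter_range = c(2, 4),
                      n_neuronal_nuclei = 8L, n_astrocyte_nuclei = 5L,
                      neuronal_nucleus_diameter = 25,
                      astrocyte_nucleus_diameter = 30,
                      background_level = 10, punctum_amplitude = 120,
                      neurite_amplitude = 60, nucleus_amplitude = 90,
                      noise_sd = 2, seed = 1L) {
  new("FieldSpec", image_shape = as.integer(image_shape),
      n_slices = as.integer(n_slices), pixel_size = pixel_size,
      n_neurite_segments = as.integer(n_neurite_segments),
      neurite_width = neurite_width, n_on_puncta = as.integer(n_on_puncta),
      n_off_puncta = as.integer(n_off_puncta),
      punctum_diameter_range = as.numeric(punctum_diameter_range),
      n_neuronal_nuclei = as.integer(n_neuronal_nuclei),
      n_astrocyte_nuclei = as.integer(n_astrocyte_nuclei),
      neuronal_nucleus_diameter = neuronal_nucleus_diameter,
      astrocyte_nucleus_diameter = astrocyte_nucleus_diameter,
      background_level = background_level,
      punctum_amplitude = punctum_amplitude,
      neurite_amplitude = neurite_amplitude,
      nucleus_amplitude = nucleus_amplitude,
      noise_sd = noise_sd, seed = as.integer(seed))
}

#' ArtifactSpec: acquisition artifacts applied to a synthetic field
#'
#' Integer translational misalignment of the non-reference channels
#' (dendrite and presynaptic, relative to the nuclear reference) and a
#' multiplicative illumination plane \code{gain = a + b*y + c*x} plus an
#' optional radial vignette. These stress the alignment and
#' illumination-correction stages of the pipeline.
#'
#' @slot channel_shift integer (dy, dx) applied to both non-reference
#'   channels.
#' @slot illumination_gradient numeric (a, b, c) of the gain plane.
#' @slot vignette_strength non-negative radial attenuation coefficient.
#' @slot max_shift declared maximum shift magnitude (search radius bound).
#' @exportClass ArtifactSpec
setClass("ArtifactSpec", representation(
  channel_shift = "integer", illumination_gradient = "numeric",
  vignette_strength = "numeric", max_shift = "integer"))

setValidity("ArtifactSpec", function(object) {
  msg <- character()
  if (length(object@channel_shift) != 2L)
    msg <- c(msg, "channel_shift must be (dy, dx)")
  if (any(abs(object@channel_shift) > object@max_shift))
    msg <- c(msg, "channel_shift exceeds declared max_shift")
  if (length(object@illumination_gradient) != 3L)
    msg <- c(msg, "illumination_gradient must be (a, b, c)")
  if (object@vignette_strength < 0)
    msg <- c(msg, "vignette_strength must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an ArtifactSpec
#'
#' @param channel_shift integer (dy, dx) translation of the dendrite and
#'   presynaptic channels; default no shift.
#' @param illumination_gradient gain-plane coefficients (a, b, c); the gain
#'   at pixel (y, x) (0-based) is \code{a + b*y + c*x} and must stay
#'   positive over the image.
#' @param vignette_strength radial attenuation (0 disables).
#' @param max_shift declared maximum shift magnitude (default 10, matching
#'   the default alignment search radius).
#' @return An [ArtifactSpec-class] object.
#' @export
artifactSpec <- function(channel_shift = c(0L, 0L),
                         illumination_gradient = c(1, 0, 0),
                         vignette_strength = 0, max_shift = 10L) {
  new("ArtifactSpec", channel_shift = as.integer(channel_shift),
      illumination_gradient = as.numeric(illumination_gradient),
      vignette_strength = vignette_strength, max_shift = as.integer(max_shift))
}

#' FieldStack: one field's raw three-channel z-stack
#'
#' @slot plate_id,well,field_index acquisition identifiers.
#' @slot channels named list (nuclear, dendrite, presynaptic) of
#'   n_slices x height x width arrays sharing a common shape.
#' @slot pixel_size micrometers per pixel.
#' @exportClass FieldStack
setClass("FieldStack", representation(
  plate_id = "character", well = "character", field_index = "integer",
  channels = "list", pixel_size = "numeric"))

setValidity("FieldStack", function(object) {
  msg <- character()
  nm <- c("nuclear", "dendrite", "presynaptic")
  if (!identical(names(object@channels), nm))
    msg <- c(msg, "channels must be named nuclear, dendrite, presynaptic")
  dims <- lapply(object@channels, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1L)
    msg <- c(msg, "all channels must share shape")
  if (any(vapply(object@channels, function(ch) any(ch < 0), logical(1))))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ProjectedField: per-channel maximum projections after alignment
#'
#' @slot planes named list of 2-D planes (nuclear, dendrite, presynaptic).
#' @slot alignment_offset integer (dy, dx) applied to the non-reference
#'   channels.
#' @slot alignment_degenerate TRUE when alignment fell back to (0, 0)
#'   because a plane was constant.
#' @exportClass ProjectedField
setClass("ProjectedField", representation(
  planes = "list", alignment_offset = "integer",
  alignment_degenerate = "logical"))

#' GroundTruth: planted object inventory of a synthetic field
#'
#' @slot neurite_mask binary matrix of the true neurite footprint.
#' @slot puncta data.frame (y, x, equivalent_diameter, on_neurite), 0-based
#'   centroids.
#' @slot nuclei data.frame (y, x, diameter, class), diameter in pixels,
#'   class in neuronal/astrocytic.
#' @slot applied_shift integer (dy, dx) planted channel misalignment.
#' @slot planted_density on-neurite puncta per neurite-mask pixel.
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  neurite_mask = "matrix", puncta = "data.frame", nuclei = "data.frame",
  applied_shift = "integer", planted_density = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  on <- object@puncta[object@puncta$on_neurite, , drop = FALSE]
  if (nrow(on)) {
    idx <- cbind(round(on$y) + 1L, round(on$x) + 1L)
    if (!all(object@neurite_mask[idx] > 0))
      msg <- c(msg, "every on-neurite punctum must lie on the neurite mask")
  }
  area <- sum(object@neurite_mask > 0)
  if (area > 0 &&
      abs(object@planted_density - nrow(on) / area) > 1e-12)
    msg <- c(msg, "planted_density must equal on-neurite count / mask area")
  if (length(msg)) msg else TRUE
})

#' EffectMap: per-well treatment effects for a simulated plate
#'
#' Multiplier on planted on-neurite puncta density and a viability
#' multiplier on nuclei counts. Control wells must carry multiplier 1.
#'
#' @slot table data.frame (well, density_multiplier, viability_multiplier).
#' @exportClass EffectMap
setClass("EffectMap", representation(table = "data.frame"))

setValidity("EffectMap", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("well", "density_multiplier", "viability_multiplier")
  if (!all(need %in% names(tb)))
    msg <- c(msg, "table needs well, density_multiplier, viability_multiplier")
  else {
    if (any(tb$density_multiplier <= 0))
      msg <- c(msg, "density multipliers must be > 0")
    if (any(tb$viability_multiplier <= 0 | tb$viability_multiplier > 1))
      msg <- c(msg, "viability multipliers must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EffectMap
#'
#' @param well character well labels (e.g. "B02").
#' @param density_multiplier per-well multiplier on planted on-neurite
#'   puncta density (> 0; 1 = no effect).
#' @param viability_multiplier per-well multiplier on nuclei counts
#'   ((0, 1]; 1 = no toxicity).
#' @return An [EffectMap-class] object.
#' @export
effectMap <- function(well, density_multiplier = 1,
                      viability_multiplier = 1) {
  new("EffectMap", table = data.frame(
    well = as.character(well),
    density_multiplier = rep_len(density_multiplier, length(well)),
    viability_multiplier = rep_len(viability_multiplier, length(well)),
    stringsAsFactors = FALSE))
}

#' PlateLayout: roles and treatments over a 96-well grid
#'
#' The assay uses the 60 inner wells of a 96-well plate (rows B-G, columns
#' 2-11); two inner columns are vehicle controls (0.1\% DMSO) to guard
#' against edge effects, and whole plates may be flagged sentinel
#' (all-vehicle, used for batch drift estimation). Treated conditions are
#' laid out in triplicate wells within a batch.
#'
#' @slot plate_id,batch_id identifiers.
#' @slot wells data.frame (well, row, col, role, compound_id,
#'   concentration, replicate); role in assay/control/excluded.
#' @slot sentinel logical, TRUE for an all-vehicle sentinel plate.
#' @exportClass PlateLayout
setClass("PlateLayout", representation(
  plate_id = "character", batch_id = "character", wells = "data.frame",
  sentinel = "logical"))

setValidity("PlateLayout", function(object) {
  w <- object@wells
  msg <- character()
  if (nrow(w) != 96L) msg <- c(msg, "layout must enumerate all 96 wells")
  inner <- w$row %in% 2:7 & w$col %in% 2:11
  if (any(w$role == "control" & !inner))
    msg <- c(msg, "control wells must be inner wells")
  if (sum(w$role %in% c("assay", "control") & inner) != 60L)
    msg <- c(msg, "the 60 inner wells must be assay or control")
  if (object@sentinel && any(!is.na(w$compound_id)))
    msg <- c(msg, "sentinel plates carry vehicle only")
  if (length(msg)) msg else TRUE
})

#' PipelineConfig: tunable parameters of the imaging pipeline
#'
#' @slot tubeness_sigma Gaussian scale of the neurite ridge filter (px).
#' @slot tubeness_tophat_radius disk radius of the white tophat applied
#'   after the ridge measure (px).
#' @slot illumination_filter_size Gaussian filter size for the plate-wide
#'   illumination function (px).
#' @slot puncta_diameter_range retained equivalent-diameter range (px).
#' @slot speckle_radius disk radius of the puncta white tophat (px); the
#'   default 5 is the smallest disk whose opening fully reconstructs (and
#'   the tophat therefore fully suppresses) objects of diameter 10 px and
#'   above, well clear of the 6 px maximum punctum diameter.
#' @slot speckle_noise_floor robust noise gate for puncta binarization: the
#'   effective threshold is the maximum of the two-class Otsu threshold and
#'   median + k * MAD of the speckle-enhanced plane (k = this slot, default 7; 0
#'   disables the gate). Prevents shot-noise speckles from being segmented
#'   on signal-free fields.
#' @slot neurite_otsu_classes,puncta_otsu_classes Otsu class counts (3 / 2).
#' @slot neurite_foreground "middle_upper" (default) or "upper": which Otsu
#'   classes form the neurite mask.
#' @slot alignment_search_radius integer shift window half-width (px).
#' @slot mi_histogram_bins joint-histogram bins for mutual information.
#' @slot otsu_bins histogram bins for Otsu thresholding on [0, 1].
#' @slot declump_tolerance,declump_ext watershed de-clumping parameters
#'   (minimum saddle depth; neighbourhood radius controlling minimum seed
#'   separation).
#' @slot nuclei_min_diameter_um,nuclei_smooth_sigma nucleus counting inside
#'   the field pipeline (all DAPI-positive nuclei, not the plating-QC
#'   neuronal subset).
#' @exportClass PipelineConfig
setClass("PipelineConfig", representation(
  tubeness_sigma = "numeric", tubeness_tophat_radius = "numeric",
  illumination_filter_size = "numeric", puncta_diameter_range = "numeric",
  speckle_radius = "numeric", speckle_noise_floor = "numeric",
  neurite_otsu_classes = "integer",
  puncta_otsu_classes = "integer", neurite_foreground = "character",
  alignment_search_radius = "integer", mi_histogram_bins = "integer",
  otsu_bins = "integer", declump_tolerance = "numeric",
  declump_ext = "integer", nuclei_min_diameter_um = "numeric",
  nuclei_smooth_sigma = "numeric"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@tubeness_sigma <= 0) msg <- c(msg, "tubeness_sigma must be > 0")
  if (diff(object@puncta_diameter_range) < 0)
    msg <- c(msg, "puncta_diameter_range must be (low, high)")
  if (!object@neurite_otsu_classes %in% c(2L, 3L) ||
      !object@puncta_otsu_classes %in% c(2L, 3L))
    msg <- c(msg, "Otsu class counts must be 2 or 3")
  if (!object@neurite_foreground %in% c("middle_upper", "upper"))
    msg <- c(msg, "neurite_foreground must be 'middle_upper' or 'upper'")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' Defaults mirror the published analysis settings: tubeness at scale
#' sigma = 2, illumination smoothing with a 100 x 100 px filter, puncta
#' retained in the 1-6 px equivalent-diameter range, three-class Otsu for
#' neurites and two-class for puncta.
#'
#' @param tubeness_sigma,tubeness_tophat_radius,illumination_filter_size,puncta_diameter_range,speckle_radius,speckle_noise_floor,neurite_otsu_classes,puncta_otsu_classes,neurite_foreground,alignment_search_radius,mi_histogram_bins,otsu_bins,declump_tolerance,declump_ext,nuclei_min_diameter_um,nuclei_smooth_sigma
#'   see [PipelineConfig-class].
#' @return A [PipelineConfig-class] object.
#' @export
pipelineConfig <- function(tubeness_sigma = 2, tubeness_tophat_radius = 8,
                           illumination_filter_size = 100,
                           puncta_diameter_range = c(1, 6),
                           speckle_radius = 5, speckle_noise_floor = 7,
                           neurite_otsu_classes = 3L,
                           puncta_otsu_classes = 2L,
                           neurite_foreground = "middle_upper",
                           alignment_search_radius = 10L,
                           mi_histogram_bins = 64L, otsu_bins = 256L,
                           declump_tolerance = 0.05, declump_ext = 2L,
                           nuclei_min_diameter_um = 8,
                           nuclei_smooth_sigma = 2) {
  new("PipelineConfig", tubeness_sigma = tubeness_sigma,
      tubeness_tophat_radius = tubeness_tophat_radius,
      illumination_filter_size = illumination_filter_size,
      puncta_diameter_range = as.numeric(puncta_diameter_range),
      speckle_radius = speckle_radius,
      speckle_noise_floor = speckle_noise_floor,
      neurite_otsu_classes = as.integer(neurite_otsu_classes),
      puncta_otsu_classes = as.integer(puncta_otsu_classes),
      neurite_foreground = neurite_foreground,
      alignment_search_radius = as.integer(alignment_search_radius),
      mi_histogram_bins = as.integer(mi_histogram_bins),
      otsu_bins = as.integer(otsu_bins),
      declump_tolerance = declump_tolerance,
      declump_ext = as.integer(declump_ext),
      nuclei_min_diameter_um = nuclei_min_diameter_um,
      nuclei_smooth_sigma = nuclei_smooth_sigma)
}

#' QCThresholds: plate acceptance thresholds
#'
#' Plating-consistency acceptance bands: between 4000 and 12,000 detected
#' neuronal nuclei per well and an intra-plate covariance (100 * SD / mean)
#' below 8\%. Nuclei are detected with a minimum diameter of 20 micrometers.
#'
#' @slot min_nuclei_per_well,max_nuclei_per_well per-well count band.
#' @slot max_covariance_pct intra-plate covariance ceiling (percent).
#' @slot min_nucleus_diameter minimum nucleus diameter (micrometers).
#' @slot band_fraction fraction of assay wells that must fall inside the
#'   count band for the plate to pass. The default 1 is strict -- a single
#'   well outside the 4000-12,000 band fails the plate -- with the
#'   fraction configurable for laxer policies.
#' @exportClass QCThresholds
setClass("QCThresholds", representation(
  min_nuclei_per_well = "numeric", max_nuclei_per_well = "numeric",
  max_covariance_pct = "numeric", min_nucleus_diameter = "numeric",
  band_fraction = "numeric"))

setValidity("QCThresholds", function(object) {
  msg <- character()
  if (object@min_nuclei_per_well >= object@max_nuclei_per_well)
    msg <- c(msg, "min_nuclei_per_well must be below max_nuclei_per_well")
  if (any(c(object@min_nuclei_per_well, object@max_covariance_pct,
            object@min_nucleus_diameter) <= 0))
    msg <- c(msg, "thresholds must be positive")
  if (object@band_fraction <= 0 || object@band_fraction > 1)
    msg <- c(msg, "band_fraction must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct QCThresholds
#'
#' @param min_nuclei_per_well,max_nuclei_per_well,max_covariance_pct,min_nucleus_diameter,band_fraction
#'   see [QCThresholds-class].
#' @return A [QCThresholds-class] object.
#' @export
qcThresholds <- function(min_nuclei_per_well = 4000,
                         max_nuclei_per_well = 12000,
                         max_covariance_pct = 8, min_nucleus_diameter = 20,
                         band_fraction = 1) {
  new("QCThresholds", min_nuclei_per_well = min_nuclei_per_well,
      max_nuclei_per_well = max_nuclei_per_well,
      max_covariance_pct = max_covariance_pct,
      min_nucleus_diameter = min_nucleus_diameter,
      band_fraction = band_fraction)
}
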