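#' Generate a synthetic plate of fields with planted ground truth
#'
#' Emits \code{fields_per_well} fields for every inner (assay + control)
#' well of the layout. Per-well treatment effects are applied through the
#' [EffectMap-class]: planted on/off puncta counts and nuclei counts are
#' Poisson draws around the base spec's values scaled by the well's
#' density and viability multipliers, so the truth table carries realistic
#' sampling error (puncta draws are truncated at twice their mean and
#' nuclei draws at mean + 2, keeping the per-field object budget
#' bounded). All randomness derives deterministically from
#' \code{seed} via a per-field seed
#' \code{(seed + 7919 * k) mod (2^31 - 1)} with \code{k} the global field
#' counter.
#'
#' @param layout a [PlateLayout-class].
#' @param base_spec a [FieldSpec-class] (per-field geometry and base
#'   counts).
#' @param effects an [EffectMap-class] or NULL (no effects). Control wells
#'   must carry multiplier 1; referencing a well outside the layout's
#'   inner wells is an error.
#' @param fields_per_well fields per well (the assay acquires 12).
#' @param artifacts an [ArtifactSpec-class] applied to every field.
#' @param seed top-level seed (default: the spec's seed).
#' @param dir when given, each field is written as TIFF into \code{dir}
#'   and dropped from memory (stacks are returned as NULL).
#' @param keep_truth keep the per-field [GroundTruth-class] objects.
#' @return list with \code{stacks} (list or NULL), \code{truths} (list or
#'   NULL), \code{truth_table} (one row per field: plate_id, well, field,
#'   n_on, n_off, mask_area, planted_density, density_multiplier,
#'   viability_multiplier) and \code{files}.
#' @export
generatePlate <- function(layout, base_spec, effects = NULL,
                          fields_per_well = 12L,
                          artifacts = artifactSpec(),
                          seed = base_spec@seed, dir = NULL,
                          keep_truth = FALSE) {
  w <- layout@wells
  inner <- w[w$role %in% c("assay", "control"), , drop = FALSE]
  mult <- setNames(rep(1, nrow(inner)), inner$well)
  viab <- mult
  if (!is.null(effects)) {
    validObject(effects)
    tb <- effects@table
    bad <- !(tb$well %in% inner$well)
    if (any(bad))
      stop("effect map references wells outside the layout: ",
           paste(tb$well[bad], collapse = ", "))
    ctrl <- inner$well[inner$role == "control"]
    off <- tb$well %in% ctrl &
      (tb$density_multiplier != 1 | tb$viability_multiplier != 1)
    if (any(off))
      stop("control wells must carry multiplier 1: ",
           paste(tb$well[off], collapse = ", "))
    mult[tb$well] <- tb$density_multiplier
    viab[tb$well] <- tb$viability_multiplier
  }
  stacks <- if (is.null(dir)) list() else NULL
  truths <- if (keep_truth) list() else NULL
  files <- character(0)
  rows <- vector("list", nrow(inner) * fields_per_well)
  k <- 0L
  for (wi in seq_len(nrow(inner))) {
    wl <- inner$well[wi]
    for (f in seq_len(fields_per_well)) {
      k <- k + 1L
      fseed <- as.integer((as.numeric(seed) + 7919 * k) %% 2147483647)
      lam <- c(mult[wl] * base_spec@n_on_puncta, base_spec@n_off_puncta,
               viab[wl] * base_spec@n_neuronal_nuclei,
               viab[wl] * base_spec@n_astrocyte_nuclei)
      ## Poisson draws truncated (puncta at twice the mean, nuclei at
      ## mean + 2): keeps the per-field object budget and nucleus
      ## placement feasible; negligible mass at the default counts
      cap <- c(ceiling(2 * lam[1:2]), ceiling(lam[3:4] + 2))
      counts <- withr::with_seed(fseed, as.integer(
        pmin(rpois(4, lam), cap)))
      spec_f <- base_spec
      spec_f@n_on_puncta <- counts[1]
      spec_f@n_off_puncta <- counts[2]
      spec_f@n_neuronal_nuclei <- counts[3]
      spec_f@n_astrocyte_nuclei <- counts[4]
      spec_f@seed <- as.integer((fseed + 1) %% 2147483647)
      fl <- generateField(spec_f, artifacts, plate_id = layout@plate_id,
                          well = wl, field_index = f)
      area <- sum(fl$truth@neurite_mask > 0)
      rows[[k]] <- data.frame(
        plate_id = layout@plate_id, well = wl, field = f,
        n_on = counts[1], n_off = counts[2], mask_area = area,
        planted_density = if (area > 0) counts[1] / area else NA_real_,
        density_multiplier = mult[wl], viability_multiplier = viab[wl],
        stringsAsFactors = FALSE)
      if (is.null(dir)) stacks[[k]] <- fl$stack
      else files <- c(files, writeFieldTIFF(fl$stack, dir))
      if (keep_truth) truths[[k]] <- fl$truth
    }
  }
  list(stacks = stacks, truths = truths,
       truth_table = do.call(rbind, rows), files = files)
}
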