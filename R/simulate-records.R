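#' Simulate field-level measurement records for a screen
#'
#' A fast table-level counterpart of rendering and re-measuring whole
#' plates: draws per-field measurements directly from the generative
#' statistical model underlying the field simulator (truncated-normal
#' neurite area; Poisson on-neurite puncta counts at
#' \code{base_density * area} scaled by per-condition effect multipliers;
#' Poisson nuclei counts scaled by viability). Used to exercise the
#' analytics layer (QC filters, normalization, hit calling) at realistic
#' screen scale — many plates, 12 fields per well — where image rendering
#' would be disproportionate.
#'
#' @param layouts [PlateLayout-class] or list of them.
#' @param effects named numeric vector of density multipliers by
#'   \code{compound_id} (unlisted compounds and vehicle get 1).
#' @param viability named numeric vector of viability multipliers by
#'   compound (default 1).
#' @param fields_per_well fields per well (default 12).
#' @param base_density on-neurite puncta per neurite-area pixel under
#'   vehicle (default 0.004).
#' @param map2_area_mean,map2_area_sd per-field neurite area (px).
#' @param nuclei_mean per-field nuclei count under full viability.
#' @param punctum_area_mean mean retained punctum area (px), used for the
#'   total puncta area column.
#' @param row_gradient optional multiplicative row drift on density: the
#'   mean is scaled by \code{1 + row_gradient * (row - 4.5) / 3.5} (rows
#'   1-8), emulating an intra-plate edge/drift pattern.
#' @param seed integer seed.
#' @return Field records data.frame with canonical columns (batch_id,
#'   plate_id, well, field, map2_area, syn_on_map2_count, nuclei_count,
#'   syn_total_area).
#' @export
simulateFieldRecords <- function(layouts, effects = numeric(0),
                                 viability = numeric(0),
                                 fields_per_well = 12L,
                                 base_density = 0.004,
                                 map2_area_mean = 6000, map2_area_sd = 900,
                                 nuclei_mean = 60, punctum_area_mean = 7,
                                 row_gradient = 0, seed = 1L) {
  layouts <- .layoutList(layouts)
  withr::with_seed(as.integer(seed), {
    out <- lapply(layouts, function(lay) {
      w <- lay@wells
      inner <- w[w$role %in% c("assay", "control"), , drop = FALSE]
      rows <- lapply(seq_len(nrow(inner)), function(i) {
        cmpd <- inner$compound_id[i]
        m <- if (!is.na(cmpd) && cmpd %in% names(effects))
          effects[[cmpd]] else 1
        v <- if (!is.na(cmpd) && cmpd %in% names(viability))
          viability[[cmpd]] else 1
        drift <- 1 + row_gradient * (inner$row[i] - 4.5) / 3.5
        area <- pmax(rnorm(fields_per_well, map2_area_mean, map2_area_sd),
                     0.2 * map2_area_mean)
        count <- rpois(fields_per_well, base_density * m * drift * area)
        nuc <- rpois(fields_per_well, nuclei_mean * v)
        data.frame(batch_id = lay@batch_id, plate_id = lay@plate_id,
                   well = inner$well[i], field = seq_len(fields_per_well),
                   map2_area = area, syn_on_map2_count = count,
                   nuclei_count = nuc,
                   syn_total_area = round(count * punctum_area_mean *
                                            runif(fields_per_well, .9, 1.1)),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}
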