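## End-to-end orchestration: simulate -> process -> analyze, with a
## manifest (tool version, config hash, seed) stamped on every output so
## reruns are auditable and bit-identical under a fixed seed.

.configHash <- function(obj) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(obj, tmp)
  unname(tools::md5sum(tmp))
}

.manifest <- function(config_hash, seed) {
  sprintf("synaptoscreen %s config=%s seed=%d",
          as.character(packageVersion("synaptoscreen")), config_hash,
          as.integer(seed))
}

#' Run the field pipeline over a (simulated or stored) plate
#'
#' Chains simulation and image processing: generates a synthetic plate
#' for the layout (or consumes an existing TIFF directory), processes
#' every field through the imaging pipeline, and writes the field-level
#' measurement CSV plus, for simulated plates, the planted-truth CSV.
#' Reruns with the same configuration and seed are bit-identical;
#' unreadable fields are skipped and logged in the manifest sidecar.
#'
#' @param layout a [PlateLayout-class].
#' @param out_dir output directory.
#' @param spec a [FieldSpec-class] for simulation, or NULL when
#'   \code{image_dir} is given.
#' @param effects optional [EffectMap-class] for simulation.
#' @param artifacts an [ArtifactSpec-class] for simulation.
#' @param fields_per_well fields per well for simulation.
#' @param image_dir existing directory of field TIFFs to process instead
#'   of simulating.
#' @param config a [PipelineConfig-class].
#' @param seed top-level seed.
#' @param write_images also write the simulated TIFFs under
#'   \code{out_dir/fields}.
#' @return list with \code{fields_csv}, \code{records}, \code{truth_table}
#'   (NULL for stored plates), \code{skipped} and \code{manifest}.
#' @export
runFieldPipeline <- function(layout, out_dir, spec = fieldSpec(),
                             effects = NULL, artifacts = artifactSpec(),
                             fields_per_well = 12L, image_dir = NULL,
                             config = pipelineConfig(), seed = spec@seed,
                             write_images = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- .configHash(list(
    layout = layout@plate_id, fields_per_well = fields_per_well,
    config = capture.output(show(config)), seed = as.integer(seed)))
  man <- .manifest(hash, seed)
  truth_table <- NULL
  if (is.null(image_dir)) {
    sim_dir <- if (write_images) file.path(out_dir, "fields") else NULL
    plate <- generatePlate(layout, spec, effects = effects,
                           fields_per_well = fields_per_well,
                           artifacts = artifacts, seed = seed,
                           dir = sim_dir)
    truth_table <- plate$truth_table
    src <- if (write_images) sim_dir else plate$stacks
  } else src <- image_dir
  res <- processPlate(src, config = config, pixel_size = spec@pixel_size)
  rec <- res$measurements
  rec$batch_id <- layout@batch_id
  fields_csv <- file.path(out_dir, "fields.csv")
  writeFieldCSV(rec, fields_csv, manifest = man)
  if (!is.null(truth_table)) {
    con <- file(file.path(out_dir, "truth.csv"), "w")
    writeLines(paste0("# ", man), con)
    write.csv(truth_table, con, row.names = FALSE)
    close(con)
  }
  info <- list(manifest = man, seed = as.integer(seed),
               n_fields = nrow(rec), n_skipped = length(res$skipped),
               skipped = as.list(res$skipped))
  jsonlite::write_json(info, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(fields_csv = fields_csv, records = rec, truth_table = truth_table,
       skipped = res$skipped, manifest = man)
}

#' Run the screen-analytics chain over field records
#'
#' Applies the three QC filters (field area band, >= 5 fields/well,
#' >= 2 of 3 wells/condition), optional pattern correction, computes
#' percent-of-control and intra-plate Z-scores, aggregates to conditions
#' and calls hits. Writes well-level, condition-level and rejection CSVs
#' plus a JSON report (per-plate control z means, per-class counts and
#' library fractions).
#'
#' @param records field records data.frame (canonical columns) or a
#'   fields.csv path.
#' @param layouts [PlateLayout-class] or list covering every plate in the
#'   records.
#' @param out_dir output directory (NULL skips writing).
#' @param pattern_correct apply [patternCorrect()] (default FALSE).
#' @param min_fields,min_wells QC minima.
#' @param scope field-filter scope ("batch" or "plate").
#' @param hit_rules list of thresholds passed to [callHits()].
#' @param seed recorded in the manifest (analytics are deterministic).
#' @return list with \code{wells}, \code{conditions}, \code{rejections},
#'   \code{report} and output paths.
#' @export
runScreen <- function(records, layouts, out_dir = NULL,
                      pattern_correct = FALSE, min_fields = 5L,
                      min_wells = 2L, scope = "batch",
                      hit_rules = list(), seed = 0L) {
  if (is.character(records)) records <- readFieldCSV(records)
  layouts <- .layoutList(layouts)
  ff <- filterFields(records, scope = scope)
  fw <- filterWellsAndConditions(ff$kept, layouts, min_fields = min_fields,
                                 min_wells = min_wells)
  wells <- fw$wells
  if (pattern_correct) wells <- patternCorrect(wells, layouts)
  wells <- percentOfControl(wells)
  wells <- zscoreWells(wells)
  conditions <- conditionSummary(wells, min_wells = min_wells)
  conditions <- do.call(callHits, c(list(conditions), hit_rules))
  ctrl_z <- vapply(split(wells, wells$plate_id), function(g) {
    cz <- g$z_density[g$role == "control" & g$qc_pass]
    if (length(cz)) mean(cz) else NA_real_
  }, numeric(1))
  n_cond <- nrow(conditions)
  counts <- table(factor(conditions$hit_class,
                         levels = c("enhancer_candidate", "toxic",
                                    "inactive", "qc_fail")))
  report <- list(
    n_fields_in = nrow(records), n_fields_kept = nrow(ff$kept),
    n_wells = nrow(wells), n_wells_pass = sum(wells$qc_pass),
    n_conditions = n_cond,
    control_z_mean_per_plate = as.list(ctrl_z),
    hit_counts = as.list(counts),
    library_fractions = if (n_cond)
      as.list(libraryFractions(conditions, n_cond)) else list(),
    pattern_corrected = pattern_correct, seed = as.integer(seed))
  paths <- list()
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    hash <- .configHash(list(min_fields = min_fields, min_wells = min_wells,
                             scope = scope, pattern = pattern_correct))
    man <- .manifest(hash, seed)
    wcsv <- file.path(out_dir, "wells.csv")
    ccsv <- file.path(out_dir, "conditions.csv")
    rcsv <- file.path(out_dir, "rejections.csv")
    for (p in list(list(wells, wcsv), list(conditions, ccsv))) {
      con <- file(p[[2]], "w")
      writeLines(paste0("# ", man), con)
      write.csv(p[[1]], con, row.names = FALSE)
      close(con)
    }
    rej <- ff$rejected
    con <- file(rcsv, "w")
    writeLines(paste0("# ", man), con)
    write.csv(rej, con, row.names = FALSE)
    close(con)
    report$manifest <- man
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    paths <- list(wells_csv = wcsv, conditions_csv = ccsv,
                  rejections_csv = rcsv,
                  report_json = file.path(out_dir, "report.json"))
  }
  c(list(wells = wells, conditions = conditions, rejections = ff$rejected,
         report = report), paths)
}
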