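## Field -> well -> condition analytics. Field records use the canonical
## columns plate_id, well, field, map2_area, syn_on_map2_count,
## nuclei_count, syn_total_area (+ batch_id); the external CSV uses the
## pipeline's long column names (see writeFieldCSV / readFieldCSV).

.metricCols <- c("density", "map2_area", "nuclei_count", "syn_total_area")

#' Presynaptic density
#'
#' Number of on-neurite presynaptic puncta divided by the neurite area
#' (puncta per pixel). Records with zero area are undefined and return NA
#' (flagged and excluded downstream).
#'
#' @param count on-neurite puncta count(s).
#' @param area neurite area(s) in pixels.
#' @return Numeric density, NA where \code{area <= 0}.
#' @export
synDensity <- function(count, area) {
  ifelse(area > 0, count / area, NA_real_)
}

#' Field-level quality-control filter
#'
#' Removes fields whose neurite (dendrite-marker) area lies outside the
#' band mean +/- SD computed over all fields in scope (the whole batch by
#' default, or per plate); bounds are inclusive. A scope with a single
#' field is kept with a warning.
#'
#' @param records field records data.frame (needs \code{map2_area}; scoped
#'   by \code{batch_id} or \code{plate_id}).
#' @param scope "batch" (default) or "plate".
#' @return list with \code{kept}, \code{rejected} (with a \code{reason}
#'   column) and \code{band} (per-scope mean/sd/bounds).
#' @export
filterFields <- function(records, scope = c("batch", "plate")) {
  scope <- match.arg(scope)
  key <- if (scope == "batch") {
    if (is.null(records$batch_id)) rep("all", nrow(records))
    else records$batch_id
  } else records$plate_id
  keep <- logical(nrow(records))
  bands <- list()
  for (g in unique(key)) {
    sel <- which(key == g)
    a <- records$map2_area[sel]
    if (length(sel) < 2L) {
      warning("QC scope with a single field: kept without banding")
      keep[sel] <- TRUE
      bands[[g]] <- data.frame(scope = g, mean = mean(a), sd = NA_real_,
                               lower = -Inf, upper = Inf)
      next
    }
    mu <- mean(a); s <- sd(a)
    keep[sel] <- a >= mu - s & a <= mu + s
    bands[[g]] <- data.frame(scope = g, mean = mu, sd = s,
                             lower = mu - s, upper = mu + s)
  }
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- "map2_area outside mean +/- SD band"
  list(kept = records[keep, , drop = FALSE], rejected = rejected,
       band = do.call(rbind, bands))
}

#' Condense surviving fields to wells and conditions
#'
#' Wells retaining at least \code{min_fields} fields (default 5) after the
#' field filter are kept; each well metric is the mean over its surviving
#' fields, except density, which is the ratio of well-level aggregates
#' (total on-neurite puncta / total neurite area). Conditions (compounds)
#' with at least \code{min_wells} surviving wells (default 2 of the 3
#' replicates) are retained; others are flagged \code{qc_fail}.
#'
#' @param records field-filtered records.
#' @param layouts a [PlateLayout-class] or list of them (matched to
#'   records by \code{plate_id}).
#' @param min_fields,min_wells QC minima.
#' @return list with \code{wells} (per-well table with \code{qc_pass}),
#'   \code{conditions} (per-condition table with \code{n_wells_used} and
#'   \code{hit_class} qc_fail/pending) and \code{rejected_wells}.
#' @export
filterWellsAndConditions <- function(records, layouts, min_fields = 5L,
                                     min_wells = 2L) {
  layouts <- .layoutList(layouts)
  .checkRecordWells(records, layouts)
  key <- paste(records$plate_id, records$well, sep = "/")
  agg <- function(x, f) as.numeric(tapply(x, factor(key, unique(key)), f))
  u <- !duplicated(key)
  wells <- data.frame(
    plate_id = records$plate_id[u], well = records$well[u],
    batch_id = if (is.null(records$batch_id)) "batch1"
               else records$batch_id[u],
    n_fields = agg(records$map2_area, length),
    map2_area = agg(records$map2_area, mean),
    syn_on_map2_count = agg(records$syn_on_map2_count, mean),
    nuclei_count = agg(records$nuclei_count, mean),
    syn_total_area = agg(records$syn_total_area, mean),
    density = agg(records$syn_on_map2_count, sum) /
      pmax(agg(records$map2_area, sum), .Machine$double.eps),
    stringsAsFactors = FALSE)
  zero_area <- agg(records$map2_area, sum) <= 0
  wells$density[zero_area] <- NA_real_
  wells$qc_pass <- wells$n_fields >= min_fields & !is.na(wells$density)
  lk <- .wellRoles(layouts)
  m <- match(paste(wells$plate_id, wells$well), paste(lk$plate_id, lk$well))
  wells$role <- lk$role[m]
  wells$compound_id <- lk$compound_id[m]
  wells$concentration <- lk$concentration[m]
  rejected <- wells[!wells$qc_pass, , drop = FALSE]
  conditions <- .conditionTable(wells, min_wells)
  list(wells = wells, conditions = conditions, rejected_wells = rejected)
}

.layoutList <- function(layouts) {
  if (is(layouts, "PlateLayout")) layouts <- list(layouts)
  names(layouts) <- vapply(layouts, function(l) l@plate_id, "")
  layouts
}

.wellRoles <- function(layouts) {
  do.call(rbind, lapply(layouts, function(l) {
    w <- l@wells
    data.frame(plate_id = l@plate_id, well = w$well, role = w$role,
               compound_id = w$compound_id, concentration = w$concentration,
               stringsAsFactors = FALSE)
  }))
}

.checkRecordWells <- function(records, layouts) {
  lk <- .wellRoles(layouts)
  bad <- !(paste(records$plate_id, records$well) %in%
             paste(lk$plate_id, lk$well))
  if (any(bad))
    stop("field records reference wells absent from the layout: ",
         paste(unique(paste(records$plate_id[bad], records$well[bad])),
               collapse = ", "))
}

.conditionTable <- function(wells, min_wells = 2L) {
  tw <- wells[!is.na(wells$compound_id), , drop = FALSE]
  if (!nrow(tw))
    return(data.frame(compound_id = character(0), n_wells_used = integer(0),
                      hit_class = character(0), stringsAsFactors = FALSE))
  out <- lapply(split(tw, tw$compound_id), function(g) {
    ok <- g[g$qc_pass, , drop = FALSE]
    row <- data.frame(compound_id = g$compound_id[1],
                      concentration = g$concentration[1],
                      n_wells_total = nrow(g), n_wells_used = nrow(ok),
                      stringsAsFactors = FALSE)
    for (mc in intersect(c(.metricCols,
                           paste0("pct_", .metricCols),
                           paste0("z_", c("density", "map2", "nuclei"))),
                         names(g)))
      row[[mc]] <- if (nrow(ok)) mean(ok[[mc]]) else NA_real_
    row$hit_class <- if (nrow(ok) >= min_wells) "pending" else "qc_fail"
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Percent-of-control normalization
#'
#' Expresses each metric of each well as a percentage of the mean over the
#' surviving vehicle-control wells of the same plate. Plates with no
#' surviving control wells (or a zero control mean) have all wells flagged
#' \code{qc_fail}.
#'
#' @param wells well table from [filterWellsAndConditions()].
#' @param metrics metric columns to normalize.
#' @return The well table with \code{pct_<metric>} columns appended.
#' @export
percentOfControl <- function(wells, metrics = .metricCols) {
  for (mc in metrics) wells[[paste0("pct_", mc)]] <- NA_real_
  for (p in unique(wells$plate_id)) {
    sel <- wells$plate_id == p
    ctrl <- sel & wells$role == "control" & wells$qc_pass
    if (!any(ctrl)) { wells$qc_pass[sel] <- FALSE; next }
    for (mc in metrics) {
      mu <- mean(wells[[mc]][ctrl])
      if (!is.finite(mu) || mu == 0) { wells$qc_pass[sel] <- FALSE; next }
      wells[[paste0("pct_", mc)]][sel] <- 100 * wells[[mc]][sel] / mu
    }
  }
  wells
}

#' Intra-plate Z-scores
#'
#' For each plate and metric, \code{z = (X - mean(controls)) /
#' sd(controls)} with the sample SD (n - 1) over that plate's surviving
#' vehicle-control wells; control wells are scored too. Plates with fewer
#' than two surviving controls or zero control SD are flagged
#' \code{qc_fail}.
#'
#' @param wells well table (after [percentOfControl()] or directly from
#'   [filterWellsAndConditions()]).
#' @param metrics named character vector mapping z-column suffixes to
#'   metric columns.
#' @return The well table with \code{z_<name>} columns appended.
#' @export
zscoreWells <- function(wells, metrics = c(density = "density",
                                           map2 = "map2_area",
                                           nuclei = "nuclei_count")) {
  for (nm in names(metrics)) wells[[paste0("z_", nm)]] <- NA_real_
  for (p in unique(wells$plate_id)) {
    sel <- wells$plate_id == p
    ctrl <- sel & wells$role == "control" & wells$qc_pass
    if (sum(ctrl) < 2L) { wells$qc_pass[sel] <- FALSE; next }
    for (nm in names(metrics)) {
      x <- wells[[metrics[[nm]]]]
      mu <- mean(x[ctrl]); s <- sd(x[ctrl])
      if (!is.finite(s) || s == 0) { wells$qc_pass[sel] <- FALSE; next }
      wells[[paste0("z_", nm)]][sel] <- (x[sel] - mu) / s
    }
  }
  wells
}

#' Aggregate wells to conditions
#'
#' Mean of each metric / percent / z column over the surviving wells of
#' each condition; conditions with fewer than \code{min_wells} surviving
#' wells are flagged \code{qc_fail}.
#'
#' @param wells annotated well table.
#' @param min_wells minimum surviving wells per condition (default 2).
#' @return Condition table (one row per compound).
#' @export
conditionSummary <- function(wells, min_wells = 2L) {
  .conditionTable(wells, min_wells)
}

#' Call hits from condition-level Z-scores
#'
#' A condition is \code{toxic} when it reduces presynaptic density by a
#' Z-score at or below \code{z_toxic_density} (-3) AND reduces the neurite
#' area by a Z-score at or below \code{z_toxic_map2} (-2) — compounds
#' collapsing both readouts. It is an \code{enhancer_candidate} when
#' density Z is at or above \code{z_enhancer} (+2) without the neurite
#' collapse. Everything else is \code{inactive}; \code{qc_fail}
#' propagates.
#'
#' @param conditions condition table with \code{z_density} and
#'   \code{z_map2}.
#' @param z_toxic_density,z_toxic_map2,z_enhancer rule thresholds.
#' @return The condition table with \code{hit_class} set.
#' @export
callHits <- function(conditions, z_toxic_density = -3, z_toxic_map2 = -2,
                     z_enhancer = 2) {
  hc <- conditions$hit_class
  act <- hc != "qc_fail"
  toxic <- act & conditions$z_density <= z_toxic_density &
    conditions$z_map2 <= z_toxic_map2
  enh <- act & !toxic & conditions$z_density >= z_enhancer &
    conditions$z_map2 > z_toxic_map2
  hc[act] <- "inactive"
  hc[toxic] <- "toxic"
  hc[enh] <- "enhancer_candidate"
  conditions$hit_class <- hc
  conditions
}

#' Library fractions per hit class
#'
#' Percent of the screened library in each hit class, rounded to two
#' decimals (e.g. 13 of 376 -> 3.46).
#'
#' @param x condition table with \code{hit_class}, or a named vector of
#'   class counts.
#' @param library_size total number of library compounds.
#' @return Named numeric vector of percentages.
#' @export
libraryFractions <- function(x, library_size) {
  stopifnot(library_size > 0)
  counts <- if (is.data.frame(x)) table(x$hit_class) else x
  out <- round(100 * as.numeric(counts) / library_size, 2)
  names(out) <- names(counts)
  out
}
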