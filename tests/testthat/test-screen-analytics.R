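test_that("density follows its definition and degenerate convention", {
  expect_equal(synDensity(50, 1000), 0.05)
  expect_equal(synDensity(0, 123), 0)
  expect_equal(synDensity(10, 200), synDensity(20, 400))
  expect_true(is.na(synDensity(5, 0)))
})

.mkRecords <- function(areas, plate = "P1", well = "B03", batch = "b1") {
  data.frame(batch_id = batch, plate_id = plate, well = well,
             field = seq_along(areas), map2_area = areas,
             syn_on_map2_count = 10L, nuclei_count = 50L,
             syn_total_area = 70L, stringsAsFactors = FALSE)
}

test_that("field filter keeps exactly the mean +/- SD band, bounds inclusive", {
  areas <- c(rep(100, 10), 500, 2)
  rec <- .mkRecords(areas)
  ff <- filterFields(rec)
  mu <- mean(areas); s <- sd(areas)
  keep_oracle <- sapply(areas, function(a) a >= mu - s && a <= mu + s)
  expect_equal(ff$kept$field, which(keep_oracle))
  expect_equal(nrow(ff$kept) + nrow(ff$rejected), length(areas))
  ## identical areas: sd 0, all kept
  same <- filterFields(.mkRecords(rep(40, 8)))
  expect_equal(nrow(same$kept), 8)
  ## a field exactly at mu + s is kept
  a2 <- c(10, 20, 30)
  mu2 <- mean(a2); s2 <- sd(a2)
  rec2 <- .mkRecords(c(a2, mu2 + s2))
  mu3 <- mean(rec2$map2_area); s3 <- sd(rec2$map2_area)
  border <- .mkRecords(c(mu3 - s3, mu3, mu3 + s3))
  expect_equal(nrow(filterFields(border)$kept), 3)
  ## single-field scope warns and keeps
  expect_warning(one <- filterFields(.mkRecords(5)), "single field")
  expect_equal(nrow(one$kept), 1)
})

test_that("well and condition rules follow the published minima", {
  lay <- plateLayout96("P1", treatments = sprintf("t%02d", 1:16))
  tw <- wellTable(lay)
  t01 <- tw$well[!is.na(tw$compound_id) & tw$compound_id == "t01"]
  ctrl <- controlWells(lay)[1:3]
  rec <- rbind(.mkRecords(rep(100, 5), well = t01[1]),   # 5 fields: pass
               .mkRecords(rep(100, 6), well = t01[2]),   # 6 fields: pass
               .mkRecords(rep(100, 4), well = t01[3]),   # 4 fields: fail
               .mkRecords(rep(100, 5), well = ctrl[1]),
               .mkRecords(rep(100, 5), well = ctrl[2]),
               .mkRecords(rep(100, 5), well = ctrl[3]))
  fw <- filterWellsAndConditions(rec, lay)
  w <- fw$wells
  expect_false(w$qc_pass[w$well == t01[3]])
  expect_true(all(w$qc_pass[w$well %in% t01[1:2]]))
  cond <- fw$conditions[fw$conditions$compound_id == "t01", ]
  expect_equal(cond$n_wells_used, 2)
  expect_identical(cond$hit_class, "pending")
  ## a condition with a single surviving well is qc_fail
  rec2 <- rec[rec$well != t01[2], ]
  fw2 <- filterWellsAndConditions(rec2, lay)
  expect_identical(
    fw2$conditions$hit_class[fw2$conditions$compound_id == "t01"], "qc_fail")
  ## records naming unknown wells are rejected outright
  bad <- .mkRecords(rep(100, 5), well = "Z99")
  expect_error(filterWellsAndConditions(bad, lay), "absent from the layout")
})

test_that("QC filters equal a single-pass brute-force implementation", {
  set.seed(23)
  lay <- plateLayout96("P1", treatments = sprintf("t%02d", 1:16))
  rec <- simulateFieldRecords(lay, fields_per_well = 8L, seed = 14L)
  ## drop a random 25% of fields to create uneven well coverage
  rec <- rec[-sample(nrow(rec), nrow(rec) %/% 4), ]
  ff <- filterFields(rec)
  fw <- filterWellsAndConditions(ff$kept, lay)
  surv <- fw$wells[fw$wells$qc_pass, c("plate_id", "well")]
  oracle <- oracleQCSurvivors(rec)
  oracle_wells <- unique(oracle[, c("plate_id", "well")])
  expect_setequal(paste(surv$plate_id, surv$well),
                  paste(oracle_wells$plate_id, oracle_wells$well))
})

.mkWells <- function(vals, roles, plate = "P1") {
  n <- length(vals)
  data.frame(plate_id = plate, well = wellLabel(rep(2, n), seq_len(n) + 1),
             batch_id = "b1", n_fields = 6, map2_area = 5000,
             syn_on_map2_count = 20, nuclei_count = 60, syn_total_area = 150,
             density = vals, qc_pass = TRUE, role = roles,
             compound_id = ifelse(roles == "assay", "cmp", NA),
             concentration = NA_real_, stringsAsFactors = FALSE)
}

test_that("percent-of-control is the plate-relative percentage", {
  w <- .mkWells(c(8, 12, 15), c("control", "control", "assay"))
  out <- percentOfControl(w, metrics = "density")
  expect_equal(out$pct_density[3], 150)
  expect_equal(out$pct_density[1:2], c(80, 120))
  ## value equal to the control mean reads 100%
  w2 <- .mkWells(c(10, 10, 10), c("control", "control", "assay"))
  expect_equal(percentOfControl(w2, metrics = "density")$pct_density[3], 100)
  ## zero control mean fails the plate
  w3 <- .mkWells(c(0, 0, 5), c("control", "control", "assay"))
  expect_false(any(percentOfControl(w3, metrics = "density")$qc_pass))
})

test_that("z-scores use the control mean and sample SD, controls included", {
  w <- .mkWells(c(10, 20, 30, 20), c("control", "control", "control", "assay"))
  z <- zscoreWells(w, metrics = c(density = "density"))
  expect_equal(z$z_density[4], 0)             # at the control mean
  expect_equal(mean(z$z_density[1:3]), 0, tolerance = 1e-12)
  w2 <- .mkWells(c(10, 30, 40), c("control", "control", "assay"))
  z2 <- zscoreWells(w2, metrics = c(density = "density"))
  expect_equal(z2$z_density[3], (40 - 20) / sd(c(10, 30)))
  ## zero control SD fails the plate
  w3 <- .mkWells(c(10, 10, 40), c("control", "control", "assay"))
  expect_false(any(zscoreWells(w3, metrics = c(density = "density"))$qc_pass))
})

test_that("z-scores are invariant under affine rescaling of a plate", {
  set.seed(9)
  w <- .mkWells(rnorm(12, 50, 8),
                c(rep("control", 4), rep("assay", 8)))
  z1 <- zscoreWells(w, metrics = c(density = "density"))$z_density
  w2 <- w; w2$density <- 3.7 * w$density + 11
  z2 <- zscoreWells(w2, metrics = c(density = "density"))$z_density
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("hit calling implements the conjunctive toxicity rule", {
  cond <- data.frame(compound_id = c("a", "b", "c", "d", "e"),
                     n_wells_used = 3,
                     z_density = c(-3.5, 0, -3.5, 2.5, 2.5),
                     z_map2 = c(-2.4, 0, 0, 0, -2.5),
                     hit_class = c("pending", "pending", "pending",
                                   "pending", "qc_fail"),
                     stringsAsFactors = FALSE)
  out <- callHits(cond)
  expect_equal(out$hit_class,
               c("toxic", "inactive", "inactive", "enhancer_candidate",
                 "qc_fail"))
})

test_that("library fractions reproduce the percentage arithmetic", {
  expect_equal(unname(libraryFractions(c(qc_fail = 13), 376)), 3.46)
  expect_equal(unname(libraryFractions(c(toxic = 7), 376)), 1.86)
  expect_equal(unname(libraryFractions(c(toxic = 0), 376)), 0)
})

test_that("pattern correction removes planted drift but preserves spikes", {
  lays <- c(screenLayouts(3, prefix = "t"),
            list(plateLayout96("S1", sentinel = TRUE),
                 plateLayout96("S2", sentinel = TRUE)))
  ## clean batch: correction is a near no-op
  rec0 <- simulateFieldRecords(lays, seed = 30L)
  fw0 <- filterWellsAndConditions(filterFields(rec0)$kept, lays)
  pc0 <- patternCorrect(fw0$wells, lays)
  expect_lt(max(abs(pc0$density - pc0$density_raw)),
            0.01 * sd(fw0$wells$density))
  ## planted row gradient: slope reduced by >= 80%
  rec1 <- simulateFieldRecords(lays, row_gradient = 0.12, seed = 31L)
  fw1 <- filterWellsAndConditions(filterFields(rec1)$kept, lays)
  pc1 <- patternCorrect(fw1$wells, lays)
  rows <- parseWell(pc1$well)$row
  s_before <- unname(coef(lm(pc1$density_raw ~ rows))[2])
  s_after <- unname(coef(lm(pc1$density ~ rows))[2])
  expect_lt(abs(s_after), 0.2 * abs(s_before))
  ## a single-well spike on an assay plate survives correction
  fw2 <- fw0$wells
  spike_i <- which(fw2$plate_id == "P01" & fw2$role == "assay")[5]
  fw2$density[spike_i] <- fw2$density[spike_i] * 2
  pc2 <- patternCorrect(fw2, lays)
  expect_gt(pc2$density[spike_i] / median(pc2$density[pc2$role == "assay"]),
            1.8)
})

test_that("null screens stay within |z| <= 2 for most conditions", {
  lays <- screenLayouts(4)
  rec <- simulateFieldRecords(lays, seed = 44L)
  scr <- runScreen(rec, lays)
  cond <- scr$conditions
  expect_gte(mean(abs(cond$z_density) <= 2), 0.9)
  expect_equal(sum(cond$hit_class == "toxic"), 0)
})
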