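test_that("empty field spec yields background-only channels and empty truth", {
  sp <- tinySpec(3, on = 0L, off = 0L, nn = 0L, na = 0L, segments = 0L)
  fl <- generateField(sp)
  expect_equal(nrow(punctaTable(fl$truth)), 0)
  expect_equal(nrow(nucleiTable(fl$truth)), 0)
  expect_equal(sum(neuriteMask(fl$truth)), 0)
  pre <- getChannel(fl$stack, "presynaptic")
  ## background 10 photons + shot/read noise, no planted structure
  expect_lt(abs(mean(pre) - 10), 1)
  expect_true(all(pre >= 0))
})

test_that("planted object bookkeeping matches the requested counts", {
  sp <- tinySpec(5, on = 40L, off = 10L, shape = c(128L, 128L))
  fl <- generateField(sp)
  p <- punctaTable(fl$truth)
  expect_equal(sum(p$on_neurite), 40)
  expect_equal(sum(!p$on_neurite), 10)
  ## every on-neurite centroid lies on the mask (validity re-checked here)
  m <- neuriteMask(fl$truth)
  on <- p[p$on_neurite, ]
  expect_true(all(m[cbind(on$y + 1, on$x + 1)] > 0))
  expect_equal(plantedDensity(fl$truth), 40 / sum(m > 0))
})

test_that("generation is deterministic and leaves the caller RNG alone", {
  sp <- tinySpec(9)
  set.seed(123); r1 <- runif(1)
  a <- generateField(sp)
  set.seed(123); r2 <- runif(1)
  b <- generateField(sp)
  expect_identical(a$stack@channels, b$stack@channels)
  expect_identical(punctaTable(a$truth), punctaTable(b$truth))
  expect_identical(r1, r2)
})

test_that("artifact identity: zero shift and unit gain are a no-op", {
  sp <- tinySpec(4)
  fl <- generateField(sp)
  out <- applyArtifacts(fl$stack, artifactSpec())
  expect_identical(out@channels, fl$stack@channels)
})

test_that("planted channel shift sits at the brute-force cross-correlation peak", {
  sp <- tinySpec(6)
  fl <- generateField(sp)
  pre0 <- maxProject(getChannel(fl$stack, "presynaptic"))
  sh <- applyArtifacts(fl$stack, artifactSpec(channel_shift = c(3L, -2L)))
  pre1 <- maxProject(getChannel(sh, "presynaptic"))
  ## exhaustive shift search maximizing correlation of shifted vs original
  best <- c(NA, NA); best_c <- -Inf
  for (dy in -4:4) for (dx in -4:4) {
    ys <- max(1, 1 + dy):min(nrow(pre0), nrow(pre0) + dy)
    xs <- max(1, 1 + dx):min(ncol(pre0), ncol(pre0) + dx)
    cc <- cor(as.vector(pre1[ys, xs]), as.vector(pre0[ys - dy, xs - dx]))
    if (cc > best_c) { best_c <- cc; best <- c(dy, dx) }
  }
  expect_equal(best, c(3, -2))
  ## the nuclear reference channel is never shifted
  expect_identical(getChannel(sh, "nuclear"), getChannel(fl$stack, "nuclear"))
})

test_that("illumination gain plane makes column means increase in x", {
  st <- new("FieldStack", plate_id = "P", well = "B02", field_index = 1L,
            channels = list(nuclear = array(50, c(2, 32, 48)),
                            dendrite = array(50, c(2, 32, 48)),
                            presynaptic = array(50, c(2, 32, 48))),
            pixel_size = 0.6)
  out <- applyArtifacts(st, artifactSpec(illumination_gradient = c(1, 0, 0.001)))
  cm <- colMeans(maxProject(getChannel(out, "presynaptic")))
  expect_true(all(diff(cm) > 0))
  expect_error(applyArtifacts(st, artifactSpec(illumination_gradient = c(0.001, 0, -0.01))),
               "positive")
})

test_that("field generation refuses impossible object budgets", {
  expect_error(generateField(fieldSpec(image_shape = c(32L, 32L))),
               "too small")
})

test_that("plate generation emits fields per well, honors effects, rejects bad maps", {
  lay <- plateLayout96("P1", treatments = sprintf("t%02d", 1:16))
  base <- tinySpec(1, on = 15L, off = 5L, nn = 1L, na = 1L, segments = 3L,
                   shape = c(112L, 112L))
  treated <- assayWells(lay)[1:24]
  eff <- effectMap(treated, density_multiplier = 2)
  plate <- generatePlate(lay, base, effects = eff, fields_per_well = 2L,
                         seed = 77L)
  tt <- plate$truth_table
  expect_equal(nrow(tt), 60 * 2)
  expect_equal(length(plate$stacks), 60 * 2)
  ## effect fidelity: >= 24 wells per arm, ratio of mean planted density
  agg <- function(wells) {
    sel <- tt$well %in% wells
    sum(tt$n_on[sel]) / sum(tt$mask_area[sel])
  }
  others <- setdiff(unique(tt$well), treated)
  ratio <- agg(treated) / agg(others)
  expect_lt(abs(ratio - 2), 0.2)
  ## referencing an outer-ring well fails
  expect_error(
    generatePlate(lay, base, effects = effectMap("A01", 2), fields_per_well = 1L),
    "outside the layout")
  ## non-unit control multiplier fails
  expect_error(
    generatePlate(lay, base, effects = effectMap(controlWells(lay)[1], 2),
                  fields_per_well = 1L),
    "multiplier 1")
})

test_that("null plate shows only sampling dispersion in planted density", {
  lay <- plateLayout96("P1")
  base <- tinySpec(2, on = 20L, off = 0L, nn = 0L, na = 0L, segments = 3L)
  plate <- generatePlate(lay, base, fields_per_well = 2L, seed = 99L)
  tt <- plate$truth_table
  per_well <- tapply(tt$n_on, tt$well, sum)
  ## Poisson counts: variance/mean of well totals consistent with the
  ## generative model (index of dispersion near 1)
  disp <- var(per_well) / mean(per_well)
  expect_gt(disp, 0.4); expect_lt(disp, 2.5)
})
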