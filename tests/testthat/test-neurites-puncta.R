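test_that("tubeness amplifies thin ridges over background and blobs", {
  H <- 96; W <- 96
  flat <- matrix(0.2, H, W)
  expect_lt(max(enhanceNeurites(flat)), 1e-8)
  tube <- matrix(0.05, H, W); tube[46:49, ] <- 1       # width-4 ridge
  enh <- enhanceNeurites(tube)
  on_tube <- matrix(FALSE, H, W); on_tube[46:49, ] <- TRUE
  expect_gt(mean(enh[on_tube]), 5 * max(mean(enh[!on_tube]), 1e-9))
  blob <- drawDisk(matrix(0.05, H, W), 48, 48, 20, 1)  # 20 px blob
  expect_lt(max(enhanceNeurites(blob)), max(enh))
})

test_that("neurite segmentation recovers the planted network", {
  fl <- generateField(fieldSpec160(41))
  proj <- lapply(fl$stack@channels, maxProject)
  enh <- enhanceNeurites(rescaleIntensity(proj$dendrite))
  seg <- segmentNeurites(enh)
  truth <- neuriteMask(fl$truth) > 0
  ## the segmented mask must cover the core of the planted network
  core <- truth & !is.na(truth)
  coverage <- sum(seg$mask & core) / sum(core)
  expect_gt(coverage, 0.8)
  expect_equal(seg$area, sum(seg$mask))
})

test_that("puncta detection finds planted spots, rejects noise and big objects", {
  H <- 112; W <- 112
  ## 20 well-separated spots of diameter 3
  img <- matrix(0, H, W)
  pos <- expand.grid(y = seq(12, 100, length.out = 5),
                     x = seq(12, 100, length.out = 4))
  for (i in seq_len(nrow(pos)))
    img <- drawSpot(img, round(pos$y[i]), round(pos$x[i]), 3)
  pp <- detectPuncta(rescaleIntensity(img))
  expect_equal(nrow(pp$table), 20)
  expect_true(all(pp$table$equivalent_diameter >= 1 &
                    pp$table$equivalent_diameter <= 6))
  ## a 10 px disk fails the 1-6 px equivalent-diameter rule
  disk <- drawDisk(matrix(0, H, W), 56, 56, 10, 1)
  expect_equal(nrow(detectPuncta(disk)$table), 0)
  ## noise-only plane at default amplitude/noise -> no puncta
  fl <- generateField(tinySpec(55, on = 0L, off = 0L, nn = 0L, na = 0L,
                               segments = 0L))
  pre <- rescaleIntensity(maxProject(getChannel(fl$stack, "presynaptic")))
  expect_equal(nrow(detectPuncta(pre)$table), 0)
})

test_that("retained diameters always satisfy the configured range", {
  for (s in 1:3) {
    fl <- generateField(tinySpec(60 + s, shape = c(128L, 128L), on = 30L,
                                 off = 10L))
    pre <- rescaleIntensity(maxProject(getChannel(fl$stack, "presynaptic")))
    tab <- detectPuncta(pre)$table
    expect_true(all(2 * sqrt(tab$area / pi) >= 1 &
                      2 * sqrt(tab$area / pi) <= 6))
  }
})

test_that("colocalization counts pixel overlaps and is monotone in the mask", {
  H <- 64; W <- 64
  img <- matrix(0, H, W)
  img <- drawSpot(img, 16, 16, 3)   # fully inside the mask
  img <- drawSpot(img, 16, 40, 3)   # straddles the mask edge
  img <- drawSpot(img, 48, 48, 3)   # fully outside
  pp <- detectPuncta(rescaleIntensity(img))
  expect_equal(nrow(pp$table), 3)
  mask <- matrix(FALSE, H, W); mask[1:24, 1:40] <- TRUE
  cc <- colocalize(pp, mask)
  expect_equal(sum(cc$table$on_neurite), 2)
  ## empty and universal masks
  expect_equal(sum(colocalize(pp, matrix(FALSE, H, W))$table$on_neurite), 0)
  expect_equal(sum(colocalize(pp, matrix(TRUE, H, W))$table$on_neurite), 3)
  ## monotone: growing the mask never drops an on-neurite punctum
  m1 <- matrix(FALSE, H, W); m1[1:20, 1:20] <- TRUE
  m2 <- m1; m2[1:30, 1:64] <- TRUE
  expect_lte(sum(colocalize(pp, m1)$table$on_neurite),
             sum(colocalize(pp, m2)$table$on_neurite))
})

test_that("field measurement is plain arithmetic over the parts", {
  empty <- detectPuncta(matrix(0, 32, 32))
  expect_equal(unlist(measureField(matrix(FALSE, 32, 32), empty, 0)),
               c(map2_area = 0, syn_on_map2_count = 0, nuclei_count = 0,
                 syn_total_area = 0))
  fake <- list(table = data.frame(
    label = 1:7, area = rep(4L, 7), equivalent_diameter = 2 * sqrt(4 / pi),
    y = 0, x = 0, on_neurite = c(rep(TRUE, 5), FALSE, FALSE)))
  mask <- matrix(FALSE, 50, 50); mask[1:20, 1:50] <- TRUE
  m <- measureField(mask, fake, 11)
  expect_equal(m$map2_area, 1000)
  expect_equal(m$syn_on_map2_count, 5)
  expect_equal(m$nuclei_count, 11)
  expect_equal(m$syn_total_area, 28)
})

test_that("end-to-end field recovery stays within 15% of the planted count", {
  ## puncta planted uniformly can coincide within a resolution element;
  ## clusters merging past the 6 px diameter cap are (correctly) discarded,
  ## so single fields fluctuate -- the recovery claim is about the mean
  rel_err <- vapply(71:76, function(s) {
    fl <- generateField(fieldSpec160(s, on = 25L))
    row <- processField(fl$stack, pipelineConfig(alignment_search_radius = 5L))
    planted <- sum(punctaTable(fl$truth)$on_neurite)
    abs(row$syn_on_map2_count - planted) / planted
  }, numeric(1))
  expect_lt(mean(rel_err), 0.15)
  expect_true(all(rel_err < 0.25))
})
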