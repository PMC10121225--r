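test_that("self-alignment of identical planes yields zero offset", {
  set.seed(11)
  p <- matrix(runif(64 * 64), 64, 64)
  pf <- alignChannels(p, p, p, pipelineConfig(alignment_search_radius = 4L))
  expect_equal(alignmentOffset(pf), c(0L, 0L))
  expect_false(pf@alignment_degenerate)
})

test_that("planted integer shifts are recovered and applied to both channels", {
  cfg <- pipelineConfig(alignment_search_radius = 6L)
  shifts <- list(c(3L, -2L), c(-4L, 1L), c(0L, 5L))
  for (k in seq_along(shifts)) {
    sh <- shifts[[k]]
    fl <- generateField(fieldSpec(seed = 20L + k),
                        artifactSpec(channel_shift = sh))
    proj <- lapply(fl$stack@channels, maxProject)
    pf <- alignChannels(proj$nuclear, proj$dendrite, proj$presynaptic, cfg)
    expect_equal(alignmentOffset(pf), -sh)
    ## idempotence: re-aligning the aligned planes finds no further shift
    pf2 <- alignChannels(planes(pf)$nuclear, planes(pf)$dendrite,
                         planes(pf)$presynaptic, cfg)
    expect_equal(alignmentOffset(pf2), c(0L, 0L))
  }
})

test_that("the reported offset equals the brute-force MI surface argmax", {
  set.seed(31)
  fl <- generateField(tinySpec(31, shape = c(64L, 64L), nn = 1L, na = 0L))
  a <- maxProject(getChannel(fl$stack, "nuclear"))
  structured <- maxProject(getChannel(fl$stack, "dendrite"))
  noise <- matrix(runif(64 * 64), 64, 64)
  cfg <- pipelineConfig(alignment_search_radius = 3L)
  for (b in list(structured, noise)) {
    pf <- alignChannels(a, b, b, cfg)
    expect_equal(alignmentOffset(pf), as.integer(oracleMIArgmax(a, b, 3L)))
  }
})

test_that("mutual information matches an independent joint-table computation", {
  set.seed(13)
  a <- matrix(runif(40 * 30), 40, 30)
  b <- a + matrix(rnorm(40 * 30, 0, 0.2), 40, 30)
  expect_equal(mutualInformation(a, b), oracleMI(a, b), tolerance = 1e-12)
  expect_gt(mutualInformation(a, a), mutualInformation(a, b))
})

test_that("degenerate constant planes align at (0, 0) with a warning", {
  p <- matrix(runif(32 * 32), 32, 32)
  flat <- matrix(1, 32, 32)
  expect_warning(pf <- alignChannels(flat, p, p, pipelineConfig()),
                 "constant")
  expect_equal(alignmentOffset(pf), c(0L, 0L))
  expect_true(pf@alignment_degenerate)
})
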