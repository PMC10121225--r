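test_that("nucleus detection counts planted ellipses and honors the size gate", {
  expect_equal(nrow(detectNuclei(matrix(0, 64, 64), 0.6)), 0)
  ## 15 well-separated 25 um nuclei on a blank plane (0.6 um/px)
  H <- 300; W <- 300
  img <- matrix(0, H, W)
  pos <- expand.grid(y = seq(40, 260, length.out = 5),
                     x = seq(40, 260, length.out = 3))
  r_px <- 25 / 0.6 / 2
  for (i in seq_len(nrow(pos)))
    img <- drawDisk(img, pos$y[i], pos$x[i], 2 * r_px, 1)
  nuc <- detectNuclei(img, 0.6)
  expect_equal(nrow(nuc), 15)
  expect_true(all(nuc$diameter_um >= 20))
  ## a 10 um object is excluded by the diameter criterion
  img2 <- drawDisk(matrix(0, 100, 100), 50, 50, 10 / 0.6, 1)
  expect_equal(nrow(detectNuclei(img2, 0.6)), 0)
  ## but a lower gate admits it
  expect_equal(nrow(detectNuclei(img2, 0.6, min_diameter_um = 8)), 1)
})

test_that("neuronal classification separates the two simulated classes", {
  sp <- fieldSpec(image_shape = c(448L, 448L), n_on_puncta = 0L,
                  n_off_puncta = 0L, n_neuronal_nuclei = 10L,
                  n_astrocyte_nuclei = 20L, n_neurite_segments = 4L,
                  seed = 83L)
  fl <- generateField(sp)
  proj <- lapply(fl$stack@channels, maxProject)
  nuc <- detectNuclei(rescaleIntensity(proj$nuclear), 0.6)
  cl <- classifyNeuronal(nuc, rescaleIntensity(proj$dendrite), 0.6)
  tt <- nucleiTable(fl$truth)
  ## match detections to planted truth by nearest centroid
  truth_class <- vapply(seq_len(nrow(cl)), function(i) {
    d2 <- (tt$y - cl$y[i])^2 + (tt$x - cl$x[i])^2
    tt$class[which.min(d2)]
  }, "")
  tp <- sum(cl$class == "neuronal" & truth_class == "neuronal")
  fp <- sum(cl$class == "neuronal" & truth_class == "astrocytic")
  expect_gte(tp, 9)
  expect_lte(fp, 2)
})

test_that("gate logic: failing only the soma gate makes a nucleus astrocytic", {
  nuc <- data.frame(y = 30, x = 30, area = 1200L, diameter = 39,
                    diameter_um = 23.4, mean_intensity = 0.9,
                    contrast = 0.8, roundness = 0.95,
                    class = "unclassified", stringsAsFactors = FALSE)
  dend <- matrix(0, 64, 64)  # no dendrite signal anywhere: soma gate fails
  cl <- classifyNeuronal(nuc, dend, 0.6)
  expect_equal(cl$class, "astrocytic")
  ## with a bright perinuclear ring the same nucleus passes
  dend2 <- matrix(0.5, 64, 64)
  expect_equal(classifyNeuronal(nuc, dend2, 0.6)$class, "neuronal")
  ## empty input, and missing dendrite plane
  expect_equal(nrow(classifyNeuronal(nuc[0, ], dend, 0.6)), 0)
  expect_warning(un <- classifyNeuronal(nuc, NULL, 0.6), "unclassified")
  expect_equal(un$class, "unclassified")
})

test_that("classification is deterministic and permutation-equivariant", {
  set.seed(17)
  n <- 6
  nuc <- data.frame(y = seq(20, 80, length.out = n), x = 50, area = 1200L,
                    diameter = 39, diameter_um = 23.4,
                    mean_intensity = runif(n, 0.2, 0.9),
                    contrast = runif(n, 0.1, 0.9),
                    roundness = runif(n, 0.5, 1),
                    class = "unclassified", stringsAsFactors = FALSE)
  dend <- matrix(runif(120 * 120, 0, 0.4), 120, 120)
  a <- classifyNeuronal(nuc, dend, 0.6)
  b <- classifyNeuronal(nuc, dend, 0.6)
  expect_identical(a, b)
  perm <- sample(n)
  expect_identical(classifyNeuronal(nuc[perm, ], dend, 0.6)$class,
                   a$class[perm])
})

test_that("plate consistency computes the covariance and both rules", {
  r <- plateConsistency(rep(8000, 60))
  expect_equal(r$covariance_pct, 0)
  expect_true(r$pass)
  ## one well below 4000 fails the count band
  r2 <- plateConsistency(c(rep(6000, 58), 3000, 9000))
  expect_false(r2$count_rule)
  expect_false(r2$pass)
  ## alternating +/- 800 around 8000: CV just over 10 -> covariance fail
  x <- rep(c(7200, 8800), 30)
  r3 <- plateConsistency(x)
  expect_equal(r3$covariance_pct, 100 * sd(x) / mean(x))
  expect_gt(r3$covariance_pct, 10)
  expect_false(r3$covariance_rule)
  expect_true(r3$count_rule)
  ## degenerate all-zero plate
  r4 <- plateConsistency(c(0, 0, 0))
  expect_true(r4$degenerate); expect_false(r4$pass)
})

test_that("covariance is invariant under count rescaling", {
  set.seed(3)
  x <- rnorm(60, 8000, 300)
  base <- plateConsistency(x)$covariance_pct
  for (k in c(0.5, 2, 10))
    expect_equal(plateConsistency(k * x)$covariance_pct, base,
                 tolerance = 1e-12)
})

test_that("plate report JSON carries the verdict", {
  r <- plateConsistency(setNames(rep(8000, 4), c("B02", "B03", "B04", "B05")))
  js <- writePlateReport(r)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$mean, 8000)
  expect_true(parsed$pass)
})
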