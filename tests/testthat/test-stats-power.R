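test_that("Cohen's d follows the pooled-SD formula", {
  r <- cohensD(c(3, 4, 5), c(1, 2, 3))
  expect_equal(r$d, 2)
  expect_equal(r$pooled_sd, 1)
  ## sign flips when groups are swapped; scale invariance
  expect_equal(cohensD(c(1, 2, 3), c(3, 4, 5))$d, -2)
  expect_equal(cohensD(10 * c(3, 4, 5), 10 * c(1, 2, 3))$d, 2)
  ## equal group means -> zero numerator
  expect_equal(cohensD(c(5, 6, 7), c(5, 6, 7))$d, 0)
  expect_error(cohensD(c(1), c(1, 2)), "at least 2")
  expect_error(cohensD(c(2, 2), c(2, 2)), "pooled")
})

test_that("power matches the closed normal form and its boundary behavior", {
  ## d = 0: power equals alpha (one-sided)
  expect_equal(powerOfTest(0, 25, 0.05, "greater"), 0.05, tolerance = 1e-12)
  ## direct normal-CDF evaluation as oracle
  expect_equal(powerOfTest(0.8, 17, 0.05, "greater"),
               pnorm(sqrt(17) * 0.8 - qnorm(0.95)), tolerance = 1e-12)
  expect_equal(powerOfTest(0.8, 17, 0.05, "greater"), 0.951,
               tolerance = 5e-4)
  ## monotone in n
  p <- powerOfTest(0.3, 5:40, alternative = "greater")
  expect_true(all(diff(p) > 0))
  ## symmetry between one-sided alternatives
  for (d in c(0.2, 0.5, 1.3))
    expect_equal(powerOfTest(d, 20, alternative = "greater"),
                 powerOfTest(-d, 20, alternative = "less"),
                 tolerance = 1e-12)
})

test_that("required n reproduces the study-design values and inverts power", {
  r <- lapply(c(0.2, 0.5, 0.8), requiredN, power = 0.95, alpha = 0.05,
              alternative = "greater")
  expect_equal(r[[1]]$n, 270.55, tolerance = 1e-4)
  expect_equal(r[[2]]$n, 43.29, tolerance = 1e-4)
  expect_equal(r[[3]]$n, 16.91, tolerance = 1e-3)
  ## closed form agrees with the printed continuous values
  expect_equal(vapply(r, `[[`, 0, "n_integer"), c(271, 43, 17))
  ## round trip: requiredN(d, powerOfTest(d, n)) returns n
  for (d in c(0.2, 0.5, 0.8, 2)) for (n in c(5, 17, 43, 271))
    for (alt in c("greater", "two_sided")) {
      pw <- powerOfTest(d, n, 0.05, alt)
      if (pw < 1 - 1e-12 && pw > 0.05 + 1e-9)
        expect_equal(requiredN(d, pw, 0.05, alt)$n, n, tolerance = 1e-6)
    }
  expect_error(requiredN(0, 0.95), "infinite")
})

test_that("power curves enumerate the grid and match the closed form", {
  d <- c(0.2, 0.5, 0.8); n <- c(5, 17, 43, 100)
  g <- powerCurves(d, n, alternative = "greater")
  expect_equal(nrow(g), length(d) * length(n))
  for (i in seq_len(nrow(g)))
    expect_equal(g$power[i],
                 pnorm(sqrt(g$n[i]) * g$d[i] - qnorm(0.95)),
                 tolerance = 1e-12)
  ## singleton grids reduce to powerOfTest
  expect_equal(powerCurves(0.5, 43, alternative = "greater")$power,
               powerOfTest(0.5, 43, alternative = "greater"))
})

test_that("simulated rejection rates agree with closed-form power", {
  ## one-sample z test of n standardized observations at effect d
  d <- 0.5; n <- 43; reps <- 20000
  rate <- withr::with_seed(424241L, {
    z <- vapply(seq_len(reps), function(i)
      mean(rnorm(n, d, 1)) * sqrt(n), numeric(1))
    mean(z > qnorm(0.95))
  })
  expect_lt(abs(rate - powerOfTest(d, n, 0.05, "greater")), 0.01)
})
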