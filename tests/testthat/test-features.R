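test_that("forward interframe difference follows the telescoping identity", {
  expect_equal(interframeDifference(c(1, 3, 6)), c(2, 3))
  expect_equal(interframeDifference(rep(4, 10)), rep(0, 9))
  set.seed(41)
  x <- rnorm(30)
  d <- interframeDifference(x)
  expect_length(d, 29L)
  expect_equal(sum(d), x[30] - x[1])
  expect_error(interframeDifference(5), "at least 2")
})

test_that("joint distances are per-axis magnitudes over the 13 pairs", {
  ts <- makeTranslated(2, function(t, k) {
    if (k == 14) c(10, 7) else if (k == 11) c(-20, 7) else if (k == 1) c(-5, 2) else c(1, 1)
  })
  d <- jointDistanceSeries(ts)
  expect_length(d, 26L)
  expect_equal(d$dist_14_11_x, c(30, 30))
  expect_equal(d$dist_14_11_y, c(0, 0)) # coincident on y
  expect_true(all(unlist(d) >= 0))
  pairNames <- unique(sub("_(x|y)$", "", names(d)))
  expect_length(pairNames, 13L)
  s <- jointDistanceSeries(ts, signed = TRUE)
  expect_equal(s$dist_14_11_x, c(30, 30))
  expect_equal(d$dist_1_0_x, c(6, 6)) # |(-5) - 1|
  expect_equal(s$dist_1_0_x, c(-6, -6)) # sign preserved when requested
})

test_that("joint angles are vertex angles in degrees within [0, 180]", {
  # keypoints 0,1,2 placed so the angle at the neck (1) is controlled
  ts <- makeTranslated(1, function(t, k) {
    switch(as.character(k),
      "0" = c(0, 1), "1" = c(0, 0), "2" = c(1, 0), # right angle
      "5" = c(0, -1), # collinear with 0 through 1 -> 180
      c(3, 3)
    )
  })
  # unused keypoints coincide in this fixture, so some triples degenerate
  a <- suppressWarnings(jointAngleSeries(ts))
  expect_length(a, 10L)
  expect_equal(a$angle_0_1_2[1], 90)
  expect_equal(a$angle_0_1_5[1], 180)
  expect_true(all(unlist(a) >= 0 & unlist(a) <= 180))
})

test_that("angles are invariant under global rotation of every frame", {
  ts <- translateToMidHip(makeSequence(frames = 10L, seed = 42L))
  a0 <- jointAngleSeries(ts)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rc <- keypointCoords(ts)
  for (t in 1:10) rc[t, , ] <- rc[t, , ] %*% t(R)
  # rebuild a GaitSequence with rotated coordinates and MidHip at origin
  full <- array(0, c(10, 25, 2))
  full[, setdiff(1:25, 9), ] <- rc
  a1 <- jointAngleSeries(translateToMidHip(GaitSequence("r", full)))
  for (nm in names(a0)) expect_equal(a1[[nm]], a0[[nm]], tolerance = 1e-10)
})

test_that("degenerate zero-length rays give angle 0 with a warning", {
  ts <- makeTranslated(1, function(t, k) {
    if (k %in% c(0, 1)) c(0, 0) else c(1, 2) # keypoint 0 coincides with vertex 1
  })
  expect_warning(a <- jointAngleSeries(ts), "zero-length")
  expect_equal(a$angle_0_1_2[1], 0)
})

test_that("time-domain summaries use population moments", {
  s <- timeDomainSummary(c(1, 2, 3))
  expect_equal(s[["mean"]], 2)
  expect_equal(s[["median"]], 2)
  expect_equal(s[["abs_energy"]], 14)
  expect_equal(s[["skewness"]], 0)
  expect_equal(s[["variance"]], 2 / 3) # population, not sample
  expect_equal(s[["root_mean_square"]], sqrt(14 / 3))
  expect_equal(s[["variation_coefficient"]], sqrt(2 / 3) / 2)

  cst <- timeDomainSummary(c(2, 2, 2))
  expect_equal(cst[["variance"]], 0)
  expect_equal(cst[["variation_coefficient"]], 0)
  expect_equal(cst[["root_mean_square"]], 2)
  expect_equal(cst[["skewness"]], 0)
  expect_equal(cst[["kurtosis"]], 0)

  zeroMean <- timeDomainSummary(c(-1, 0, 1))
  expect_equal(zeroMean[["variation_coefficient"]], 0) # mean-0 convention
  expect_named(s, c(
    "maximum", "minimum", "mean", "median", "variance", "root_mean_square",
    "skewness", "kurtosis", "abs_energy", "variation_coefficient"
  ))
})

test_that("frequency-domain summaries give 4 statistics per band", {
  bands <- list(
    D1 = c(-3, 1), D2 = 0, D3 = 1:3, D4 = -2, D5 = c(0, 0), A5 = c(5, 5)
  )
  f <- frequencyDomainSummary(bands)
  expect_length(f, 24L)
  expect_equal(f[["D1__abs_max"]], 3)
  expect_equal(f[["D1__mean"]], -1)
  expect_equal(f[["D1__variance"]], 4)
  expect_equal(f[["D1__abs_energy"]], 10)
  expect_equal(unname(f[paste0("D5__", c("abs_max", "mean", "variance", "abs_energy"))]),
    rep(0, 4))
  expect_error(frequencyDomainSummary(bands[1:5]), "6 coefficient arrays")
  expect_error(
    frequencyDomainSummary(c(bands[1:5], list(A5 = numeric(0)))), "empty"
  )
})

test_that("the feature pool holds exactly 132 series and 48 x 6 wavelet arrays", {
  ts <- smoothSequence(translateToMidHip(makeSequence(seed = 43L)))
  pool <- buildFeaturePool(ts)
  expect_length(pool@series, 132L)
  expect_false(anyDuplicated(names(pool@series)) > 0)
  expect_length(pool@waveletBands, 48L)
  expect_true(all(grepl("^coord_", names(pool@waveletBands))))
  expect_true(all(vapply(pool@waveletBands, length, 1L) == 6L))
  counts <- table(sub("_.*", "", names(pool@series)))
  expect_equal(
    as.integer(counts[c("coord", "diff", "dist", "angle")]),
    c(48L, 48L, 26L, 10L)
  )
  # difference series are one frame shorter than coordinate series
  expect_length(pool@series$diff_0_x, 74L)
  expect_equal(pool@series$diff_0_x, diff(pool@series$coord_0_x))
})

test_that("the feature vector has 2472 uniquely named finite entries", {
  ts <- smoothSequence(translateToMidHip(makeSequence(seed = 44L)))
  fv <- extractFeatureVector(ts)
  expect_length(fv, 2472L)
  expect_identical(names(fv), gaitFeatureNames())
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_true(all(is.finite(fv)))
  td <- sum(!grepl("__(D[1-5]|A5)__", names(fv)))
  expect_equal(td, 1320L)
  expect_equal(2472L - td, 1152L)
})

test_that("half sequences yield the same feature schema, shifted input the same values", {
  gs <- makeSequence(seed = 45L)
  ts <- smoothSequence(translateToMidHip(gs))
  fvFull <- extractFeatureVector(ts)
  halves <- splitOddEven(ts)
  fvOdd <- extractFeatureVector(halves$odd)
  expect_identical(names(fvOdd), names(fvFull))
  expect_false(isTRUE(all.equal(fvOdd, fvFull)))

  shifted <- GaitSequence(
    "s", keypointCoords(gs) + 500, keypointConfidence(gs)
  )
  fvShift <- extractFeatureVector(smoothSequence(translateToMidHip(shifted)))
  expect_equal(fvShift, fvFull, tolerance = 1e-9)
})
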