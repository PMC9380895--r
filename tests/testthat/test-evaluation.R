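test_that("Pearson correlation matches the closed form and flags degenerate input", {
  u <- c(1, 2, 3)
  expect_equal(pearsonR(u, u)$r, 1)
  expect_equal(pearsonR(u, -u)$r, -1)
  pr <- pearsonR(u, c(1, 2, 4))
  expect_equal(pr$r, 9 / sqrt(84), tolerance = 1e-12)
  # p from the t distribution with n - 2 df, computed independently
  tstat <- pr$r * sqrt((3 - 2) / (1 - pr$r^2))
  expect_equal(pr$p, 2 * pt(-abs(tstat), df = 1), tolerance = 1e-12)
  expect_error(pearsonR(c(2, 2, 2), u), "constant")
  expect_error(pearsonR(1:2, 1:2), "at least 3")
  expect_error(pearsonR(1:3, 1:4), "equal length")
})

test_that("RMSE follows its defining formula", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(3, 5), c(1, 1)), sqrt(10))
  set.seed(61)
  a <- rnorm(20)
  expect_equal(rmse(a + 1.7, a), 1.7)
  expect_error(rmse(1:3, 1:4), "length mismatch")
})

test_that("perfect predictions give r1 = 1, RMSE = 0 across the report", {
  set.seed(62)
  traits <- bigFiveTraits()$trait
  scores <- as.data.frame(matrix(rnorm(40 * 5, 27, 5), 40, 5,
    dimnames = list(NULL, traits)
  ))
  preds <- lapply(traits, function(tr) fakePredictionSet(scores[[tr]]))
  names(preds) <- traits
  rep <- criterionValidityTable(preds, scores)
  expect_s3_class(rep, "EvaluationReport")
  expect_equal(nrow(rep$table), 5L)
  expect_named(
    rep$table, c("trait", "rmse", "r1", "r1_p", "r2", "r2_p")
  )
  expect_equal(rep$table$r1, rep(1, 5))
  expect_equal(rep$table$rmse, rep(0, 5))
  expect_equal(rep$table$r2, rep(1, 5))
  expect_equal(unname(rep$means["r1"]), 1)
})

test_that("independent noise drives criterion validity toward zero", {
  set.seed(63)
  y <- rnorm(150, 27, 5)
  noise <- rnorm(150, 0, 5)
  preds <- list(openness = fakePredictionSet(noise))
  rep <- criterionValidityTable(preds, data.frame(openness = y))
  expect_lt(abs(rep$table$r1), 0.2)
})

test_that("split-half reliability is the odd/even prediction correlation", {
  set.seed(64)
  base <- rnorm(80)
  ps <- fakePredictionSet(base, odd = base, even = base)
  expect_equal(splitHalfReliability(ps)$r2, 1)
  psn <- fakePredictionSet(base, odd = rnorm(80), even = rnorm(80))
  expect_lt(abs(splitHalfReliability(psn)$r2), 0.3)
  r2 <- splitHalfReliability(fakePredictionSet(base,
    odd = base + rnorm(80), even = base + rnorm(80)
  ))$r2
  expect_true(r2 >= -1 && r2 <= 1)
})

test_that("the MTMM matrix of identical methods is block-constant with unit convergent diagonal", {
  set.seed(65)
  traits <- bigFiveTraits()$trait
  scores <- as.data.frame(matrix(rnorm(60 * 5, 27, 5), 60, 5,
    dimnames = list(NULL, traits)
  ))
  m <- mtmmMatrix(as.matrix(scores), scores)
  expect_s3_class(m, "MTMMMatrix")
  expect_equal(dim(m$matrix), c(10L, 10L))
  expect_equal(m$matrix, t(m$matrix))
  expect_equal(unname(diag(m$matrix)), rep(1, 10))
  # all four 5x5 blocks identical
  blocks <- list(
    m$matrix[1:5, 1:5], m$matrix[1:5, 6:10],
    m$matrix[6:10, 1:5], m$matrix[6:10, 6:10]
  )
  for (b in blocks[-1]) expect_equal(b, blocks[[1]], ignore_attr = TRUE)
  expect_equal(unname(convergentValidities(m)), rep(1, 5))
  # block entry counts
  expect_length(convergentValidities(m), 5L)
  expect_length(discriminantCorrelations(m, "model"), 10L)
  expect_length(discriminantCorrelations(m, "scale"), 10L)
  expect_length(heteroMethodHetero(m), 20L)
})

test_that("the scale block reproduces a known simulated correlation structure", {
  cohort <- generateCohort(syntheticConfig(nSubjects = 1000, nFrames = 1, seed = 66))
  sc <- cohort$scores[, -1]
  m <- mtmmMatrix(as.matrix(sc), sc)
  disc <- discriminantCorrelations(m, "scale")
  negWithN <- grepl("neuroticism", names(disc))
  expect_true(all(disc[negWithN] < 0))
  expect_true(all(disc[!negWithN] > 0))
  # magnitude: latent rho 0.3 attenuated by score noise, so roughly 0.15-0.35
  expect_true(all(abs(disc) > 0.1 & abs(disc) < 0.45))
})

test_that("validity summary separates convergent from discriminant structure", {
  set.seed(67)
  traits <- bigFiveTraits()$trait
  scores <- as.data.frame(matrix(rnorm(100 * 5, 27, 5), 100, 5,
    dimnames = list(NULL, traits)
  ))
  m <- mtmmMatrix(as.matrix(scores), scores)
  vs <- validitySummary(m, nPerm = 200, seed = 1)
  expect_equal(vs$meanConvergent, 1)
  expect_lt(vs$permutationP, 0.01)
  # independent traits: discriminant magnitudes near zero
  expect_lt(vs$meanScaleDiscriminant, 0.15)
  expect_lt(vs$meanModelDiscriminant, 0.15)
})

test_that("criterion validity and RMSE move inversely across noise levels", {
  r1s <- numeric(0)
  rmses <- numeric(0)
  for (noise in c(1, 8, 30)) {
    cfg <- syntheticConfig(
      nSubjects = 60, seed = 68,
      noiseSd = 1, scoreNoiseSd = noise
    )
    cohort <- generateCohort(cfg)
    feats <- extractCohortFeatures(cohort$sequences, halves = FALSE)
    ps <- repeatedCvPredict(feats, cohort$scores$conscientiousness,
      "conscientiousness", "lr",
      repeats = 2, folds = 5, seed = 3, k = 10
    )
    r1s <- c(r1s, pearsonR(
      ps$aggregated[, "all"], cohort$scores$conscientiousness
    )$r)
    rmses <- c(rmses, rmse(
      ps$aggregated[, "all"], cohort$scores$conscientiousness
    ))
  }
  expect_true(all(diff(r1s) < 0))
  expect_true(all(diff(rmses) > 0))
})
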