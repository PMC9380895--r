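# Small feature matrices for modeling tests: low-rank so OLS on all
# components is exact, or generic random matrices.
lowRankFeatures <- function(n, rank, seed) {
  set.seed(seed)
  L <- matrix(rnorm(n * rank), n, rank)
  V <- matrix(rnorm(2472 * rank), 2472, rank)
  X <- L %*% t(V)
  colnames(X) <- gaitFeatureNames()
  X
}

test_that("SFS picks the perfectly predictive component first", {
  set.seed(51)
  Z <- matrix(rnorm(40 * 6), 40, 6)
  y <- 2 * Z[, 3] + 1 # exact function of component 3
  sel <- sequentialForwardSelection(Z, y, "lr", k = 3, seed = 9)
  expect_equal(sel[1], 3L)
  # k = 1 collapses to the argmax over single-component scores
  expect_equal(sequentialForwardSelection(Z, y, "lr", k = 1, seed = 9), 3L)
  expect_error(sequentialForwardSelection(Z, y, "lr", k = 7), "infeasible")
})

test_that("SFS equals the brute-force greedy oracle and is deterministic", {
  set.seed(52)
  for (i in 1:8) {
    n <- sample(20:40, 1)
    m <- sample(4:8, 1)
    k <- sample(1:3, 1)
    Z <- matrix(rnorm(n * m), n, m)
    beta <- rnorm(m) * rbinom(m, 1, 0.5)
    y <- drop(Z %*% beta) + rnorm(n, sd = 0.5)
    seed <- sample.int(10000, 1)
    sel <- sequentialForwardSelection(Z, y, "lr", k = k, seed = seed)
    expect_identical(sel, greedyOracleLr(Z, y, k = k, seed = seed))
    expect_identical(
      sel, sequentialForwardSelection(Z, y, "lr", k = k, seed = seed)
    )
  }
})

test_that("the generic SFS path (non-OLS estimator) agrees on an identifiable case", {
  set.seed(53)
  Z <- matrix(rnorm(30 * 5), 30, 5)
  y <- Z[, 4] # exact in component 4; any reasonable scorer must find it
  sel <- sequentialForwardSelection(Z, y, "svr-linear", k = 1, seed = 2)
  expect_equal(sel, 4L)
})

test_that("the transform stack standardises, rotates and selects reproducibly", {
  X <- lowRankFeatures(40, 10, seed = 54)
  y <- drop(X[, 5]) + rnorm(40, sd = 0.01)
  st <- fitTransformStack(X, y, "lr", k = 6, seed = 3)
  expect_s3_class(st, "TransformStack")
  expect_lte(ncol(st$rotation), 39L) # rank bound: min(n - 1, rank)
  expect_equal(ncol(st$rotation), 10L) # rank of the construction
  expect_length(st$selected, 6L)
  expect_false(anyDuplicated(st$selected) > 0)
  Z1 <- applyTransformStack(st, X)
  expect_equal(dim(Z1), c(40L, 6L))
  expect_identical(Z1, applyTransformStack(st, X)) # determinism
  # zero-variance feature: scale 1, contributes a zero column
  X2 <- X
  X2[, 7] <- 42
  st2 <- fitTransformStack(X2, y, "lr", k = 6, seed = 3)
  expect_equal(st2$scale[[7]], 1)
  expect_error(fitTransformStack(X, rep(3, 40), "lr", k = 6), "constant target")
  expect_error(fitTransformStack(X, y, "lr", k = 11, seed = 3), "infeasible")
})

test_that("an exact linear trait is recovered to numerical precision by LR", {
  X <- lowRankFeatures(30, 5, seed = 55)
  y <- 2 * X[, 17] + 3
  fit <- fitTraitModel(X, y, "extraversion", "lr", seed = 4, k = 5)
  expect_lt(max(abs(predict(fit, X) - y)), 1e-6)
})

test_that("each of the seven algorithms fits and predicts finite values", {
  X <- lowRankFeatures(25, 6, seed = 56)
  y <- drop(scale(X[, 3])) * 4 + 25 + rnorm(25)
  for (alg in gaitAlgorithms()) {
    fit <- fitTraitModel(X, y, "openness", alg, seed = 5, k = 4)
    p <- predict(fit, X)
    expect_true(all(is.finite(p)), info = alg)
    expect_length(p, 25L)
  }
  expect_error(fitTraitModel(X, y, "openness", "deep-net", k = 4), "arg")
})

test_that("GPR predicts the constant on a degenerate target", {
  X <- matrix(rnorm(20 * 3), 20, 3)
  est <- gaitfive:::makeEstimator("gpr", seed = 1)
  m <- est$fit(X, rep(7, 20))
  expect_equal(est$predict(m, X), rep(7, 20))
})

test_that("repeated CV bookkeeping: one out-of-fold prediction per subject, rep and stream", {
  X <- lowRankFeatures(20, 8, seed = 57)
  y <- drop(X[, 2]) + rnorm(20, sd = 0.1)
  feats <- list(all = X, odd = X + rnorm(length(X), sd = 0.01), even = X)
  ps <- repeatedCvPredict(feats, y, "agreeableness", "lr",
    repeats = 2, folds = 10, seed = 6, k = 5
  )
  for (s in c("all", "odd", "even")) {
    expect_equal(dim(ps$perRepetition[[s]]), c(20L, 2L))
    expect_false(anyNA(ps$perRepetition[[s]]))
  }
  expect_equal(dim(ps$aggregated), c(20L, 3L))
  expect_equal(
    ps$aggregated[, "all"], rowMeans(ps$perRepetition$all)
  )
  # identical odd/even inputs pass through the identical stack:
  expect_identical(ps$aggregated[, "even"], ps$aggregated[, "all"])
  # rerun equality: pure function of (data, seed)
  ps2 <- repeatedCvPredict(feats, y, "agreeableness", "lr",
    repeats = 2, folds = 10, seed = 6, k = 5
  )
  expect_identical(ps$aggregated, ps2$aggregated)
  expect_error(
    repeatedCvPredict(feats, y, "agreeableness", "lr", folds = 21),
    "fewer subjects"
  )
})

test_that("held-out subjects never influence the training-fold stack", {
  X <- lowRankFeatures(30, 10, seed = 58)
  y <- drop(X[, 1]) + rnorm(30, sd = 0.1)
  te <- 1:6
  st1 <- fitTransformStack(X[-te, ], y[-te], "lr", k = 5, seed = 7)
  Xp <- X
  Xp[te, ] <- Xp[te, ] + 1e6 # wildly perturb held-out subjects
  st2 <- fitTransformStack(Xp[-te, ], y[-te], "lr", k = 5, seed = 7)
  expect_identical(st1, st2)
})
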