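## Modeling: standardisation -> PCA -> sequential forward selection ->
## per-trait regression, with repeated cross-validation over the three data
## streams (all frames / odd frames / even frames).

.ALGORITHMS <- c(
  "gpr", "lr", "rfr", "svr-linear", "svr-poly", "svr-rbf", "svr-sigmoid"
)

.BIG5 <- c(
  "extraversion", "agreeableness", "conscientiousness",
  "neuroticism", "openness"
)

#' The Big Five trait names and BFI-44 subscale score ranges
#'
#' Subscale scores are sums of five-point Likert items: extraversion
#' (8 items, 8--40), agreeableness (9, 9--45), conscientiousness (9, 9--45),
#' neuroticism (8, 8--40), openness (10, 10--50).
#'
#' @return Data frame with columns `trait`, `items`, `min`, `max`.
#' @export
bigFiveTraits <- function() {
  items <- c(8L, 9L, 9L, 8L, 10L)
  data.frame(
    trait = .BIG5, items = items, min = items, max = items * 5L,
    stringsAsFactors = FALSE
  )
}

#' Regression estimators available for trait modeling
#'
#' Builds the fit/predict interface for one of the seven regression
#' algorithms: `"gpr"` (Gaussian process regression, RBF kernel with the
#' median-distance bandwidth heuristic and a white-noise term of
#' 0.1 var(y), via kernlab), `"lr"` (ordinary least squares), `"rfr"`
#' (random forest, 100 trees), and `"svr-linear"`, `"svr-poly"`,
#' `"svr-rbf"`, `"svr-sigmoid"` (epsilon-SVR with the respective kernel,
#' via e1071). All fits are deterministic given `seed`.
#'
#' @param algorithm One of `gaitAlgorithms()`.
#' @param seed Integer seed controlling any randomised fitting (random
#'   forest).
#' @param params Optional list of hyperparameter overrides: `ntree` (rfr),
#'   `noiseVarFraction` and `sigma` (gpr), `cost` and `epsilon` (svr).
#' @return An estimator object (list with elements `algorithm`, `fit`,
#'   `predict`).
#' @keywords internal
makeEstimator <- function(algorithm, seed = 1L, params = list()) {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  est <- list(algorithm = algorithm)
  if (algorithm == "lr") {
    est$fit <- function(X, y) {
      cf <- .lm.fit(cbind(1, X), y)$coefficients
      cf[is.na(cf)] <- 0
      list(coef = cf)
    }
    est$predict <- function(model, X) drop(cbind(1, X) %*% model$coef)
  } else if (algorithm == "gpr") {
    est$fit <- function(X, y) {
      ym <- mean(y)
      if (stats::var(y) == 0) {
        return(list(const = ym))
      }
      sigma <- params$sigma %||% {
        med <- stats::median(stats::dist(X))
        if (!is.finite(med) || med <= 0) 1 else 1 / (2 * med^2)
      }
      noise <- max((params$noiseVarFraction %||% 0.1) * stats::var(y), 1e-8)
      fit <- kernlab::gausspr(
        x = X, y = y - ym, type = "regression",
        kernel = "rbfdot", kpar = list(sigma = sigma),
        var = noise, scaled = FALSE
      )
      list(fit = fit, ym = ym)
    }
    est$predict <- function(model, X) {
      if (!is.null(model$const)) {
        return(rep(model$const, nrow(X)))
      }
      drop(kernlab::predict(model$fit, X)) + model$ym
    }
  } else if (algorithm == "rfr") {
    est$fit <- function(X, y) {
      localSeed(
        deriveSeed(seed, 104729L),
        randomForest::randomForest(
          x = X, y = y,
          ntree = params$ntree %||% 100L
        )
      )
    }
    est$predict <- function(model, X) unname(predict(model, X))
  } else {
    kern <- c(
      "svr-linear" = "linear", "svr-poly" = "polynomial",
      "svr-rbf" = "radial", "svr-sigmoid" = "sigmoid"
    )[[algorithm]]
    est$fit <- function(X, y) {
      if (stats::var(y) == 0) {
        return(list(const = mean(y)))
      }
      suppressWarnings(e1071::svm(
        x = X, y = y, type = "eps-regression", kernel = kern,
        cost = params$cost %||% 1, epsilon = params$epsilon %||% 0.1
      ))
    }
    est$predict <- function(model, X) {
      if (is.list(model) && !is.null(model$const)) {
        return(rep(model$const, nrow(X)))
      }
      unname(predict(model, X))
    }
  }
  est
}

#' @rdname makeEstimator
#' @export
gaitAlgorithms <- function() .ALGORITHMS

## Batched candidate scoring for OLS via normal equations: for the current
## subset S (Cholesky-factored once) and every candidate column j, solve the
## bordered system by a Schur complement and score held-out RMSE. Identical
## model to refitting lm per candidate, at a fraction of the cost.
.scoreCandidatesLr <- function(foldData, selCols, cand) {
  total <- numeric(length(cand))
  for (fd in foldData) {
    cols <- c(1L, selCols)
    L <- chol(fd$G[cols, cols, drop = FALSE]) # upper: t(L) %*% L = G
    v <- backsolve(L, fd$b[cols], transpose = TRUE)
    U <- backsolve(L, fd$G[cols, cand + 1L, drop = FALSE], transpose = TRUE)
    sjj <- diag(fd$G)[cand + 1L] - colSums(U^2)
    rhs <- fd$b[cand + 1L] - colSums(U * v)
    bad <- sjj <= 1e-10
    sjj[bad] <- 1
    betaj <- rhs / sjj
    V <- v - U * rep(betaj, each = length(cols))
    BS <- backsolve(L, V)
    preds <- fd$Aval[, cols, drop = FALSE] %*% BS +
      fd$Aval[, cand + 1L, drop = FALSE] *
        rep(betaj, each = nrow(fd$Aval))
    rmseF <- sqrt(colMeans((preds - fd$yval)^2))
    rmseF[bad] <- Inf
    total <- total + rmseF
  }
  -total / length(foldData) # mean negative RMSE across folds
}

.scoreCandidatesGeneric <- function(Z, y, foldId, estimator, sel, cand) {
  nf <- max(foldId)
  scores <- numeric(length(cand))
  for (ci in seq_along(cand)) {
    cols <- c(sel, cand[ci])
    tot <- 0
    for (f in seq_len(nf)) {
      tr <- foldId != f
      model <- estimator$fit(Z[tr, cols, drop = FALSE], y[tr])
      p <- estimator$predict(model, Z[!tr, cols, drop = FALSE])
      tot <- tot + sqrt(mean((p - y[!tr])^2))
    }
    scores[ci] <- -tot / nf
  }
  scores
}

#' Sequential forward selection of principal components
#'
#' Greedy selection: starting from the empty set, at each of `k` stages the
#' component whose addition maximises the mean inner cross-validation score
#' (negative RMSE) of the estimator refit on the candidate subset is added;
#' ties go to the lowest component index. Deterministic given `seed` (which
#' fixes the inner fold assignment). For the OLS estimator the candidate
#' scoring uses an exact batched normal-equations path; other estimators are
#' refit per candidate.
#'
#' @param Z Numeric matrix, subjects x components.
#' @param y Numeric target vector.
#' @param estimator An estimator from [makeEstimator()], or an algorithm
#'   name.
#' @param k Number of components to select.
#' @param cvFolds Inner cross-validation folds (default 5).
#' @param seed Integer seed for the inner fold assignment.
#' @return Integer vector of the `k` selected component indices, in order of
#'   addition.
#' @export
sequentialForwardSelection <- function(Z, y, estimator, k, cvFolds = 5L,
                                       seed = 1L) {
  Z <- as.matrix(Z)
  m <- ncol(Z)
  n <- nrow(Z)
  if (k > m) {
    stop("infeasible selection: k = ", k, " exceeds ", m, " components")
  }
  if (is.character(estimator)) estimator <- makeEstimator(estimator, seed)
  foldId <- foldAssignment(n, cvFolds, deriveSeed(seed, 7L))
  useLr <- identical(estimator$algorithm, "lr")
  foldData <- NULL
  if (useLr) {
    foldData <- lapply(seq_len(cvFolds), function(f) {
      tr <- foldId != f
      A <- cbind(1, Z[tr, , drop = FALSE])
      list(
        G = crossprod(A), b = drop(crossprod(A, y[tr])),
        Aval = cbind(1, Z[!tr, , drop = FALSE]), yval = y[!tr]
      )
    })
  }
  sel <- integer(0)
  for (stage in seq_len(k)) {
    cand <- setdiff(seq_len(m), sel)
    scores <- if (useLr) {
      .scoreCandidatesLr(foldData, sel + 1L, cand)
    } else {
      .scoreCandidatesGeneric(Z, y, foldId, estimator, sel, cand)
    }
    sel <- c(sel, cand[which.max(scores)]) # which.max: ties -> lowest index
  }
  sel
}

#' Fit the feature transform stack (standardise, PCA, SFS)
#'
#' The 2472 time-frequency features are far more numerous than subjects, so
#' models are fit in a reduced space: features are standardised (zero mean,
#' unit SD per feature; zero-variance features get scale 1 and become zero
#' columns), projected onto their principal components (all
#' `min(n - 1, rank)` of them, so selection sees the full decorrelated
#' space), and 40 components are chosen by [sequentialForwardSelection()]
#' with the same algorithm as inner estimator. The stack is always fitted on
#' all-frames features; odd/even half features of a subject pass through the
#' identical stack.
#'
#' @param X Numeric matrix, subjects x 2472 all-frames features.
#' @param y Numeric trait score vector.
#' @param estimator Estimator object or algorithm name.
#' @param k Number of components to select (default 40).
#' @param cvFolds Inner CV folds for SFS scoring (default 5).
#' @param seed Integer seed.
#' @param sfsEstimator Optional estimator (or algorithm name) used only for
#'   SFS scoring; default `NULL` uses `estimator` itself.
#' @return A `TransformStack` object (list with `center`, `scale`,
#'   `rotation`, `sdev`, `selected`, `featureNames`).
#' @export
fitTransformStack <- function(X, y, estimator, k = 40L, cvFolds = 5L,
                              seed = 1L, sfsEstimator = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) {
    stop("need at least 2 subjects")
  }
  if (stats::var(y) == 0) {
    stop("constant target: trait scores carry no variance")
  }
  if (is.character(estimator)) estimator <- makeEstimator(estimator, seed)
  center <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")
  sv <- svd(Xs, nu = 0)
  rank <- sum(sv$d > max(sv$d[1L], .Machine$double.eps) * 1e-8)
  ncomp <- min(n - 1L, rank)
  if (ncomp < k) {
    stop(
      "infeasible selection: only ", ncomp, " principal components but k = ",
      k, " requested"
    )
  }
  rotation <- sv$v[, seq_len(ncomp), drop = FALSE]
  Z <- Xs %*% rotation
  scorer <- sfsEstimator %||% estimator
  if (is.character(scorer)) scorer <- makeEstimator(scorer, seed)
  selected <- sequentialForwardSelection(Z, y,
    estimator = scorer, k = k,
    cvFolds = cvFolds, seed = seed
  )
  structure(
    list(
      center = center, scale = scl, rotation = rotation,
      sdev = sv$d[seq_len(ncomp)] / sqrt(max(n - 1L, 1L)),
      selected = selected, featureNames = colnames(X)
    ),
    class = "TransformStack"
  )
}

#' Apply a fitted transform stack to new features
#'
#' @param stack A `TransformStack` from [fitTransformStack()].
#' @param X Numeric matrix, subjects x features (same columns as at fit
#'   time).
#' @return Numeric matrix, subjects x `length(stack$selected)` selected
#'   component scores.
#' @export
applyTransformStack <- function(stack, X) {
  stopifnot(inherits(stack, "TransformStack"))
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2L, stack$center), 2L, stack$scale, "/")
  (Xs %*% stack$rotation)[, stack$selected, drop = FALSE]
}

#' @export
print.TransformStack <- function(x, ...) {
  cat(sprintf(
    "TransformStack: %d features -> %d principal components, %d selected by SFS\n",
    length(x$center), ncol(x$rotation), length(x$selected)
  ))
  invisible(x)
}

#' Fit a single trait model on all-frames features
#'
#' Fits the transform stack and the final regressor for one trait and one
#' algorithm. The model is a pure function of the data and the seed.
#'
#' @param X Numeric matrix, subjects x 2472 all-frames features.
#' @param y Numeric trait score vector (raw subscale sums).
#' @param trait Trait name (one of [bigFiveTraits()]).
#' @param algorithm One of [gaitAlgorithms()].
#' @param seed Integer seed.
#' @param k Components selected by SFS (default 40).
#' @param cvFolds Inner CV folds for SFS (default 5).
#' @param params Hyperparameter overrides, see [makeEstimator()].
#' @param sfsEstimator Optional SFS-scoring algorithm override.
#' @return A `TraitModel` object; use `predict(model, newX)` for new
#'   all/odd/even feature matrices.
#' @export
fitTraitModel <- function(X, y, trait, algorithm, seed = 1L, k = 40L,
                          cvFolds = 5L, params = list(), sfsEstimator = NULL) {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  est <- makeEstimator(algorithm, seed, params)
  stack <- fitTransformStack(X, y,
    estimator = est, k = k, cvFolds = cvFolds,
    seed = seed, sfsEstimator = sfsEstimator
  )
  Zsel <- applyTransformStack(stack, X)
  model <- est$fit(Zsel, y)
  structure(
    list(
      trait = trait, algorithm = algorithm, stack = stack,
      regressor = model, estimator = est, seed = seed
    ),
    class = "TraitModel"
  )
}

#' @export
predict.TraitModel <- function(object, newdata, ...) {
  object$estimator$predict(
    object$regressor,
    applyTransformStack(object$stack, newdata)
  )
}

#' @export
print.TraitModel <- function(x, ...) {
  cat(sprintf(
    "TraitModel: %s ~ gait features [%s], %d selected components (seed %d)\n",
    x$trait, x$algorithm, length(x$stack$selected), x$seed
  ))
  invisible(x)
}

#' Repeated cross-validated out-of-fold predictions for one trait
#'
#' The evaluation protocol: `repeats` repetitions of `folds`-fold
#' cross-validation. Per repetition, subjects are shuffled (seeded) into
#' folds; per fold, the full stack (standardiser, PCA, SFS) and the
#' regressor are fitted on the training folds' all-frames features only and
#' applied to the held-out subjects' all-frames, odd-half and even-half
#' features. Every subject receives one out-of-fold prediction per stream
#' per repetition; the aggregated prediction is the mean over repetitions.
#' With `stackMode = "global"` the stack is instead fitted once on the full
#' cohort (the literal one-stack reading of the modeling flowchart; it leaks
#' feature information across folds and is provided for comparison only).
#'
#' @param features List of feature matrices `all` (and usually `odd`,
#'   `even`), as from [extractCohortFeatures()].
#' @param y Numeric trait score vector, one per subject.
#' @param trait Trait name.
#' @param algorithm One of [gaitAlgorithms()].
#' @param repeats Repetitions (default 10).
#' @param folds Folds (default 10).
#' @param seed Integer master seed for every source of randomness.
#' @param k,cvFolds,params,sfsEstimator Passed to the stack/estimator.
#' @param stackMode `"per-fold"` (default) or `"global"`.
#' @return A `PredictionSet`: list with `aggregated` (subjects x streams
#'   matrix of repetition-mean predictions), `perRepetition` (list of
#'   subjects x repeats matrices per stream), `trait`, `algorithm`, `seed`.
#' @export
repeatedCvPredict <- function(features, y, trait, algorithm, repeats = 10L,
                              folds = 10L, seed = 1L, k = 40L, cvFolds = 5L,
                              params = list(), sfsEstimator = NULL,
                              stackMode = c("per-fold", "global")) {
  stackMode <- match.arg(stackMode)
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  stopifnot(is.list(features), "all" %in% names(features))
  streams <- intersect(c("all", "odd", "even"), names(features))
  Xall <- as.matrix(features$all)
  n <- nrow(Xall)
  if (n < folds) {
    stop("fewer subjects (", n, ") than folds (", folds, ")")
  }
  stopifnot(length(y) == n)
  est <- makeEstimator(algorithm, seed, params)
  perRep <- lapply(streams, function(s) {
    matrix(NA_real_, n, repeats, dimnames = list(rownames(Xall), NULL))
  })
  names(perRep) <- streams
  globalStack <- NULL
  if (stackMode == "global") {
    globalStack <- fitTransformStack(Xall, y,
      estimator = est, k = k,
      cvFolds = cvFolds, seed = seed, sfsEstimator = sfsEstimator
    )
  }
  for (r in seq_len(repeats)) {
    foldId <- foldAssignment(n, folds, deriveSeed(seed, r))
    for (f in seq_len(folds)) {
      te <- foldId == f
      stack <- if (stackMode == "global") {
        globalStack
      } else {
        fitTransformStack(Xall[!te, , drop = FALSE], y[!te],
          estimator = est, k = k, cvFolds = cvFolds,
          seed = deriveSeed(seed, r, f), sfsEstimator = sfsEstimator
        )
      }
      model <- est$fit(
        applyTransformStack(stack, Xall[!te, , drop = FALSE]), y[!te]
      )
      for (s in streams) {
        Zte <- applyTransformStack(
          stack, as.matrix(features[[s]])[te, , drop = FALSE]
        )
        perRep[[s]][te, r] <- est$predict(model, Zte)
      }
    }
  }
  aggregated <- vapply(streams, function(s) rowMeans(perRep[[s]]), numeric(n))
  if (!all(is.finite(aggregated))) {
    stop("non-finite predictions produced")
  }
  structure(
    list(
      aggregated = aggregated, perRepetition = perRep, trait = trait,
      algorithm = algorithm, repeats = repeats, folds = folds, seed = seed
    ),
    class = "PredictionSet"
  )
}

#' @export
print.PredictionSet <- function(x, ...) {
  cat(sprintf(
    "PredictionSet: %s [%s], %d subjects, %dx%d-fold CV, streams: %s\n",
    x$trait, x$algorithm, nrow(x$aggregated), x$repeats, x$folds,
    paste(colnames(x$aggregated), collapse = "/")
  ))
  invisible(x)
}
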