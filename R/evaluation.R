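## Psychometric evaluation of trait models: criterion validity, RMSE,
## odd-even split-half reliability, and the multitrait-multimethod matrix.

#' Pearson correlation with a t-distribution p-value
#'
#' Standard product-moment correlation; the two-sided p-value comes from the
#' t distribution with n - 2 degrees of freedom. Constant input vectors make
#' the correlation undefined and raise an error.
#'
#' @param u,v Numeric vectors of equal length >= 3.
#' @return List with `r`, `p`, `n`.
#' @examples
#' pearsonR(c(1, 2, 3), c(1, 2, 4))$r # 9 / sqrt(84)
#' @export
pearsonR <- function(u, v) {
  if (length(u) != length(v)) {
    stop("vectors must have equal length")
  }
  if (length(u) < 3L) {
    stop("need at least 3 paired observations")
  }
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    stop("undefined correlation: constant vector")
  }
  ct <- stats::cor.test(u, v, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(u))
}

#' Root mean square error
#'
#' `sqrt(mean((predicted - actual)^2))`, the headline error metric for the
#' trait regressions (trait scores are raw subscale sums, so RMSE is in
#' score points).
#'
#' @param predicted,actual Numeric vectors of equal length >= 1.
#' @return Non-negative scalar.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("length mismatch between predicted and actual")
  }
  if (length(predicted) < 1L) {
    stop("empty input")
  }
  sqrt(mean((predicted - actual)^2))
}

.aggStream <- function(preds, stream) {
  stopifnot(inherits(preds, "PredictionSet"))
  if (!stream %in% colnames(preds$aggregated)) {
    stop("prediction set has no '", stream, "' stream")
  }
  preds$aggregated[, stream]
}

#' Odd-even split-half reliability of a trait model
#'
#' Reliability is the correlation between the predictions the model produces
#' from the odd-frame half and from the even-frame half of each subject's
#' gait (repetition-averaged out-of-fold predictions). A reliable model
#' extracts the same signal from either half.
#'
#' @param preds A `PredictionSet` (from [repeatedCvPredict()]) with odd and
#'   even streams, or a named list of them.
#' @return For a single set, a list with `r2`, `p`, `n`; for a list, a named
#'   list of those.
#' @export
splitHalfReliability <- function(preds) {
  if (inherits(preds, "PredictionSet")) {
    pr <- pearsonR(.aggStream(preds, "odd"), .aggStream(preds, "even"))
    return(list(r2 = pr$r, p = pr$p, n = pr$n))
  }
  lapply(preds, splitHalfReliability)
}

#' Criterion validity, RMSE and reliability per trait
#'
#' Per trait: RMSE and criterion validity r1 (Pearson correlation of the
#' repetition-averaged all-frames out-of-fold predictions with the BFI-44
#' subscale scores as ground truth), and the odd-even split-half reliability
#' r2, with t-distribution p-values; plus the means across traits.
#'
#' @param preds Named list of `PredictionSet` objects, one per trait.
#' @param scores Data frame of subscale scores with one column per trait
#'   name in `preds` (subjects in the same order as the feature matrices).
#' @return An `EvaluationReport`: list with `table` (data frame of trait,
#'   rmse, r1, r1_p, r2, r2_p) and `means`.
#' @export
criterionValidityTable <- function(preds, scores) {
  stopifnot(is.list(preds), length(preds) >= 1L)
  traits <- names(preds)
  stopifnot(all(traits %in% names(scores)))
  rows <- lapply(traits, function(tr) {
    p <- preds[[tr]]
    yhat <- .aggStream(p, "all")
    y <- scores[[tr]]
    r1 <- pearsonR(yhat, y)
    r2 <- if ("odd" %in% colnames(p$aggregated)) {
      splitHalfReliability(p)
    } else {
      list(r2 = NA_real_, p = NA_real_)
    }
    data.frame(
      trait = tr, rmse = rmse(yhat, y), r1 = r1$r, r1_p = r1$p,
      r2 = r2$r2, r2_p = r2$p, stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  means <- c(
    rmse = mean(tab$rmse), r1 = mean(tab$r1), r2 = mean(tab$r2)
  )
  structure(list(table = tab, means = means), class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, digits = 3L, ...) {
  cat("Per-trait criterion validity (r1) and split-half reliability (r2):\n")
  tab <- x$table
  tab[-1L] <- lapply(tab[-1L], round, digits = digits)
  print(tab, row.names = FALSE)
  cat(sprintf(
    "Means: RMSE %.3f, r1 %.3f, r2 %.3f\n",
    x$means["rmse"], x$means["r1"], x$means["r2"]
  ))
  invisible(x)
}

#' Multitrait-multimethod matrix of model and scale scores
#'
#' The 10 x 10 Pearson correlation matrix over the five traits measured by
#' two methods: the gait model (aggregated all-frames predictions) and the
#' BFI-44 scale. Entry blocks: the diagonal of the model-vs-scale cross
#' block holds the convergent validities (same trait, different method); the
#' off-diagonal triangles of the model and scale blocks hold the
#' discriminant (hetero-trait mono-method) correlations; the remaining cross
#' entries are hetero-trait hetero-method correlations.
#'
#' @param preds Named list of `PredictionSet` objects, or a subjects x 5
#'   matrix of model scores with trait column names.
#' @param scores Data frame or matrix of subscale scores, same trait
#'   columns, same subject order.
#' @return An `MTMMMatrix` object: list with `matrix` (10 x 10, labelled
#'   `model.<trait>` / `scale.<trait>`), `model`, `scale`, `traits`.
#' @seealso [validitySummary()], [convergentValidities()]
#' @export
mtmmMatrix <- function(preds, scores) {
  if (is.list(preds) && !is.matrix(preds) && !is.data.frame(preds)) {
    traits <- names(preds)
    model <- vapply(
      preds, function(p) .aggStream(p, "all"),
      numeric(nrow(preds[[1L]]$aggregated))
    )
  } else {
    model <- as.matrix(preds)
    traits <- colnames(model)
  }
  scale <- as.matrix(as.data.frame(scores)[, traits, drop = FALSE])
  stopifnot(nrow(model) == nrow(scale), length(traits) >= 2L)
  combined <- cbind(model, scale)
  colnames(combined) <- c(
    paste0("model.", traits), paste0("scale.", traits)
  )
  M <- stats::cor(combined)
  structure(
    list(matrix = M, model = model, scale = scale, traits = traits),
    class = "MTMMMatrix"
  )
}

#' Block extractors for an MTMM matrix
#'
#' `convergentValidities()`: the mono-trait hetero-method entries (one per
#' trait). `discriminantCorrelations()`: the hetero-trait mono-method
#' entries of the requested method block (`choose(k, 2)` values).
#' `heteroMethodHetero()`: the hetero-trait hetero-method entries of the
#' cross block.
#'
#' @param mtmm An `MTMMMatrix`.
#' @return Named numeric vector of correlations.
#' @export
convergentValidities <- function(mtmm) {
  stopifnot(inherits(mtmm, "MTMMMatrix"))
  k <- length(mtmm$traits)
  cross <- mtmm$matrix[seq_len(k), k + seq_len(k), drop = FALSE]
  stats::setNames(diag(cross), mtmm$traits)
}

#' @rdname convergentValidities
#' @param method `"model"` or `"scale"`.
#' @export
discriminantCorrelations <- function(mtmm, method = c("model", "scale")) {
  stopifnot(inherits(mtmm, "MTMMMatrix"))
  method <- match.arg(method)
  k <- length(mtmm$traits)
  idx <- if (method == "model") seq_len(k) else k + seq_len(k)
  block <- mtmm$matrix[idx, idx, drop = FALSE]
  pairs <- which(upper.tri(block), arr.ind = TRUE)
  stats::setNames(
    block[upper.tri(block)],
    paste(mtmm$traits[pairs[, 1L]], mtmm$traits[pairs[, 2L]], sep = ":")
  )
}

#' @rdname convergentValidities
#' @export
heteroMethodHetero <- function(mtmm) {
  stopifnot(inherits(mtmm, "MTMMMatrix"))
  k <- length(mtmm$traits)
  cross <- mtmm$matrix[seq_len(k), k + seq_len(k), drop = FALSE]
  off <- row(cross) != col(cross)
  pairs <- which(off, arr.ind = TRUE)
  stats::setNames(
    cross[off],
    paste(mtmm$traits[pairs[, 1L]], mtmm$traits[pairs[, 2L]], sep = ":")
  )
}

#' @export
print.MTMMMatrix <- function(x, digits = 3L, ...) {
  cat(sprintf(
    "Multitrait-multimethod matrix (%d traits x 2 methods)\n",
    length(x$traits)
  ))
  print(round(x$matrix, digits))
  invisible(x)
}

#' Convergent / discriminant validity summary of an MTMM matrix
#'
#' Reports the mean convergent validity, the mean absolute discriminant
#' correlation within each method block, and a permutation test of whether
#' the convergent entries exceed the hetero-trait hetero-method entries:
#' subject labels of the model method are permuted `nPerm` times and the
#' statistic mean(convergent) - mean(|hetero-method hetero-trait|) is
#' recomputed. Entries whose |r| is not significant at p < 0.001 (n - 2 df
#' t test) are flagged.
#'
#' @param mtmm An `MTMMMatrix`.
#' @param nPerm Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return A `ValiditySummary`: list with `meanConvergent`,
#'   `meanModelDiscriminant`, `meanScaleDiscriminant`, `meanHeteroMethod`,
#'   `permutationP`, `nonSignificant`.
#' @export
validitySummary <- function(mtmm, nPerm = 1000L, seed = 1L) {
  stopifnot(inherits(mtmm, "MTMMMatrix"))
  conv <- convergentValidities(mtmm)
  discM <- discriminantCorrelations(mtmm, "model")
  discS <- discriminantCorrelations(mtmm, "scale")
  hthm <- heteroMethodHetero(mtmm)
  obs <- mean(conv) - mean(abs(hthm))
  n <- nrow(mtmm$model)
  permStats <- localSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      perm <- sample.int(n)
      cross <- stats::cor(mtmm$model[perm, , drop = FALSE], mtmm$scale)
      off <- row(cross) != col(cross)
      mean(diag(cross)) - mean(abs(cross[off]))
    }, numeric(1L))
  })
  permP <- (1 + sum(permStats >= obs)) / (1 + nPerm)
  entryP <- function(r) {
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2)
  }
  allEntries <- c(conv, discM, discS, hthm)
  ns <- allEntries[entryP(allEntries) >= 0.001]
  structure(
    list(
      meanConvergent = mean(conv),
      meanModelDiscriminant = mean(abs(discM)),
      meanScaleDiscriminant = mean(abs(discS)),
      meanHeteroMethod = mean(abs(hthm)),
      permutationP = permP,
      nonSignificant = ns,
      n = n
    ),
    class = "ValiditySummary"
  )
}

#' @export
print.ValiditySummary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Mean convergent validity: %.3f\n",
      "Mean |discriminant| (model block): %.3f\n",
      "Mean |discriminant| (scale block): %.3f\n",
      "Mean |hetero-trait hetero-method|: %.3f\n",
      "Permutation p (convergent > hetero-method): %.4g\n"
    ),
    x$meanConvergent, x$meanModelDiscriminant, x$meanScaleDiscriminant,
    x$meanHeteroMethod, x$permutationP
  ))
  if (length(x$nonSignificant)) {
    cat(
      "Entries not significant at p < 0.001:",
      paste(names(x$nonSignificant), collapse = ", "), "\n"
    )
  }
  invisible(x)
}
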