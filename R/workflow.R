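#' End-to-end trait assessment over a cohort
#'
#' Convenience wrapper running [repeatedCvPredict()] for each requested
#' trait and assembling the psychometric evaluation: the per-trait criterion
#' validity / RMSE / split-half reliability table and, when all five traits
#' are assessed, the multitrait-multimethod matrix with its validity
#' summary.
#'
#' @param features Feature matrices from [extractCohortFeatures()].
#' @param scores Data frame of BFI-44 subscale scores (columns named by
#'   trait), subjects in the same row order as the feature matrices.
#' @param algorithm One of [gaitAlgorithms()].
#' @param traits Traits to assess (default all five).
#' @param repeats,folds,seed,k,params,sfsEstimator,stackMode Passed to
#'   [repeatedCvPredict()].
#' @return List with `predictions` (named list of `PredictionSet`),
#'   `report` (an `EvaluationReport`), and -- for the full five traits --
#'   `mtmm` and `validity`.
#' @examples
#' \donttest{
#' cohort <- generateCohort(syntheticConfig(nSubjects = 30, seed = 7))
#' feats <- extractCohortFeatures(cohort$sequences)
#' res <- runTraitAssessment(feats, cohort$scores,
#'   algorithm = "lr",
#'   traits = "extraversion", repeats = 2, folds = 5, k = 10
#' )
#' res$report
#' }
#' @export
runTraitAssessment <- function(features, scores, algorithm = "lr",
                               traits = bigFiveTraits()$trait,
                               repeats = 10L, folds = 10L, seed = 1L,
                               k = 40L, params = list(), sfsEstimator = NULL,
                               stackMode = "per-fold") {
  stopifnot(all(traits %in% names(scores)))
  predictions <- stats::setNames(lapply(traits, function(tr) {
    repeatedCvPredict(features, scores[[tr]],
      trait = tr, algorithm = algorithm, repeats = repeats, folds = folds,
      seed = deriveSeed(seed, match(tr, .BIG5)), k = k, params = params,
      sfsEstimator = sfsEstimator, stackMode = stackMode
    )
  }), traits)
  out <- list(
    predictions = predictions,
    report = criterionValidityTable(predictions, scores)
  )
  if (length(traits) == 5L) {
    out$mtmm <- mtmmMatrix(predictions, scores)
    out$validity <- validitySummary(out$mtmm, seed = seed)
  }
  out
}
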