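## Mapping model-selected features back to body keypoints: the inverse of
## feature construction, with weights reflecting how many keypoints each
## feature was built from.

#' Keypoint weights of a single feature
#'
#' Inverts the feature-construction grammar: a coordinate, difference or
#' wavelet feature of keypoint k maps wholly to k; a distance feature
#' `dist_a_b_*` splits its mass half/half between a and b; an angle feature
#' `angle_a_b_c` splits it in thirds. MidHip (keypoint 8) was the coordinate
#' origin and can never appear.
#'
#' @param featureName A feature name following the [gaitFeatureNames()]
#'   grammar.
#' @return Named numeric vector (names = keypoint indices) summing to 1.
#' @examples
#' featureKeypointWeights("dist_7_4_x__mean") # 7 and 4, half each
#' @export
featureKeypointWeights <- function(featureName) {
  base <- strsplit(featureName, "__", fixed = TRUE)[[1L]][1L]
  parts <- strsplit(base, "_", fixed = TRUE)[[1L]]
  kind <- parts[1L]
  nums <- suppressWarnings(as.integer(parts[-1L]))
  weights <- switch(kind,
    coord = ,
    diff = stats::setNames(1, parts[2L]),
    dist = stats::setNames(c(0.5, 0.5), parts[2:3]),
    angle = stats::setNames(rep(1 / 3, 3L), parts[2:4]),
    stop("unparseable feature name: ", featureName)
  )
  kp <- as.integer(names(weights))
  if (anyNA(kp) || any(kp < 0L | kp > 24L) || any(kp == .MIDHIP)) {
    stop("unparseable feature name: ", featureName)
  }
  weights
}

## 24 x 2472 matrix distributing each feature's unit mass over keypoints
.keypointWeightMatrix <- function(featureNames) {
  kp <- .translatedKeypoints()
  W <- matrix(0, length(kp), length(featureNames),
    dimnames = list(as.character(kp), featureNames)
  )
  for (j in seq_along(featureNames)) {
    w <- featureKeypointWeights(featureNames[j])
    W[names(w), j] <- w
  }
  W
}

#' Keypoint contribution statistics of a fitted transform stack
#'
#' Maps the SFS-selected principal components back to the 24 body keypoints.
#' Each selected component distributes one unit of mass over the raw
#' features in proportion to its absolute PCA loadings (`weighting =
#' "abs"`, default) or squared loadings (`"squared"`); each feature's mass
#' then flows to the keypoints it was constructed from via
#' [featureKeypointWeights()]. Total keypoint mass therefore equals the
#' number of selected components.
#'
#' @param stack A fitted `TransformStack` (from [fitTransformStack()] or a
#'   `TraitModel`'s `$stack`).
#' @param weighting `"abs"` or `"squared"` loading weights.
#' @return A `KeypointStats` data frame with columns `keypoint`, `label`,
#'   `weight`, `rank`, `topHalf` (membership in the top 50% by weight).
#' @export
keypointContributionStats <- function(stack, weighting = c("abs", "squared")) {
  if (inherits(stack, "TraitModel")) stack <- stack$stack
  stopifnot(inherits(stack, "TransformStack"))
  weighting <- match.arg(weighting)
  featureNames <- stack$featureNames %||% gaitFeatureNames()
  loadings <- stack$rotation[, stack$selected, drop = FALSE]
  mass <- if (weighting == "abs") abs(loadings) else loadings^2
  mass <- sweep(mass, 2L, colSums(mass), "/")
  W <- .keypointWeightMatrix(featureNames)
  kpWeight <- drop(W %*% rowSums(mass))
  kp <- .translatedKeypoints()
  ord <- order(-kpWeight, kp) # ties -> lower keypoint index first
  rank <- integer(length(kp))
  rank[ord] <- seq_along(kp)
  topn <- ceiling(length(kp) * 0.5)
  out <- data.frame(
    keypoint = kp,
    label = .BODY25_LABELS[kp + 1L],
    weight = unname(kpWeight),
    rank = rank,
    topHalf = rank <= topn,
    stringsAsFactors = FALSE
  )
  class(out) <- c("KeypointStats", "data.frame")
  out
}

#' Intersection of the top-weighted keypoints of two models
#'
#' Ranks each model's keypoints by contribution weight (ties to the lower
#' index), keeps the top `ceiling(24 * fraction)` of each, and returns the
#' intersection -- the keypoints both models rely on.
#'
#' @param statsA,statsB `KeypointStats` from [keypointContributionStats()].
#' @param fraction Top fraction to keep (default 0.5, i.e. 12 keypoints).
#' @return Integer vector of keypoint indices, ascending.
#' @export
topHalfIntersection <- function(statsA, statsB, fraction = 0.5) {
  topSet <- function(st) {
    stopifnot(inherits(st, "KeypointStats"))
    topn <- ceiling(nrow(st) * fraction)
    st$keypoint[st$rank <= topn]
  }
  sort(intersect(topSet(statsA), topSet(statsB)))
}
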