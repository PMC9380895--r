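#' GaitSequence: a 2-D body-keypoint walking sequence
#'
#' Container for one subject's gait recording as per-frame OpenPose BODY_25
#' keypoints: an array of `frames x 25 keypoints x (x, y)` pixel coordinates
#' plus a per-point detection confidence in `[0, 1]` (1 where the source
#' format carries none).
#'
#' @slot subjectId Character scalar identifying the subject.
#' @slot coords Numeric array `frames x 25 x 2`; third dimension is `c("x", "y")`.
#' @slot confidence Numeric matrix `frames x 25` of detection confidences.
#'
#' @seealso [readOpenPoseFrames()], [readKeypointCsv()], [unifyFrames()],
#'   [translateToMidHip()]
#' @export
setClass("GaitSequence",
  representation(
    subjectId = "character",
    coords = "array",
    confidence = "matrix"
  )
)

setValidity("GaitSequence", function(object) {
  d <- dim(object@coords)
  if (length(object@subjectId) != 1L) {
    return("subjectId must be a single string")
  }
  if (length(d) != 3L || d[2L] != 25L || d[3L] != 2L) {
    return("coords must be a frames x 25 x 2 array")
  }
  if (d[1L] < 1L) {
    return("a sequence needs at least one frame")
  }
  if (!all(dim(object@confidence) == d[1:2])) {
    return("confidence must be a frames x 25 matrix")
  }
  if (anyNA(object@coords) || any(!is.finite(object@coords))) {
    return("coordinates must be finite")
  }
  if (any(object@confidence < 0 | object@confidence > 1)) {
    return("confidences must lie in [0, 1]")
  }
  TRUE
})

#' TranslatedSequence: MidHip-origin keypoint sequence
#'
#' A [GaitSequence-class] after coordinate translation: per frame, MidHip
#' (keypoint 8) is subtracted from every keypoint and then removed, leaving
#' 24 keypoints in the body-centred coordinate system in which all gait
#' features are constructed.
#'
#' @slot subjectId Character scalar identifying the subject.
#' @slot coords Numeric array `frames x 24 x 2`; keypoint dimension carries
#'   the retained BODY_25 indices (0--24 without 8) as dimnames.
#'
#' @seealso [translateToMidHip()], [smoothSequence()], [splitOddEven()],
#'   [extractFeatureVector()]
#' @export
setClass("TranslatedSequence",
  representation(
    subjectId = "character",
    coords = "array"
  )
)

setValidity("TranslatedSequence", function(object) {
  d <- dim(object@coords)
  if (length(object@subjectId) != 1L) {
    return("subjectId must be a single string")
  }
  if (length(d) != 3L || d[2L] != 24L || d[3L] != 2L) {
    return("coords must be a frames x 24 x 2 array")
  }
  kp <- dimnames(object@coords)[[2L]]
  if (is.null(kp) || !identical(kp, as.character(.translatedKeypoints()))) {
    return("keypoint dimnames must be BODY_25 indices 0..24 without 8 (MidHip)")
  }
  if (anyNA(object@coords) || any(!is.finite(object@coords))) {
    return("coordinates must be finite")
  }
  TRUE
})

#' FeaturePool: named gait time series and wavelet bands
#'
#' The intermediate feature data pool built from a [TranslatedSequence-class]:
#' 132 named time series (48 coordinate, 48 interframe-difference, 26 joint
#' distance, 10 joint angle series) and, for each of the 48 coordinate
#' series, the 6 Haar wavelet coefficient arrays D1..D5, A5.
#'
#' @slot series Named list of 132 numeric time series.
#' @slot waveletBands Named list (one entry per coordinate series) of named
#'   lists of the 6 coefficient arrays.
#' @slot nFrames Integer, frame count of the source sequence.
#'
#' @seealso [buildFeaturePool()], [extractFeatureVector()]
#' @export
setClass("FeaturePool",
  representation(
    series = "list",
    waveletBands = "list",
    nFrames = "integer"
  )
)

setValidity("FeaturePool", function(object) {
  if (length(object@series) != 132L) {
    return("feature pool must hold exactly 132 time series")
  }
  if (anyDuplicated(names(object@series))) {
    return("series names must be unique")
  }
  if (length(object@waveletBands) != 48L) {
    return("wavelet bands must cover exactly the 48 coordinate series")
  }
  if (!all(vapply(object@waveletBands, length, 1L) == 6L)) {
    return("each coordinate series must have 6 wavelet coefficient arrays")
  }
  TRUE
})

## ---- generics ----

#' @rdname GaitSequence-class
#' @param x,object A sequence object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname GaitSequence-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname GaitSequence-class
#' @export
setGeneric("keypointCoords", function(x) standardGeneric("keypointCoords"))

#' @rdname GaitSequence-class
#' @export
setGeneric("keypointConfidence", function(x) standardGeneric("keypointConfidence"))

#' @rdname GaitSequence-class
#' @export
setMethod("nFrames", "GaitSequence", function(x) dim(x@coords)[1L])

#' @rdname GaitSequence-class
#' @export
setMethod("nFrames", "TranslatedSequence", function(x) dim(x@coords)[1L])

#' @rdname GaitSequence-class
#' @export
setMethod("subjectId", "GaitSequence", function(x) x@subjectId)

#' @rdname GaitSequence-class
#' @export
setMethod("subjectId", "TranslatedSequence", function(x) x@subjectId)

#' @rdname GaitSequence-class
#' @export
setMethod("keypointCoords", "GaitSequence", function(x) x@coords)

#' @rdname GaitSequence-class
#' @export
setMethod("keypointCoords", "TranslatedSequence", function(x) x@coords)

#' @rdname GaitSequence-class
#' @export
setMethod("keypointConfidence", "GaitSequence", function(x) x@confidence)

setMethod("show", "GaitSequence", function(object) {
  cat(sprintf(
    "GaitSequence '%s': %d frames, 25 BODY_25 keypoints (mean confidence %.3f)\n",
    object@subjectId, nFrames(object), mean(object@confidence)
  ))
})

setMethod("show", "TranslatedSequence", function(object) {
  cat(sprintf(
    "TranslatedSequence '%s': %d frames, 24 keypoints (MidHip-origin coordinates)\n",
    object@subjectId, nFrames(object)
  ))
})

setMethod("show", "FeaturePool", function(object) {
  cat(sprintf(
    "FeaturePool: %d time series over %d frames; wavelet bands for %d coordinate series\n",
    length(object@series), object@nFrames, length(object@waveletBands)
  ))
})

## ---- constructors ----

#' Construct a GaitSequence
#'
#' @param subjectId Subject identifier.
#' @param coords Numeric array `frames x 25 x 2`.
#' @param confidence Optional `frames x 25` confidence matrix; defaults to 1.
#' @return A [GaitSequence-class] object.
#' @examples
#' coords <- array(rnorm(2 * 25 * 2, 500, 50), c(2, 25, 2))
#' GaitSequence("demo", coords)
#' @export
GaitSequence <- function(subjectId, coords, confidence = NULL) {
  coords <- unname(coords)
  dimnames(coords) <- list(NULL, as.character(0:24), c("x", "y"))
  if (is.null(confidence)) {
    confidence <- matrix(1, dim(coords)[1L], 25L)
  }
  confidence <- unname(as.matrix(confidence))
  new("GaitSequence",
    subjectId = as.character(subjectId),
    coords = coords, confidence = confidence
  )
}

TranslatedSequence <- function(subjectId, coords) {
  dimnames(coords) <- list(
    NULL, as.character(.translatedKeypoints()), c("x", "y")
  )
  new("TranslatedSequence", subjectId = as.character(subjectId), coords = coords)
}
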