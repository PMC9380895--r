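#' Translate keypoints to the MidHip-origin coordinate system
#'
#' Raw pixel coordinates depend on where the subject stands in the image.
#' Translating every frame so that MidHip (keypoint 8, the pelvis centre and
#' a good proxy for the body's centre of gravity) becomes the origin,
#' `x'_i = x_i - x_8`, `y'_i = y_i - y_8`, removes that positional component
#' and exposes the periodic structure of the gait. MidHip itself becomes
#' identically zero and is eliminated, leaving 24 keypoints.
#'
#' @param seq A [GaitSequence-class] (MidHip must be valid in every frame;
#'   run [interpolateMissing()] first for raw OpenPose output).
#' @return A [TranslatedSequence-class] with 24 keypoints.
#' @examples
#' coords <- array(rnorm(75 * 25 * 2, 500, 40), c(75, 25, 2))
#' ts <- translateToMidHip(GaitSequence("demo", coords))
#' dim(keypointCoords(ts)) # 75 x 24 x 2
#' @export
translateToMidHip <- function(seq) {
  stopifnot(is(seq, "GaitSequence"))
  mid <- seq@coords[, .MIDHIP + 1L, , drop = FALSE]
  keep <- setdiff(seq_len(25L), .MIDHIP + 1L)
  out <- seq@coords[, keep, , drop = FALSE] -
    mid[, rep(1L, 24L), , drop = FALSE]
  TranslatedSequence(seq@subjectId, out)
}

#' Smooth a coordinate series with the binomial 5-tap kernel
#'
#' Keypoint tracks carry high-frequency jitter from the pose estimator and
#' video background. Each coordinate series is convolved with the unit-sum
#' binomial kernel `[1, 4, 6, 4, 1] / 16`; boundaries use half-sample
#' symmetric (reflect) padding, which preserves constants and keeps the
#' output length equal to the input length.
#'
#' @param series Numeric vector of length >= 5.
#' @return Smoothed numeric vector of the same length.
#' @examples
#' smoothSeries(c(0, 0, 16, 0, 0)) # impulse -> kernel weights x 16
#' @export
smoothSeries <- function(series) {
  n <- length(series)
  if (n < 5L) {
    stop("series too short to smooth: need at least 5 points, got ", n)
  }
  ext <- c(series[2L], series[1L], series, series[n], series[n - 1L])
  kernel <- c(1, 4, 6, 4, 1) / 16
  out <- numeric(n)
  for (j in seq_len(n)) {
    out[j] <- sum(ext[j:(j + 4L)] * kernel)
  }
  out
}

#' Smooth every coordinate series of a translated sequence
#'
#' Applies [smoothSeries()] independently to each of the 48 coordinate
#' series (24 keypoints x two axes).
#'
#' @param seq A [TranslatedSequence-class] with at least 5 frames.
#' @return A smoothed [TranslatedSequence-class].
#' @export
smoothSequence <- function(seq) {
  stopifnot(is(seq, "TranslatedSequence"))
  coords <- seq@coords
  for (k in seq_len(24L)) {
    for (ax in 1:2) {
      coords[, k, ax] <- smoothSeries(coords[, k, ax])
    }
  }
  TranslatedSequence(seq@subjectId, coords)
}

#' Split a 75-frame sequence into odd- and even-frame halves
#'
#' For odd-even split-half reliability the first 74 frames are divided into
#' the odd-indexed frames (1, 3, ..., 73) and the even-indexed frames
#' (2, 4, ..., 74), 37 frames each; frame 75 is unused in the halves. Frame
#' parity is 1-based.
#'
#' @param seq A [TranslatedSequence-class] with exactly 75 frames.
#' @return List with elements `odd` and `even`, each a 37-frame
#'   [TranslatedSequence-class].
#' @seealso [splitHalfReliability()]
#' @export
splitOddEven <- function(seq) {
  stopifnot(is(seq, "TranslatedSequence"))
  if (nFrames(seq) != 75L) {
    stop("odd/even splitting requires exactly 75 frames, got ", nFrames(seq))
  }
  odd <- seq(1L, 73L, by = 2L)
  even <- seq(2L, 74L, by = 2L)
  list(
    odd = TranslatedSequence(seq@subjectId, seq@coords[odd, , , drop = FALSE]),
    even = TranslatedSequence(seq@subjectId, seq@coords[even, , , drop = FALSE])
  )
}
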