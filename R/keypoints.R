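## BODY_25 keypoint schema and the joint pairs / triples used in feature
## construction. Indices are the OpenPose 0-based labels.

.BODY25_LABELS <- c(
  "Nose", "Neck", "RShoulder", "RElbow", "RWrist",
  "LShoulder", "LElbow", "LWrist", "MidHip", "RHip",
  "RKnee", "RAnkle", "LHip", "LKnee", "LAnkle",
  "REye", "LEye", "REar", "LEar", "LBigToe",
  "LSmallToe", "LHeel", "RBigToe", "RSmallToe", "RHeel"
)

.MIDHIP <- 8L

## 13 joint pairs whose per-axis distances are tracked (head swing, arm
## swings, strides, relative swings of elbows/hands/knees/feet).
.DIST_PAIRS <- matrix(c(
  1L, 0L,
  3L, 2L,
  4L, 2L,
  6L, 5L,
  7L, 5L,
  6L, 3L,
  7L, 4L,
  10L, 9L,
  11L, 9L,
  13L, 12L,
  14L, 12L,
  13L, 10L,
  14L, 11L
), ncol = 2L, byrow = TRUE)

## 10 joint triples (a, b, c): the angle at vertex b between rays b->a and
## b->c. Neck, shoulder, elbow, hip and knee angles on both body sides; the
## hip angles use the hips themselves in place of the eliminated MidHip.
.ANGLE_TRIPLES <- matrix(c(
  0L, 1L, 2L,
  0L, 1L, 5L,
  1L, 2L, 3L,
  1L, 5L, 6L,
  2L, 3L, 4L,
  5L, 6L, 7L,
  12L, 9L, 10L,
  9L, 12L, 13L,
  9L, 10L, 11L,
  12L, 13L, 14L
), ncol = 3L, byrow = TRUE)

#' BODY_25 keypoint labels
#'
#' @return Named character vector of the 25 OpenPose BODY_25 keypoint names;
#'   names are the 0-based keypoint indices `"0"` to `"24"`.
#' @examples
#' bodyPartLabels()[["8"]] # "MidHip"
#' @export
bodyPartLabels <- function() {
  stats::setNames(.BODY25_LABELS, as.character(0:24))
}

## keypoint indices retained after MidHip elimination, ascending
.translatedKeypoints <- function() setdiff(0:24, .MIDHIP)
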