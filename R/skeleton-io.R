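#' Read an OpenPose BODY_25 keypoint sequence
#'
#' Reads a directory of per-frame OpenPose JSON files (one file per frame,
#' lexicographic file order = frame order) into a [GaitSequence-class]. Each
#' file must carry `people[[i]]$pose_keypoints_2d` as 75 floats
#' (x, y, confidence for 25 keypoints). When a frame contains several
#' detected people, the one with the highest summed keypoint confidence is
#' taken: the recording protocol has a single walker per video, so extra
#' detections are background.
#'
#' @param path Directory containing the per-frame `.json` files.
#' @param subjectId Subject identifier; defaults to the directory name.
#' @return A [GaitSequence-class].
#' @seealso [readKeypointCsv()], [interpolateMissing()], [unifyFrames()]
#' @export
readOpenPoseFrames <- function(path, subjectId = basename(normalizePath(path))) {
  if (!dir.exists(path)) {
    stop("not a directory: ", path)
  }
  files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0L) {
    stop("no OpenPose JSON files found in ", path)
  }
  n <- length(files)
  coords <- array(0, c(n, 25L, 2L))
  conf <- matrix(0, n, 25L)
  for (i in seq_len(n)) {
    js <- tryCatch(
      jsonlite::fromJSON(files[i], simplifyVector = FALSE),
      error = function(e) {
        stop("malformed JSON in ", files[i], ": ", conditionMessage(e))
      }
    )
    people <- js$people
    if (is.null(people) || length(people) == 0L) {
      stop("no detected person in ", files[i])
    }
    best <- NULL
    bestConf <- -Inf
    for (p in people) {
      kp <- suppressWarnings(as.numeric(unlist(p$pose_keypoints_2d)))
      if (length(kp) != 75L || anyNA(kp)) {
        stop(
          "schema error in ", files[i],
          ": pose_keypoints_2d must be 75 numbers (25 keypoints x x,y,confidence), got ",
          length(kp)
        )
      }
      m <- matrix(kp, ncol = 3L, byrow = TRUE)
      if (sum(m[, 3L]) > bestConf) {
        bestConf <- sum(m[, 3L])
        best <- m
      }
    }
    coords[i, , ] <- best[, 1:2]
    conf[i, ] <- pmin(pmax(best[, 3L], 0), 1)
  }
  GaitSequence(subjectId, coords, conf)
}

#' Read / write a keypoint sequence as flat CSV
#'
#' The CSV dialect has columns `frame,keypoint,x,y,confidence` (confidence
#' optional on read), 1-based frame indices and 0-based BODY_25 keypoint
#' indices, 25 rows per frame. `writeKeypointCsv()` formats coordinates with
#' 17 significant digits so a write/read round trip is bit-exact.
#'
#' @param path CSV file path.
#' @param subjectId Subject identifier; defaults to the file name stem.
#' @return `readKeypointCsv()` a [GaitSequence-class]; `writeKeypointCsv()`
#'   the path, invisibly.
#' @seealso [readOpenPoseFrames()]
#' @export
readKeypointCsv <- function(path, subjectId = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "keypoint", "x", "y")
  if (!all(need %in% names(df))) {
    stop("keypoint CSV must have columns frame,keypoint,x,y[,confidence]")
  }
  for (col in intersect(c(need, "confidence"), names(df))) {
    if (!is.numeric(df[[col]])) {
      stop("non-numeric values in column '", col, "' of ", path)
    }
  }
  frames <- sort(unique(df$frame))
  n <- length(frames)
  coords <- array(NA_real_, c(n, 25L, 2L))
  conf <- matrix(1, n, 25L)
  hasConf <- "confidence" %in% names(df)
  for (i in seq_len(n)) {
    rows <- df[df$frame == frames[i], , drop = FALSE]
    missing <- setdiff(0:24, rows$keypoint)
    if (length(missing) > 0L) {
      stop(
        "frame ", frames[i], " is missing keypoint(s) ",
        paste(missing, collapse = ", ")
      )
    }
    rows <- rows[match(0:24, rows$keypoint), , drop = FALSE]
    coords[i, , 1L] <- rows$x
    coords[i, , 2L] <- rows$y
    if (hasConf) conf[i, ] <- rows$confidence
  }
  GaitSequence(subjectId, coords, conf)
}

#' @rdname readKeypointCsv
#' @param seq A [GaitSequence-class] to write.
#' @export
writeKeypointCsv <- function(seq, path) {
  stopifnot(is(seq, "GaitSequence"))
  n <- nFrames(seq)
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  df <- data.frame(
    frame = rep(seq_len(n), each = 25L),
    keypoint = rep(0:24, times = n),
    x = fmt(as.vector(t(seq@coords[, , 1L]))),
    y = fmt(as.vector(t(seq@coords[, , 2L]))),
    confidence = fmt(as.vector(t(seq@confidence)))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fill low-confidence keypoint detections by interpolation
#'
#' OpenPose marks undetected keypoints as `(0, 0)` with zero confidence, and
#' low-confidence detections are unreliable. Per keypoint track, frames whose
#' confidence falls below `confThreshold` (or that are exactly `(0, 0)` with
#' zero confidence) are replaced by linear interpolation of x and y over the
#' frame index; runs at either end are extended with the nearest valid value.
#' Coordinates at or above the threshold are never altered.
#'
#' @param seq A [GaitSequence-class].
#' @param confThreshold Confidence below which a detection is treated as
#'   missing (default 0.1).
#' @return A [GaitSequence-class] with all keypoints filled in.
#' @export
interpolateMissing <- function(seq, confThreshold = 0.1) {
  stopifnot(is(seq, "GaitSequence"))
  n <- nFrames(seq)
  coords <- seq@coords
  conf <- seq@confidence
  for (k in seq_len(25L)) {
    invalid <- conf[, k] < confThreshold |
      (coords[, k, 1L] == 0 & coords[, k, 2L] == 0 & conf[, k] == 0)
    if (!any(invalid)) next
    valid <- which(!invalid)
    if (length(valid) == 0L) {
      stop(
        "unrecoverable track: keypoint ", k - 1L, " (",
        .BODY25_LABELS[k], ") has no frame with confidence >= ",
        confThreshold
      )
    }
    for (ax in 1:2) {
      coords[, k, ax] <- stats::approx(
        x = valid, y = coords[valid, k, ax],
        xout = seq_len(n), method = "linear", rule = 2
      )$y
    }
  }
  GaitSequence(seq@subjectId, coords, conf)
}

#' Unify a sequence to a fixed-length analysis window
#'
#' Gait sequences of all subjects are unified to the same frame count
#' (75 frames by default) so that every feature is computed on the same
#' temporal support. A contiguous window of `n` frames is selected; among all
#' candidate windows the one with the highest mean keypoint confidence is
#' taken (ties resolved to the earliest window), and frames are renumbered
#' 1..n. Sequences shorter than `n` are refused rather than up-sampled, which
#' would distort the temporal sampling the features assume.
#'
#' @param seq A [GaitSequence-class] with at least `n` frames.
#' @param n Target frame count (default 75).
#' @return A [GaitSequence-class] with exactly `n` frames.
#' @export
unifyFrames <- function(seq, n = 75L) {
  stopifnot(is(seq, "GaitSequence"))
  total <- nFrames(seq)
  if (total < n) {
    stop(
      "insufficient frames: sequence '", seq@subjectId, "' has ", total,
      " frames but ", n, " are required"
    )
  }
  if (total == n) {
    return(seq)
  }
  frameConf <- rowMeans(seq@confidence)
  cs <- c(0, cumsum(frameConf))
  windowMean <- (cs[(n + 1):(total + 1)] - cs[1:(total - n + 1)]) / n
  start <- which.max(windowMean) # first maximum = earliest window on ties
  idx <- start:(start + n - 1L)
  GaitSequence(seq@subjectId, seq@coords[idx, , , drop = FALSE],
    confidence = seq@confidence[idx, , drop = FALSE]
  )
}
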