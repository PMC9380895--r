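## Feature construction: the feature data pool (coordinates, interframe
## differences, joint distances, joint angles, wavelet bands) and the
## 2472-dimensional time-frequency feature vector.

.TIME_FUNCTIONS <- c(
  "maximum", "minimum", "mean", "median", "variance", "root_mean_square",
  "skewness", "kurtosis", "abs_energy", "variation_coefficient"
)
.FREQ_STATS <- c("abs_max", "mean", "variance", "abs_energy")
.WAVELET_BANDS <- c("D1", "D2", "D3", "D4", "D5", "A5")

.coordSeriesNames <- function() {
  kp <- .translatedKeypoints()
  as.vector(t(outer(kp, c("x", "y"), function(k, a) paste0("coord_", k, "_", a))))
}

.diffSeriesNames <- function() sub("^coord_", "diff_", .coordSeriesNames())

.distSeriesNames <- function() {
  as.vector(t(outer(seq_len(nrow(.DIST_PAIRS)), c("x", "y"), function(i, a) {
    paste0("dist_", .DIST_PAIRS[i, 1L], "_", .DIST_PAIRS[i, 2L], "_", a)
  })))
}

.angleSeriesNames <- function() {
  apply(.ANGLE_TRIPLES, 1L, function(tr) {
    paste0("angle_", tr[1L], "_", tr[2L], "_", tr[3L])
  })
}

#' Canonical names of the 2472 gait features
#'
#' The feature vector is ordered deterministically: the 10 time-domain
#' summaries of each of the 132 pool series (48 coordinate, 48 difference,
#' 26 distance, 10 angle series; 1320 values, named `<series>__<function>`),
#' followed by the 4 frequency statistics of the 6 wavelet bands of each of
#' the 48 coordinate series (1152 values, named
#' `coord_<k>_<axis>__<band>__<stat>`).
#'
#' @return Character vector of length 2472.
#' @export
gaitFeatureNames <- function() {
  seriesNames <- c(
    .coordSeriesNames(), .diffSeriesNames(),
    .distSeriesNames(), .angleSeriesNames()
  )
  td <- as.vector(t(outer(seriesNames, .TIME_FUNCTIONS, paste, sep = "__")))
  fd <- as.vector(t(outer(
    .coordSeriesNames(),
    as.vector(t(outer(.WAVELET_BANDS, .FREQ_STATS, paste, sep = "__"))),
    paste,
    sep = "__"
  )))
  c(td, fd)
}

#' Forward interframe difference of a coordinate series
#'
#' The motion content of a gait lives in the change between adjacent frames:
#' `delta f_j = f_{j+1} - f_j`.
#'
#' @param series Numeric vector of length >= 2.
#' @return Numeric vector one element shorter than the input.
#' @examples
#' interframeDifference(c(1, 3, 6)) # 2 3
#' @export
interframeDifference <- function(series) {
  if (length(series) < 2L) {
    stop("interframe difference needs at least 2 frames")
  }
  diff(series)
}

#' Per-axis distances between the 13 tracked joint pairs
#'
#' For each joint pair (a, b) of the distance table (head swing, upper-arm /
#' arm swings, thigh / leg swings, and the relative swings of elbows, hands,
#' knees and feet) the per-frame axis distances `|x'_a - x'_b|` and
#' `|y'_a - y'_b|` are computed, giving 26 named series. Distances are
#' reported as magnitudes by default (a swing is a magnitude); set
#' `signed = TRUE` to keep signed differences instead.
#'
#' @param seq A [TranslatedSequence-class].
#' @param signed Keep signed differences instead of absolute values
#'   (default `FALSE`).
#' @return Named list of 26 numeric series (`dist_<a>_<b>_<axis>`).
#' @export
jointDistanceSeries <- function(seq, signed = FALSE) {
  stopifnot(is(seq, "TranslatedSequence"))
  kpIndex <- stats::setNames(
    seq_len(24L),
    as.character(.translatedKeypoints())
  )
  out <- list()
  for (i in seq_len(nrow(.DIST_PAIRS))) {
    a <- kpIndex[[as.character(.DIST_PAIRS[i, 1L])]]
    b <- kpIndex[[as.character(.DIST_PAIRS[i, 2L])]]
    for (ax in 1:2) {
      d <- seq@coords[, a, ax] - seq@coords[, b, ax]
      if (!signed) d <- abs(d)
      nm <- paste0(
        "dist_", .DIST_PAIRS[i, 1L], "_", .DIST_PAIRS[i, 2L], "_",
        c("x", "y")[ax]
      )
      out[[nm]] <- d
    }
  }
  out
}

#' Angles at the 10 tracked joint triples
#'
#' For each triple (a, b, c) of the angle table (neck, shoulder, elbow, hip
#' and knee angles on both sides) the per-frame angle at vertex b between
#' rays b->a and b->c is computed as the arccosine of the normalised dot
#' product, clipped to [-1, 1] against rounding, and reported in degrees in
#' [0, 180]. A zero-length ray (coincident keypoints) yields angle 0 with a
#' warning.
#'
#' @param seq A [TranslatedSequence-class].
#' @return Named list of 10 numeric series (`angle_<a>_<b>_<c>`).
#' @export
jointAngleSeries <- function(seq) {
  stopifnot(is(seq, "TranslatedSequence"))
  kpIndex <- stats::setNames(
    seq_len(24L),
    as.character(.translatedKeypoints())
  )
  out <- list()
  nDegenerate <- 0L
  pickKp <- function(k) {
    m <- seq@coords[, kpIndex[[as.character(k)]], , drop = FALSE]
    dim(m) <- c(dim(m)[1L], 2L)
    m
  }
  for (i in seq_len(nrow(.ANGLE_TRIPLES))) {
    tr <- .ANGLE_TRIPLES[i, ]
    a <- pickKp(tr[1L])
    b <- pickKp(tr[2L])
    cc <- pickKp(tr[3L])
    u <- a - b
    v <- cc - b
    nu <- sqrt(rowSums(u^2))
    nv <- sqrt(rowSums(v^2))
    ang <- numeric(length(nu))
    ok <- nu > 0 & nv > 0
    nDegenerate <- nDegenerate + sum(!ok)
    cosang <- rowSums(u * v)[ok] / (nu[ok] * nv[ok])
    ang[ok] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    out[[paste0("angle_", tr[1L], "_", tr[2L], "_", tr[3L])]] <- ang
  }
  if (nDegenerate > 0L) {
    warning(
      "zero-length ray in ", nDegenerate,
      " frame/angle combinations; angle set to 0"
    )
  }
  out
}

#' Build the feature data pool of a translated sequence
#'
#' Assembles the 132 time series on which features are computed: the 48
#' coordinate series (24 keypoints x two axes), their 48 forward interframe
#' difference series, the 26 joint-distance series, and the 10 joint-angle
#' series; plus, for each coordinate series, its 6 Haar wavelet coefficient
#' arrays (wavelet decomposition is applied to the coordinate series only).
#'
#' @param seq A preprocessed (translated, smoothed) [TranslatedSequence-class].
#' @param signedDistances Passed to [jointDistanceSeries()].
#' @return A [FeaturePool-class].
#' @export
buildFeaturePool <- function(seq, signedDistances = FALSE) {
  stopifnot(is(seq, "TranslatedSequence"))
  coordNames <- .coordSeriesNames()
  kp <- .translatedKeypoints()
  series <- list()
  for (j in seq_along(kp)) {
    series[[paste0("coord_", kp[j], "_x")]] <- seq@coords[, j, 1L]
    series[[paste0("coord_", kp[j], "_y")]] <- seq@coords[, j, 2L]
  }
  series <- series[coordNames]
  for (nm in coordNames) {
    series[[sub("^coord_", "diff_", nm)]] <- interframeDifference(series[[nm]])
  }
  series <- c(series, jointDistanceSeries(seq, signed = signedDistances))
  series <- c(series, jointAngleSeries(seq))
  bands <- lapply(series[coordNames], waveletDecompose)
  new("FeaturePool",
    series = series, waveletBands = bands,
    nFrames = nFrames(seq)
  )
}

#' Ten time-domain summaries of a series
#'
#' The linear and non-linear time-domain feature functions: maximum, minimum,
#' mean, median, variance, root mean square, skewness, kurtosis, absolute
#' energy (sum of squares) and coefficient of variation. Moments are
#' population moments; kurtosis is excess (Fisher) kurtosis; the coefficient
#' of variation is population-SD/mean, defined as 0 when the mean is 0, and
#' skewness/kurtosis are defined as 0 for a constant series so every feature
#' stays finite.
#'
#' @param series Numeric vector of length >= 2.
#' @return Named numeric vector of 10 values.
#' @examples
#' timeDomainSummary(c(1, 2, 3))[["variance"]] # population variance 2/3
#' @export
timeDomainSummary <- function(series) {
  n <- length(series)
  if (n < 2L) {
    stop("time-domain summary needs at least 2 samples")
  }
  m <- mean(series)
  centred <- series - m
  v <- mean(centred^2)
  absEnergy <- sum(series^2)
  c(
    maximum = max(series),
    minimum = min(series),
    mean = m,
    median = stats::median(series),
    variance = v,
    root_mean_square = sqrt(absEnergy / n),
    skewness = if (v > 0) mean(centred^3) / v^1.5 else 0,
    kurtosis = if (v > 0) mean(centred^4) / v^2 - 3 else 0,
    abs_energy = absEnergy,
    variation_coefficient = if (m == 0) 0 else sqrt(v) / m
  )
}

#' Four frequency-domain statistics of the six wavelet bands
#'
#' For each coefficient array D1..D5, A5: the absolute maximum, the mean,
#' the (population) variance, and the absolute energy (sum of squared
#' coefficients); 24 values per decomposed series.
#'
#' @param bands Output of [waveletDecompose()] (or any named list of 6
#'   non-empty coefficient arrays).
#' @return Named numeric vector of 24 values (`<band>__<stat>`).
#' @export
frequencyDomainSummary <- function(bands) {
  if (length(bands) != 6L) {
    stop("expected 6 coefficient arrays, got ", length(bands))
  }
  out <- numeric(0)
  for (b in names(bands)) {
    cfs <- bands[[b]]
    if (length(cfs) == 0L) {
      stop("empty coefficient array in band ", b)
    }
    vals <- c(
      max(abs(cfs)), mean(cfs), mean((cfs - mean(cfs))^2), sum(cfs^2)
    )
    names(vals) <- paste(b, .FREQ_STATS, sep = "__")
    out <- c(out, vals)
  }
  out
}

#' Extract the 2472-dimensional time-frequency feature vector
#'
#' Concatenates the 10 time-domain summaries of all 132 pool series
#' (1320 values) with the 4 frequency statistics of the 6 wavelet bands of
#' the 48 coordinate series (1152 values), in the fixed order of
#' [gaitFeatureNames()]. The ordering and length are identical for 75-frame
#' sequences and 37-frame odd/even halves, so full- and half-sequence
#' feature vectors are directly comparable.
#'
#' @param seq A [TranslatedSequence-class] (75 or 37 frames in the standard
#'   workflow), or a prebuilt [FeaturePool-class].
#' @param signedDistances Passed to [buildFeaturePool()].
#' @return Named numeric vector of length 2472.
#' @export
extractFeatureVector <- function(seq, signedDistances = FALSE) {
  pool <- if (is(seq, "FeaturePool")) {
    seq
  } else {
    buildFeaturePool(seq, signedDistances = signedDistances)
  }
  td <- unlist(lapply(pool@series, timeDomainSummary))
  names(td) <- as.vector(t(outer(
    names(pool@series), .TIME_FUNCTIONS, paste,
    sep = "__"
  )))
  fd <- unlist(lapply(names(pool@waveletBands), function(nm) {
    vals <- frequencyDomainSummary(pool@waveletBands[[nm]])
    names(vals) <- paste(nm, names(vals), sep = "__")
    vals
  }))
  out <- c(td, fd)
  expected <- gaitFeatureNames()
  stopifnot(
    length(out) == 2472L,
    identical(names(out), expected),
    all(is.finite(out))
  )
  out
}

#' Feature matrices for a cohort of gait sequences
#'
#' Runs the full preprocessing and feature-extraction chain for every
#' subject: interpolate low-confidence detections, unify to `frames` frames,
#' translate to the MidHip origin, smooth, and extract the 2472 features
#' from the full sequence and (optionally) from the odd- and even-frame
#' halves.
#'
#' @param sequences List of [GaitSequence-class] objects.
#' @param frames Unified frame count (default 75).
#' @param confThreshold Confidence threshold for [interpolateMissing()].
#' @param smooth Apply [smoothSequence()] (default `TRUE`).
#' @param halves Also extract odd/even half-sequence features (default `TRUE`).
#' @return List of numeric matrices `all` (and `odd`, `even`), one row per
#'   subject (rownames = subject ids), 2472 columns.
#' @export
extractCohortFeatures <- function(sequences, frames = 75L, confThreshold = 0.1,
                                  smooth = TRUE, halves = TRUE) {
  n <- length(sequences)
  featNames <- gaitFeatureNames()
  streams <- if (halves) c("all", "odd", "even") else "all"
  mats <- lapply(streams, function(s) {
    matrix(NA_real_, n, length(featNames),
      dimnames = list(
        vapply(sequences, subjectId, ""), featNames
      )
    )
  })
  names(mats) <- streams
  for (i in seq_len(n)) {
    gs <- interpolateMissing(sequences[[i]], confThreshold = confThreshold)
    gs <- unifyFrames(gs, n = frames)
    ts <- translateToMidHip(gs)
    if (smooth) ts <- smoothSequence(ts)
    mats$all[i, ] <- extractFeatureVector(ts)
    if (halves) {
      hv <- splitOddEven(ts)
      mats$odd[i, ] <- extractFeatureVector(hv$odd)
      mats$even[i, ] <- extractFeatureVector(hv$even)
    }
  }
  mats
}
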