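## 5-level Haar discrete wavelet transform with half-sample symmetric
## extension. Conventions match the standard DWT: at each level an
## odd-length signal is extended by repeating its last sample, then
## cA_k = (x_{2k-1} + x_{2k}) / sqrt(2), cD_k = (x_{2k-1} - x_{2k}) / sqrt(2).

.haarStep <- function(x) {
  n <- length(x)
  if (n %% 2L == 1L) x <- c(x, x[n])
  o <- x[seq(1L, length(x), by = 2L)]
  e <- x[seq(2L, length(x), by = 2L)]
  list(cA = (o + e) / sqrt(2), cD = (o - e) / sqrt(2), n = n)
}

.haarInvStep <- function(cA, cD, n) {
  y <- numeric(2L * length(cA))
  y[seq(1L, length(y), by = 2L)] <- (cA + cD) / sqrt(2)
  y[seq(2L, length(y), by = 2L)] <- (cA - cD) / sqrt(2)
  y[seq_len(n)]
}

#' 5-level Haar wavelet decomposition of a coordinate series
#'
#' Decomposes a gait coordinate series into five detail coefficient arrays
#' D1..D5 (high-frequency content at successively coarser scales) and the
#' level-5 approximation array A5 (the low-frequency trend), using the Haar
#' basis with symmetric signal extension. The decomposition is invertible:
#' the band signals reconstructed from the six arrays sum exactly to the
#' input (`X = D1 + D2 + D3 + D4 + D5 + A5`), see [waveletReconstruct()].
#'
#' @param series Numeric vector of length >= 32 (a 5-level decomposition
#'   needs at least 2^5 samples; both 75- and 37-frame series qualify).
#' @param levels Decomposition depth (default 5).
#' @return Named list of coefficient arrays `D1`..`D5`, `A5`, with the
#'   per-level signal lengths stored in attribute `origLengths` for
#'   reconstruction.
#' @examples
#' bands <- waveletDecompose(sin(2 * pi * (1:75) / 25))
#' names(bands)
#' max(abs(waveletReconstruct(bands) - sin(2 * pi * (1:75) / 25))) < 1e-10
#' @export
waveletDecompose <- function(series, levels = 5L) {
  n <- length(series)
  if (n < 2^levels) {
    stop(
      "decomposition depth error: a ", levels, "-level decomposition needs ",
      2^levels, " samples, got ", n
    )
  }
  details <- vector("list", levels)
  lengths <- integer(levels)
  x <- as.numeric(series)
  for (lvl in seq_len(levels)) {
    st <- .haarStep(x)
    details[[lvl]] <- st$cD
    lengths[lvl] <- st$n
    x <- st$cA
  }
  out <- c(stats::setNames(details, paste0("D", seq_len(levels))), list(A5 = x))
  names(out)[levels + 1L] <- paste0("A", levels)
  attr(out, "origLengths") <- lengths
  out
}

#' Reconstruct a signal (or one band of it) from Haar coefficients
#'
#' `waveletReconstruct()` inverts [waveletDecompose()]. With `band = NULL`
#' all six coefficient arrays are used and the original series is recovered
#' exactly; with a band name only that band's coefficients are kept (the
#' others zeroed), yielding the reconstructed band signal. By linearity the
#' six band signals sum to the input series.
#'
#' @param bands Output of [waveletDecompose()].
#' @param band Optional band name (`"D1"`..`"D5"`, `"A5"`).
#' @return Numeric vector of the original series length.
#' @export
waveletReconstruct <- function(bands, band = NULL) {
  lengths <- attr(bands, "origLengths")
  if (is.null(lengths)) {
    stop("bands must come from waveletDecompose()")
  }
  levels <- length(lengths)
  approxName <- paste0("A", levels)
  keep <- band %||% c(names(bands))
  if (!all(keep %in% names(bands))) {
    stop("unknown band: ", paste(setdiff(keep, names(bands)), collapse = ", "))
  }
  cA <- if (approxName %in% keep) bands[[approxName]] else 0 * bands[[approxName]]
  for (lvl in rev(seq_len(levels))) {
    dName <- paste0("D", lvl)
    cD <- if (dName %in% keep) bands[[dName]] else 0 * bands[[dName]]
    cA <- .haarInvStep(cA, cD, lengths[lvl])
  }
  cA
}

#' Reconstructed band signals of a Haar decomposition
#'
#' @param bands Output of [waveletDecompose()].
#' @return Named list of six numeric vectors (band signals `D1`..`D5`, `A5`),
#'   each of the original series length; their sum equals the input series.
#' @export
waveletBandSignals <- function(bands) {
  stats::setNames(
    lapply(names(bands), function(b) waveletReconstruct(bands, band = b)),
    names(bands)
  )
}
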