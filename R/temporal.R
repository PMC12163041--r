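#' Conventional time-series feature panel (24 per series)
#'
#' A fixed, documented panel of 22 conventional time-series statistics —
#' autocorrelation and predictability, frequency content, distributional
#' shape, complexity and stationarity measures — plus the series mean and
#' standard deviation appended as positions 23 and 24. This is the
#' interpretable temporal baseline against which the topological features
#' are compared. The standard deviation uses the population (divide by n)
#' convention. Deterministic: identical input gives an identical vector.
#'
#' Feature order (names are attached to the result):
#' \enumerate{
#'   \item acf_lag1, acf_lag2, acf_lag5: autocorrelation at lags 1/2/5
#'   \item acf_first_zero, acf_first_1e: first lags where the ACF crosses 0
#'     and 1/e, as fractions of the max lag considered (T/2)
#'   \item spec_peak_freq: periodogram argmax as a fraction of Nyquist
#'   \item spec_centroid: power-weighted mean frequency fraction
#'   \item spec_entropy: normalised spectral entropy in [0, 1]
#'   \item spec_low_power: fraction of power in the lowest frequency quarter
#'   \item skewness, ex_kurtosis: standardised 3rd / excess 4th moment
#'   \item z_median: median of the z-scored series
#'   \item iqr_over_sd: interquartile range over sd
#'   \item prop_above_mean, longest_above_mean, mean_cross_rate: level stats
#'   \item trev_asym: time-reversal asymmetry of first differences
#'   \item hjorth_mobility, hjorth_complexity
#'   \item sampen: sample entropy (m = 2, r = 0.2 sd)
#'   \item seg_var_ratio: variance of 5 segment means over total variance
#'   \item periodicity: max ACF beyond its first zero crossing
#' }
#'
#' A constant series is flagged (\code{attr(, "degenerate")}); its
#' scale-free entries are 0 by convention, its mean is the constant and its
#' sd is 0.
#'
#' @param series numeric vector, length >= 30.
#' @return named numeric vector of length 24.
#' @export
temporalFeatures <- function(series) {
  T <- length(series)
  if (T < 30L) stop("temporalFeatures needs length >= 30")
  mu <- mean(series)
  sdP <- sqrt(mean((series - mu)^2))
  nm <- c("acf_lag1", "acf_lag2", "acf_lag5", "acf_first_zero",
          "acf_first_1e", "spec_peak_freq", "spec_centroid", "spec_entropy",
          "spec_low_power", "skewness", "ex_kurtosis", "z_median",
          "iqr_over_sd", "prop_above_mean", "longest_above_mean",
          "mean_cross_rate", "trev_asym", "hjorth_mobility",
          "hjorth_complexity", "sampen", "seg_var_ratio", "periodicity",
          "mean", "std")
  if (sdP == 0) {
    out <- c(rep(0, 22), mu, 0)
    names(out) <- nm
    return(structure(out, degenerate = TRUE))
  }
  z <- (series - mu) / sdP
  maxLag <- floor(T / 2)
  ac <- as.numeric(stats::acf(series, lag.max = maxLag, plot = FALSE,
                              demean = TRUE)$acf)[-1L]
  firstBelow <- function(v, thr) {
    i <- which(v < thr)
    if (length(i)) i[1L] else length(v)
  }
  zc <- firstBelow(ac, 0)
  ## periodogram over positive frequencies
  P <- Mod(fft(z))^2
  half <- P[2:(floor(T / 2) + 1L)]
  fFrac <- seq_along(half) / length(half)
  pw <- half / sum(half)
  specEnt <- -sum(pw[pw > 0] * log(pw[pw > 0])) / log(length(pw))
  above <- series > mu
  runs <- rle(above)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  dx <- diff(series)
  sdDx <- sqrt(mean((dx - mean(dx))^2))
  ddx <- diff(dx)
  sdDdx <- sqrt(mean((ddx - mean(ddx))^2))
  mob <- sdDx / sdP
  out <- c(
    ac[1L], ac[2L], ac[5L],
    zc / maxLag,
    firstBelow(ac, exp(-1)) / maxLag,
    fFrac[which.max(pw)],
    sum(fFrac * pw),
    specEnt,
    sum(pw[fFrac <= 0.25]),
    mean(z^3),
    mean(z^4) - 3,
    median(z),
    (quantile(series, 0.75, names = FALSE) -
       quantile(series, 0.25, names = FALSE)) / sdP,
    mean(above),
    longest / T,
    mean(above[-1L] != above[-T]),
    mean(dx^3) / max(mean(dx^2)^1.5, .Machine$double.eps),
    mob,
    if (sdDx > 0) (sdDdx / sdDx) / mob else 0,
    sampleEntropy(z),
    segVarRatio(series, 5L),
    if (zc < maxLag) max(ac[(zc + 1L):maxLag]) else 0,
    mu, sdP)
  names(out) <- nm
  structure(out, degenerate = FALSE)
}

# sample entropy, m = 2, tolerance r = 0.2 (series already z-scored)
sampleEntropy <- function(z, m = 2L, r = 0.2) {
  ab <- .sampenCountsCpp(as.numeric(z), as.integer(m), r)
  if (ab[1L] == 0 || ab[2L] == 0) return(0)
  -log(ab[1L] / ab[2L])
}

# variance of segment means over total variance (nonstationarity)
segVarRatio <- function(x, nSeg) {
  segs <- split(x, cut(seq_along(x), nSeg, labels = FALSE))
  var(vapply(segs, mean, numeric(1))) / max(var(x), .Machine$double.eps)
}

#' Temporal feature matrix for a cohort
#'
#' Applies [temporalFeatures()] to every ROI of every subject-session and
#' assembles a [TopoFeatures-class] of kind "temporal" with nRois x 24
#' features per subject-session (ROI-major layout). Any non-finite feature
#' value is imputed with that feature's median across the cohort.
#'
#' @param seriesList named list of ROI x time matrices keyed
#'   "sub-XXX_ses-S" (e.g. the \code{series} slot of a
#'   [SyntheticCohort-class]).
#' @return a [TopoFeatures-class].
#' @export
temporalFeatureSet <- function(seriesList) {
  keys <- names(seriesList)
  nRois <- nrow(seriesList[[1L]])
  mat <- matrix(NA_real_, nRois * 24L, length(keys))
  for (ci in seq_along(keys)) {
    x <- seriesList[[ci]]
    mat[, ci] <- as.numeric(vapply(seq_len(nRois), function(r)
      as.numeric(temporalFeatures(x[r, ])), numeric(24L)))
  }
  bad <- !is.finite(mat)
  if (any(bad)) {
    for (ri in unique(which(bad, arr.ind = TRUE)[, 1L])) {
      v <- mat[ri, ]
      v[!is.finite(v)] <- median(v[is.finite(v)])
      mat[ri, ] <- v
    }
  }
  colnames(mat) <- keys
  featNames <- names(temporalFeatures(rnorm(30)))
  meta <- strcapture("sub-([0-9]+)_ses-([0-9]+)", keys,
                     data.frame(subject = integer(), session = integer()))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    rowData = S4Vectors::DataFrame(
      roi = rep(seq_len(nRois), each = 24L),
      feature = rep(featNames, nRois)),
    colData = S4Vectors::DataFrame(subject = meta$subject,
                                   session = meta$session,
                                   row.names = keys),
    metadata = list(kind = "temporal", nRois = nRois))
  new("TopoFeatures", se)
}
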