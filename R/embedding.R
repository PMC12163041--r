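#' Zero-phase bandpass filter
#'
#' 4th-order Butterworth bandpass applied forward-backward
#' (\code{signal::filtfilt}), i.e. zero phase distortion and doubled
#' attenuation. The default band 0.01-0.08 Hz is the conventional
#' resting-state fMRI band.
#'
#' @param series numeric vector.
#' @param fs sampling frequency, Hz (1/TR for fMRI).
#' @param low,high band edges, Hz; must satisfy 0 < low < high < fs/2.
#' @param order filter order (per pass).
#' @return filtered numeric vector, same length.
#' @export
bandpassFilter <- function(series, fs, low = 0.01, high = 0.08, order = 4L) {
  if (low <= 0 || high <= low || high >= fs / 2)
    stop("band must satisfy 0 < low < high < fs/2 (Nyquist ", fs / 2, " Hz)")
  if (length(series) <= 3L * (2L * order + 1L))
    stop("series too short for the filter: need length > ",
         3L * (2L * order + 1L))
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  ## odd-reflection padding over the full series length bounds the
  ## forward-backward filter's edge transients
  n <- length(series)
  pad <- n - 1L
  ext <- c(2 * series[1L] - series[(pad + 1L):2L],
           series,
           2 * series[n] - series[(n - 1L):(n - pad)])
  out <- as.numeric(signal::filtfilt(bf, ext))
  out[(pad + 1L):(pad + n)]
}

#' Delay selection by mutual information
#'
#' Histogram-estimated mutual information (equal-width 2-D histogram,
#' \code{nBins} bins per axis over each margin's range, nats) between
#' x(t) and x(t + lag), for lag = 1..maxLag. Returns the first local
#' minimum of the MI profile — the first lag l with MI(l) < MI(l-1) and
#' MI(l) <= MI(l+1) — or, when no local minimum exists, the global
#' minimum with \code{attr(, "warning") = TRUE}. The rule is applied to a
#' lightly smoothed profile (centred moving average, window
#' \code{smoothWindow}): the raw histogram estimate wobbles by a few
#' hundredths of a nat from bin-edge effects, and the strict rule would
#' otherwise latch onto that wobble rather than the profile's shape.
#' Binning on per-series ranges makes the estimate invariant to affine
#' rescaling.
#'
#' @param series numeric vector.
#' @param maxLag largest lag considered; must be < length(series)/2.
#' @param nBins histogram bins per axis.
#' @param smoothWindow moving-average window for the profile (odd; 1
#'   disables smoothing).
#' @return integer lag; attributes \code{mi} (the raw profile),
#'   \code{miSmooth} and \code{warning} (TRUE when no interior local
#'   minimum existed).
#' @export
selectDelayMI <- function(series, maxLag = 40L, nBins = 16L,
                          smoothWindow = 5L) {
  if (maxLag >= length(series) / 2) stop("maxLag must be < length/2")
  if (sd(series) == 0) stop("degenerate input: constant series")
  mi <- vapply(seq_len(maxLag), function(l) {
    histogramMI(series[seq_len(length(series) - l)],
                series[(l + 1):length(series)], nBins)
  }, numeric(1))
  ms <- if (smoothWindow > 1L) movingAverage(mi, smoothWindow) else mi
  lag <- NA_integer_
  ## a flat profile (range below ~the histogram estimator's noise floor)
  ## has no structured minimum: fall through to the warning branch
  if (max(ms) - min(ms) >= 0.05) {
    for (l in 2:(maxLag - 1L)) {
      if (ms[l] < ms[l - 1L] && ms[l] <= ms[l + 1L]) { lag <- l; break }
    }
  }
  warn <- is.na(lag)
  if (warn) lag <- which.min(ms)
  structure(as.integer(lag), mi = mi, miSmooth = ms, warning = warn)
}

# centred moving average, window shrinking at the edges
movingAverage <- function(v, w) {
  h <- w %/% 2L
  vapply(seq_along(v), function(i)
    mean(v[max(1L, i - h):min(length(v), i + h)]), numeric(1))
}

# equal-width 2-D histogram MI in nats
histogramMI <- function(x, y, nBins) {
  bx <- pmin(nBins, 1L + floor((x - min(x)) / diff(range(x)) * nBins))
  by <- pmin(nBins, 1L + floor((y - min(y)) / diff(range(y)) * nBins))
  joint <- tabulate(bx + nBins * (by - 1L), nbins = nBins * nBins)
  joint <- joint / sum(joint)
  px <- tabulate(bx, nbins = nBins) / length(x)
  py <- tabulate(by, nbins = nBins) / length(y)
  prod <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / prod[nz]))
}

#' Embedding dimension by false nearest neighbours
#'
#' Kennel's criterion: embed at dimension m and m+1; a point's nearest
#' neighbour at dimension m is "false" if the extra coordinate stretches
#' the neighbour distance by more than \code{rTol} relative to the original
#' distance, or beyond \code{aTol} times the series' spread. Returns the
#' smallest m <= maxDim with FNN fraction below \code{fnnThreshold}, else
#' maxDim with \code{attr(, "warning") = TRUE}.
#'
#' @param series numeric vector.
#' @param delay embedding delay (samples).
#' @param maxDim largest dimension tried.
#' @param rTol,aTol Kennel tolerances (defaults 15 and 2).
#' @param fnnThreshold acceptable FNN fraction (default 0.02).
#' @return integer dimension; attributes \code{fnn} (fractions per m) and
#'   \code{warning}.
#' @export
selectDimensionFNN <- function(series, delay, maxDim = 8L, rTol = 15,
                               aTol = 2, fnnThreshold = 0.02) {
  if (sd(series) == 0) stop("degenerate input: constant series")
  sdA <- sqrt(mean((series - mean(series))^2))
  fnn <- rep(NA_real_, maxDim)
  for (m in seq_len(maxDim)) {
    nPts <- length(series) - m * delay  # need the (m+1)-th coordinate too
    if (nPts < 10L) break
    emb <- delayEmbedMatrix(series, delay, m)[seq_len(nPts), , drop = FALSE]
    nxt <- series[(m * delay + 1L):(m * delay + nPts)]
    d <- as.matrix(stats::dist(emb))
    diag(d) <- Inf
    nn <- max.col(-d, ties.method = "first")
    dnn <- d[cbind(seq_len(nPts), nn)]
    stretch <- abs(nxt - nxt[nn])
    false1 <- stretch / pmax(dnn, .Machine$double.eps) > rTol
    false2 <- sqrt(dnn^2 + stretch^2) / sdA > aTol
    ## exact revisits of the trajectory (distance at rounding level) carry
    ## no geometric information; their distance ratio is numerical noise
    dup <- dnn < 1e-8 * sdA & stretch < 1e-8 * sdA
    fnn[m] <- mean((false1 | false2) & !dup)
    if (fnn[m] < fnnThreshold)
      return(structure(as.integer(m), fnn = fnn, warning = FALSE))
  }
  structure(as.integer(maxDim), fnn = fnn, warning = TRUE)
}

# plain embedding matrix without the class wrapper (internal)
delayEmbedMatrix <- function(series, delay, m) {
  n <- length(series) - (m - 1L) * delay
  idx <- outer(seq_len(n) - 1L, (seq_len(m) - 1L) * delay, `+`) + 1L
  matrix(series[idx], n, m)
}

#' Takens delay embedding
#'
#' Maps a length-T series to the point cloud whose row i (0-based) is
#' (x_i, x_\{i+tau\}, ..., x_\{i+(m-1)tau\}); the cloud has
#' n = T - (m-1) tau points in m dimensions.
#'
#' @param series numeric vector of length T.
#' @param delay tau >= 1, in samples.
#' @param m embedding dimension >= 1.
#' @return numeric n x m matrix with attribute \code{params = c(delay, m)}.
#' @examples
#' delayEmbed(1:5, delay = 2, m = 2)  # rows (1,3), (2,4), (3,5)
#' @export
delayEmbed <- function(series, delay, m) {
  delay <- as.integer(delay); m <- as.integer(m)
  if (delay < 1L || m < 1L) stop("delay and m must be >= 1")
  n <- length(series) - (m - 1L) * delay
  if (n < m)
    stop("series too short: length ", length(series), " gives ", n,
         " points; need at least T = ", (m - 1L) * delay + m,
         " for delay ", delay, " and dimension ", m)
  structure(delayEmbedMatrix(series, delay, m),
            params = c(delay = delay, m = m))
}

#' Global embedding parameters for a collection of series
#'
#' Computes per-series delay (mutual information) and dimension (false
#' nearest neighbours, at that series' delay) on a subsample of the
#' collection, then aggregates each by the median rounded up, returning one
#' global (delay, m) pair used for every series — a single shared embedding
#' geometry is what makes feature vectors comparable across subjects.
#'
#' @param seriesList list of numeric vectors.
#' @param maxLag,nBins passed to [selectDelayMI()].
#' @param maxDim,rTol,aTol,fnnThreshold passed to [selectDimensionFNN()].
#' @param nSample number of series examined (evenly spaced subsample).
#' @return list with \code{delay}, \code{m}, and the per-series values.
#' @export
selectGlobalParams <- function(seriesList, maxLag = 40L, nBins = 16L,
                               maxDim = 8L, rTol = 15, aTol = 2,
                               fnnThreshold = 0.02, nSample = 20L) {
  if (!length(seriesList)) stop("need at least one series")
  take <- unique(round(seq(1, length(seriesList),
                           length.out = min(nSample, length(seriesList)))))
  delays <- integer(length(take)); dims <- integer(length(take))
  for (ii in seq_along(take)) {
    s <- seriesList[[take[ii]]]
    delays[ii] <- as.integer(selectDelayMI(s, maxLag = maxLag,
                                           nBins = nBins))
    dims[ii] <- as.integer(selectDimensionFNN(s, delay = delays[ii],
                                              maxDim = maxDim, rTol = rTol,
                                              aTol = aTol,
                                              fnnThreshold = fnnThreshold))
  }
  list(delay = as.integer(ceiling(median(delays))),
       m = as.integer(ceiling(median(dims))),
       perSeriesDelay = delays, perSeriesDim = dims)
}
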