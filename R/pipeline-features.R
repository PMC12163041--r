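#' Topological feature extraction for a cohort
#'
#' Runs the full topological branch on every ROI series of every
#' subject-session: optional bandpass, one global (delay, m) embedding
#' parameter pair (median-aggregated across a subsample of series, unless
#' supplied), Takens embedding, maxmin landmark subsampling, Vietoris-Rips
#' H0/H1 persistence, a shared per-dimension landscape grid over all
#' diagrams, and landscape flattening into [TopoFeatures-class] matrices.
#'
#' @param seriesList named list of ROI x time matrices keyed
#'   "sub-XXX_ses-S" (e.g. the \code{series} slot of a
#'   [SyntheticCohort-class]).
#' @param delay,m embedding parameters; NULL selects them automatically
#'   via [selectGlobalParams()].
#' @param landmarks maximum points per embedded cloud before persistence
#'   (maxmin subsampling, deterministic given \code{seed}); 0 disables.
#'   Persistence of each (possibly subsampled) cloud is computed with the
#'   filtration capped at the cloud's enclosing radius
#'   \eqn{\min_i \max_j d_{ij}}, beyond which the complex is a cone and
#'   carries no further H1 structure; the cap only affects the value at
#'   which the essential H0 bar is truncated.
#' @param k,nBins landscape layers and grid bins (k * nBins features per
#'   landscape, default 5 x 20 = 100).
#' @param band optional c(low, high) bandpass in Hz; NULL skips filtering.
#' @param tr sampling interval in seconds (needed when \code{band} is
#'   given).
#' @param seed seed for the landmark starting points.
#' @return list with elements \code{h0}, \code{h1}, \code{both}
#'   ([TopoFeatures-class]), \code{params} (the global delay/m), and
#'   \code{grids}.
#' @export
extractTopoFeatures <- function(seriesList, delay = NULL, m = NULL,
                                landmarks = 50L, k = 5L, nBins = 20L,
                                band = NULL, tr = 0.72, seed = 1L) {
  keys <- names(seriesList)
  if (is.null(keys)) stop("seriesList must be named by subject-session")
  nRois <- nrow(seriesList[[1L]])

  if (!is.null(band)) {
    seriesList <- lapply(seriesList, function(x) {
      t(apply(x, 1L, bandpassFilter, fs = 1 / tr, low = band[1L],
              high = band[2L]))
    })
  }

  if (is.null(delay) || is.null(m)) {
    flat <- list()
    for (x in seriesList[seq_len(min(5L, length(seriesList)))])
      for (r in seq_len(nRois)) flat[[length(flat) + 1L]] <- x[r, ]
    gp <- selectGlobalParams(flat)
    delay <- delay %||% gp$delay
    m <- m %||% gp$m
  }

  diagrams <- vector("list", length(keys))
  names(diagrams) <- keys
  idx <- 0L
  for (ci in seq_along(keys)) {
    x <- seriesList[[ci]]
    perRoi <- vector("list", nRois)
    for (r in seq_len(nRois)) {
      idx <- idx + 1L
      cloud <- delayEmbed(x[r, ], delay, m)
      set.seed(seed + idx)
      start <- sample.int(nrow(cloud), 1L)
      res <- .ripsCloudCpp(cloud, as.integer(landmarks), start, 1L)
      src <- paste0(keys[ci], "_", r)
      mk <- function(p, dm) {
        colnames(p) <- c("birth", "death")
        new("PersistenceDiagram", dim = dm, pairs = p,
            maxEps = res$maxEps, source = src)
      }
      perRoi[[r]] <- list(h0 = mk(res$h0, 0L), h1 = mk(res$h1, 1L))
    }
    diagrams[[ci]] <- perRoi
  }

  gridH0 <- globalGrid(unlist(lapply(diagrams, lapply, `[[`, "h0"),
                              recursive = FALSE), nBins)
  gridH1 <- globalGrid(unlist(lapply(diagrams, lapply, `[[`, "h1"),
                              recursive = FALSE), nBins)

  landscapes <- lapply(diagrams, function(perRoi)
    lapply(perRoi, function(dg) list(
      h0 = landscapeFromDiagram(dg$h0, k = k, grid = gridH0),
      h1 = landscapeFromDiagram(dg$h1, k = k, grid = gridH1))))

  list(h0 = assembleFeatures(landscapes, dims = 0L),
       h1 = assembleFeatures(landscapes, dims = 1L),
       both = assembleFeatures(landscapes, dims = c(0L, 1L)),
       params = list(delay = delay, m = m),
       grids = list(h0 = gridH0, h1 = gridH1))
}
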