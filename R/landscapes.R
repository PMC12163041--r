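#' Tent function of a persistence pair
#'
#' The triangular tent of a pair (b, d) evaluated at t:
#' \eqn{\Lambda(t) = \max(0, \min(t - b, d - t))}. Vectorised over t.
#'
#' @param b,d birth and death (b <= d).
#' @param t evaluation points.
#' @return numeric vector of tent values.
#' @export
tentValue <- function(b, d, t) {
  if (b > d) stop("tent requires birth <= death")
  pmax(0, pmin(t - b, d - t))
}

#' Persistence landscape of a diagram
#'
#' Layer k at grid point t is the k-th largest tent value over the
#' diagram's pairs (0 when the diagram has fewer than k pairs). An empty
#' diagram yields an all-zero landscape.
#'
#' @param diagram a [PersistenceDiagram-class].
#' @param k number of layers.
#' @param grid increasing filtration values to sample at.
#' @return a [PersistenceLandscape-class] with a k x length(grid) value
#'   matrix.
#' @examples
#' d <- new("PersistenceDiagram", dim = 0L,
#'          pairs = cbind(birth = 0, death = 2), maxEps = 2)
#' landscapeValues(landscapeFromDiagram(d, k = 1, grid = seq(0, 2, 0.5)))
#' @export
landscapeFromDiagram <- function(diagram, k = 5L, grid) {
  stopifnot(k >= 1L, length(grid) >= 1L)
  p <- diagram@pairs
  vals <- if (nrow(p)) .landscapeCpp(p, as.numeric(grid), as.integer(k))
          else matrix(0, k, length(grid))
  new("PersistenceLandscape", dim = diagram@dim, grid = as.numeric(grid),
      values = vals)
}

#' Shared landscape grid over a diagram collection
#'
#' Uniform grid from 0 to the maximum finite death over all diagrams in the
#' collection. One grid per homology dimension, shared across every
#' ROI/subject/session, is what makes flattened landscape vectors
#' comparable across subjects; persist it with the feature set and reuse it
#' verbatim for held-out data.
#'
#' @param diagrams list of [PersistenceDiagram-class] (one homology dim).
#' @param nBins grid length.
#' @return numeric grid of length \code{nBins}.
#' @export
globalGrid <- function(diagrams, nBins = 20L) {
  deaths <- unlist(lapply(diagrams, function(d) d@pairs[, 2]))
  if (!length(deaths))
    stop("cannot build a grid from an all-empty diagram collection")
  seq(0, max(deaths), length.out = nBins)
}

featureRowData <- function(nRois, dims, k, nBins) {
  ## ROI-major, then dim (H0 before H1), then layer, then bin
  grid <- expand.grid(bin = seq_len(nBins), layer = seq_len(k),
                      dim = dims, roi = seq_len(nRois))
  S4Vectors::DataFrame(roi = grid$roi, dim = grid$dim, layer = grid$layer,
                       bin = grid$bin)
}

#' Assemble per-subject landscape feature vectors
#'
#' Flattens and concatenates persistence landscapes into one fixed-length
#' feature vector per subject-session, in a keyed layout: ROI ascending,
#' then H0 before H1, then layer, then bin. With 200 ROIs, 100-sample
#' landscapes (k layers x nBins with k*nBins = 100) and both homology
#' dimensions this gives 200 x 100 x 2 = 40000 features per subject.
#'
#' @param landscapes nested list: \code{landscapes[[sessionKey]][[roi]]} is
#'   a list with elements \code{h0} and/or \code{h1}, each a
#'   [PersistenceLandscape-class]. Session keys look like
#'   "sub-001_ses-1". Every (roi, dim) cell must be present for every
#'   subject-session.
#' @param dims which homology dimensions to include, subset of c(0, 1).
#' @return a [TopoFeatures-class] (features x subject-sessions) whose
#'   metadata records the kind, grids, k and nBins.
#' @export
assembleFeatures <- function(landscapes, dims = c(0L, 1L)) {
  keys <- names(landscapes)
  if (is.null(keys)) stop("landscapes must be a named list of sessions")
  nRois <- length(landscapes[[1L]])
  dimNames <- paste0("h", dims)
  first <- NULL
  for (dn in dimNames) first <- first %||% landscapes[[1L]][[1L]][[dn]]
  k <- nrow(first@values); nBins <- length(first@grid)
  nFeat <- nRois * length(dims) * k * nBins
  mat <- matrix(NA_real_, nFeat, length(keys))
  for (ci in seq_along(keys)) {
    sess <- landscapes[[keys[ci]]]
    if (length(sess) != nRois)
      stop("session ", keys[ci], " has ", length(sess), " ROIs, expected ",
           nRois)
    vec <- numeric(0)
    for (r in seq_len(nRois)) {
      for (dn in dimNames) {
        l <- sess[[r]][[dn]]
        if (is.null(l))
          stop("missing landscape cell: session ", keys[ci], ", roi ", r,
               ", dim ", dn)
        vec <- c(vec, as.numeric(t(l@values)))  # layer-major, bin fastest
      }
    }
    mat[, ci] <- vec
  }
  colnames(mat) <- keys
  kind <- if (length(dims) == 2L) "PL-both" else paste0("PL-H", dims)
  grids <- lapply(dimNames, function(dn) landscapes[[1L]][[1L]][[dn]]@grid)
  names(grids) <- dimNames
  meta <- strcapture("sub-([0-9]+)_ses-([0-9]+)", keys,
                     data.frame(subject = integer(), session = integer()))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    rowData = featureRowData(nRois, dims, k, nBins),
    colData = S4Vectors::DataFrame(subject = meta$subject,
                                   session = meta$session,
                                   row.names = keys),
    metadata = list(kind = kind, grids = grids, k = k, nBins = nBins,
                    nRois = nRois))
  new("TopoFeatures", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subject-by-feature matrix for one session
#'
#' Extracts the subjects x features matrix of one session from a
#' [TopoFeatures-class] object, rows ordered by subject id — the input
#' shape of [identifySubjects()], [ccaFirstMode()] and the prediction
#' harnesses.
#'
#' @param x a [TopoFeatures-class].
#' @param session session number, or NULL for all columns.
#' @return numeric matrix, subjects (or subject-sessions) in rows.
#' @export
sessionMatrix <- function(x, session = NULL) {
  cd <- SummarizedExperiment::colData(x)
  keep <- if (is.null(session)) seq_len(ncol(x)) else
    which(cd$session == session)
  keep <- keep[order(cd$subject[keep])]
  t(SummarizedExperiment::assay(x)[, keep, drop = FALSE])
}
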