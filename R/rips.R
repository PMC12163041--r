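#' Vietoris-Rips persistence diagrams
#'
#' Computes H0 and/or H1 persistence diagrams of a Euclidean point cloud
#' under the Vietoris-Rips filtration, in which a simplex enters at the
#' scale equal to its longest pairwise distance. H0 is computed by
#' union-find over distance-sorted point pairs: finite deaths are exactly
#' the minimum-spanning-tree edge weights, and the essential component is
#' capped at \code{maxEps}, so an n-point cloud always yields n bars. H1 is
#' computed by GF(2) reduction of the triangle boundary matrix in
#' filtration order (ties broken lexicographically); zero-persistence bars
#' are discarded and loops still open at \code{maxEps} are capped there.
#'
#' @param cloud numeric matrix, points in rows.
#' @param maxEps filtration cap; default the maximum pairwise distance, at
#'   which the complex is complete and H1 has no essential classes.
#' @param maxDim 0 or 1.
#' @param source optional identifier stored in the diagrams.
#' @return \code{ripsDiagrams}: named list with elements \code{h0} and (if
#'   maxDim >= 1) \code{h1}, each a [PersistenceDiagram-class].
#'   \code{ripsH0} / \code{ripsH1}: the single diagram.
#' @examples
#' sq <- fixtureSquare()
#' persistencePairs(ripsH1(sq))           # one bar (1, sqrt(2))
#' persistencePairs(ripsH0(sq, maxEps = 2))
#' @export
ripsDiagrams <- function(cloud, maxEps = NULL, maxDim = 1L,
                         source = character()) {
  cloud <- as.matrix(cloud)
  if (nrow(cloud) < 1L) stop("empty point cloud")
  if (anyNA(cloud)) stop("point cloud contains missing values")
  ripsFromDistance(as.matrix(stats::dist(cloud)), maxEps = maxEps,
                   maxDim = maxDim, source = source)
}

# core entry point on a precomputed distance matrix (shared by the
# cohort pipeline so each cloud's distances are computed once)
ripsFromDistance <- function(d, maxEps = NULL, maxDim = 1L,
                             source = character()) {
  if (is.null(maxEps)) maxEps <- max(d)
  if (maxEps <= 0) maxEps <- max(max(d), .Machine$double.eps)
  res <- .ripsPersistenceCpp(d, maxEps, as.integer(maxDim))
  mkDiag <- function(p, dim) {
    colnames(p) <- c("birth", "death")
    new("PersistenceDiagram", dim = as.integer(dim), pairs = p,
        maxEps = maxEps, source = source)
  }
  out <- list(h0 = mkDiag(res$h0, 0L))
  if (maxDim >= 1L) out$h1 <- mkDiag(res$h1, 1L)
  out
}

#' @rdname ripsDiagrams
#' @export
ripsH0 <- function(cloud, maxEps = NULL, source = character()) {
  ripsDiagrams(cloud, maxEps = maxEps, maxDim = 0L, source = source)$h0
}

#' @rdname ripsDiagrams
#' @export
ripsH1 <- function(cloud, maxEps = NULL, source = character()) {
  if (nrow(as.matrix(cloud)) < 3L)
    return(new("PersistenceDiagram", dim = 1L,
               pairs = matrix(numeric(), 0, 2,
                              dimnames = list(NULL, c("birth", "death"))),
               maxEps = if (is.null(maxEps)) 0 else maxEps,
               source = source))
  ripsDiagrams(cloud, maxEps = maxEps, maxDim = 1L, source = source)$h1
}

#' Maxmin landmark subsampling
#'
#' Farthest-point (maxmin) landmark selection: starting from a seeded
#' random point, repeatedly adds the point farthest from the current
#' landmark set. If the cloud already has at most \code{nMax} points it is
#' returned unchanged. Deterministic given \code{seed}.
#'
#' @param cloud numeric matrix, points in rows.
#' @param nMax number of landmarks to keep (>= 3).
#' @param seed RNG seed for the starting point.
#' @return the subsampled cloud; attribute \code{index} gives the selected
#'   row indices of the input.
#' @export
landmarkSubsample <- function(cloud, nMax = 300L, seed = 1L) {
  cloud <- as.matrix(cloud)
  if (nMax < 3L) stop("nMax must be >= 3")
  n <- nrow(cloud)
  if (n <= nMax) return(structure(cloud, index = seq_len(n)))
  set.seed(seed)
  start <- sample.int(n, 1L)
  idx <- .maxminLandmarksCpp(as.matrix(stats::dist(cloud)),
                             as.integer(nMax), as.integer(start))
  structure(cloud[idx, , drop = FALSE], index = as.integer(idx))
}
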