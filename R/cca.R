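#' Behavioural item filtering
#'
#' Drops behavioural items that exceed a missingness threshold, have
#' near-zero variance, or are dominated by a single value (a discrete
#' proxy for the outlier-concentration exclusions used in large behavioural
#' batteries). Thresholds are configuration, not fixed science.
#'
#' @param Y subjects x items matrix or data.frame with unique column names.
#' @param missingMax maximum allowed fraction of missing values.
#' @param varFloor minimum allowed variance (computed on complete values).
#' @param maxCategoryFreq drop items whose most frequent value exceeds this
#'   fraction of non-missing entries.
#' @return list with \code{Y} (reduced matrix) and \code{kept} (names).
#' @export
filterBehaviors <- function(Y, missingMax = 0.10, varFloor = 1e-12,
                            maxCategoryFreq = 0.95) {
  Y <- as.matrix(Y)
  if (anyDuplicated(colnames(Y))) stop("item names must be unique")
  keep <- logical(ncol(Y))
  for (j in seq_len(ncol(Y))) {
    v <- Y[, j]
    missFrac <- mean(is.na(v))
    v <- v[!is.na(v)]
    keep[j] <- missFrac <= missingMax &&
      length(v) > 1L && var(v) > varFloor &&
      max(table(v)) / length(v) <= maxCategoryFreq
  }
  if (!any(keep)) stop("behavioural filtering dropped every item")
  list(Y = Y[, keep, drop = FALSE], kept = colnames(Y)[keep])
}

#' Residualise a matrix on confounds
#'
#' Returns X - C (C'C)^-1 C' X with an intercept always appended to C, so
#' the residuals are column-centred and orthogonal to every confound.
#'
#' @param X subjects x variables matrix.
#' @param C subjects x confounds matrix, or NULL for intercept only
#'   (column centring).
#' @return residual matrix, same shape as X.
#' @export
deconfound <- function(X, C = NULL) {
  X <- as.matrix(X)
  Cc <- cbind(intercept = rep(1, nrow(X)), C)
  if (nrow(Cc) != nrow(X)) stop("X and C must have aligned rows")
  q <- qr(Cc)
  if (q$rank < ncol(Cc)) {
    drop <- colnames(Cc)[q$pivot[(q$rank + 1L):ncol(Cc)]]
    stop("confound matrix is rank deficient; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  X - Cc %*% qr.coef(q, X)
}

# z-score columns; zero-variance columns become 0
zscore <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2L, sd)
  s[s == 0] <- 1
  sweep(sweep(X, 2L, mu), 2L, s, `/`)
}

# PCA scores (top nPc) of a z-scored matrix; rotation returned for mapping
pcaScores <- function(X, nPc) {
  Xs <- zscore(as.matrix(X))
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE, rank. = nPc)
  list(scores = pc$x[, seq_len(min(nPc, ncol(pc$x))), drop = FALSE],
       rotation = pc$rotation)
}

# first canonical correlation of two column-centred matrices via
# orthonormal bases; also returns the weight vectors in the input bases
firstCanonical <- function(Xc, Yc) {
  qx <- qr(Xc); qy <- qr(Yc)
  Qx <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  Qy <- qr.Q(qy)[, seq_len(qy$rank), drop = FALSE]
  sv <- svd(crossprod(Qx, Qy), nu = 1L, nv = 1L)
  ax <- backsolve(qr.R(qx)[seq_len(qx$rank), seq_len(qx$rank),
                           drop = FALSE], sv$u)
  ay <- backsolve(qr.R(qy)[seq_len(qy$rank), seq_len(qy$rank),
                           drop = FALSE], sv$v)
  list(r1 = min(1, sv$d[1L]), ax = drop(ax), ay = drop(ay), Qx = Qx,
       Qy = Qy)
}

#' First-mode CCA with permutation test
#'
#' z-scores both matrices, reduces each to \code{nPc} principal
#' components, and computes the first canonical correlation r1 between the
#' two PC matrices. Significance comes from a permutation test: the rows
#' of the behaviour PC matrix are shuffled \code{nPerm} times (seeded) and
#' r1 recomputed each time; p = (1 + #\{r_perm >= r1\}) / (1 + nPerm), so
#' the smallest attainable p is 1/(nPerm + 1) — with 10,000 permutations,
#' about 0.0001. Canonical weights are mapped back to feature/behaviour
#' space through the PCA rotations, and behaviour loadings (structure
#' correlations of each item with the behavioural variate) are reported
#' for interpretation.
#'
#' @param Xf subjects x features matrix.
#' @param Yb subjects x behaviours matrix.
#' @param nPc principal components kept on each side (< n subjects).
#' @param nPerm permutation count.
#' @param seed RNG seed for the permutations.
#' @return a [CcaModeResult-class].
#' @export
ccaFirstMode <- function(Xf, Yb, nPc = 100L, nPerm = 10000L, seed = 1L) {
  Xf <- as.matrix(Xf); Yb <- as.matrix(Yb)
  n <- nrow(Xf)
  if (nrow(Yb) != n) stop("Xf and Yb must have aligned rows")
  if (n <= nPc)
    stop("n_subjects (", n, ") must exceed nPc (", nPc,
         "); lower nPc")
  px <- pcaScores(Xf, nPc)
  py <- pcaScores(Yb, nPc)
  Xc <- scale(px$scores, scale = FALSE)
  Yc <- scale(py$scores, scale = FALSE)
  fc <- firstCanonical(Xc, Yc)

  ## permutation: row-permuting centred Y permutes its orthonormal basis
  ## identically, so each null r1 is the top singular value of Qx' P Qy
  set.seed(seed)
  permNull <- numeric(nPerm)
  if (nPerm > 0) {
    for (b in seq_len(nPerm)) {
      pr <- sample.int(n)
      permNull[b] <- svd(crossprod(fc$Qx, fc$Qy[pr, , drop = FALSE]),
                         nu = 0L, nv = 0L)$d[1L]
    }
  }
  pPerm <- (1 + sum(permNull >= fc$r1)) / (1 + nPerm)

  xv <- drop(Xc %*% fc$ax)
  yv <- drop(Yc %*% fc$ay)
  fw <- drop(px$rotation[, seq_along(fc$ax), drop = FALSE] %*% fc$ax)
  bw <- drop(py$rotation[, seq_along(fc$ay), drop = FALSE] %*% fc$ay)
  names(bw) <- colnames(Yb)
  loadings <- drop(suppressWarnings(cor(Yb, yv)))  # constant item -> NA
  loadings[!is.finite(loadings)] <- 0
  names(loadings) <- colnames(Yb)

  new("CcaModeResult", r1 = fc$r1, pPerm = pPerm, permNull = permNull,
      featureWeights = fw, behaviorWeights = bw,
      behaviorLoadings = loadings, xVariate = xv, yVariate = yv,
      nPc = as.integer(nPc), nPerm = as.integer(nPerm))
}

#' Per-ROI and per-network contributions to the CCA mode
#'
#' For each (ROI, homology dimension) block of the landscape feature
#' matrix, takes the first principal component of that block (z-scored;
#' sign-aligned to correlate positively with the block's row mean) as the
#' ROI's representative score, and reports its Pearson correlation with
#' the subjects' canonical feature variate as the ROI's contribution.
#' Contributions are aggregated per network (mean and sd of |r| over
#' member ROIs) and H0 vs H1 contributions are compared per network with a
#' two-sample t statistic on the absolute contributions.
#'
#' @param features a [TopoFeatures-class] of kind "PL-both" (single
#'   session), subjects ordered as in the CCA fit.
#' @param result the fitted [CcaModeResult-class].
#' @param networkLabels network name per ROI.
#' @return list with \code{roi} (data.frame: roi, dim, contribution),
#'   \code{network} (data.frame: network, dim, mean, sd), and
#'   \code{h0VsH1} (data.frame: network, t, p).
#' @export
roiContributions <- function(features, result, networkLabels) {
  rd <- SummarizedExperiment::rowData(features)
  mat <- sessionMatrix(features)  # subjects x features
  xv <- result@xVariate
  if (length(xv) != nrow(mat))
    stop("feature matrix and CCA variate have different subject counts")
  nRois <- max(rd$roi)
  if (length(networkLabels) != nRois)
    stop("need one network label per ROI")
  rows <- list()
  for (r in seq_len(nRois)) {
    for (dm in sort(unique(rd$dim))) {
      cols <- which(rd$roi == r & rd$dim == dm)
      block <- zscore(mat[, cols, drop = FALSE])
      pc1 <- prcomp(block, center = FALSE, rank. = 1L)$x[, 1L]
      if (cor(pc1, rowMeans(mat[, cols, drop = FALSE])) < 0) pc1 <- -pc1
      contrib <- suppressWarnings(cor(pc1, xv))
      if (!is.finite(contrib)) contrib <- 0
      rows[[length(rows) + 1L]] <-
        data.frame(roi = r, dim = dm, network = networkLabels[r],
                   contribution = contrib)
    }
  }
  roi <- do.call(rbind, rows)
  agg <- aggregate(abs(contribution) ~ network + dim, roi,
                   function(v) c(mean = mean(v), sd = sd(v)))
  network <- data.frame(network = agg$network, dim = agg$dim,
                        mean = agg$`abs(contribution)`[, "mean"],
                        sd = agg$`abs(contribution)`[, "sd"])
  tt <- lapply(unique(roi$network), function(net) {
    a0 <- abs(roi$contribution[roi$network == net & roi$dim == 0L])
    a1 <- abs(roi$contribution[roi$network == net & roi$dim == 1L])
    if (length(a0) < 2L || length(a1) < 2L)
      return(data.frame(network = net, t = NA_real_, p = NA_real_))
    ht <- t.test(a1, a0)
    data.frame(network = net, t = unname(ht$statistic), p = ht$p.value)
  })
  list(roi = roi, network = network, h0VsH1 = do.call(rbind, tt))
}

#' Top behaviour loadings of the CCA mode
#'
#' Behaviours ranked by the absolute value of their structure correlation
#' with the behavioural canonical variate; the signed top-k are returned.
#'
#' @param result a [CcaModeResult-class].
#' @param k how many to return; truncated with a warning if larger than
#'   the item count.
#' @return named numeric vector of signed loadings, decreasing |value|.
#' @export
topBehaviorLoadings <- function(result, k = 10L) {
  l <- result@behaviorLoadings
  if (k > length(l)) {
    warning("k exceeds item count; returning all ", length(l), " items")
    k <- length(l)
  }
  if (k == 0L) return(numeric(0))
  l[order(abs(l), decreasing = TRUE)][seq_len(k)]
}
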