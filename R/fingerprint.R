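#' Cross-session individual identification
#'
#' Fingerprinting by correlation matching: session-1 feature vectors form
#' the database, session-2 vectors the targets. For target i,
#' r_ij = Pearson correlation with database subject j, and the predicted
#' identity is the argmax over j; accuracy is the fraction of targets whose
#' argmax is themselves. Pearson similarity is invariant to affine
#' rescaling of whole feature vectors, so no prior normalisation is
#' applied. Ties are broken by the smallest database index and flagged; a
#' constant feature vector has undefined correlations, which are treated as
#' -Inf similarity and flagged.
#'
#' @param database numeric matrix, N subjects x features (session 1), row
#'   i = subject i.
#' @param targets numeric matrix, same shape and layout (session 2).
#' @return a [FingerprintResult-class].
#' @examples
#' f <- matrix(rnorm(40), 4, 10)
#' accuracy(identifySubjects(f, f))  # self-match is perfect
#' @export
identifySubjects <- function(database, targets) {
  database <- as.matrix(database); targets <- as.matrix(targets)
  if (nrow(database) < 2L) stop("need N >= 2 subjects")
  if (!identical(dim(database), dim(targets)))
    stop("database and targets must share shape and feature layout")
  r <- suppressWarnings(cor(t(targets), t(database)))
  r[!is.finite(r)] <- -Inf
  predicted <- integer(nrow(r))
  ties <- logical(nrow(r))
  for (i in seq_len(nrow(r))) {
    mx <- max(r[i, ])
    hits <- which(r[i, ] == mx)
    predicted[i] <- hits[1L]
    ties[i] <- length(hits) > 1L
  }
  correct <- predicted == seq_len(nrow(r))
  new("FingerprintResult", accuracy = mean(correct), similarity = r,
      predicted = predicted, correct = correct, ties = ties)
}

#' Per-network identification
#'
#' Runs [identifySubjects()] restricted to the feature columns of each
#' network's ROIs. The ROI of every feature column is taken from the
#' \code{roi} column of \code{rowData} when given [TopoFeatures-class]
#' inputs, or from \code{featureRoi} for plain matrices.
#'
#' @param database,targets [TopoFeatures-class] objects (single session
#'   each) or subjects x features matrices.
#' @param networkLabels character vector, network name per ROI.
#' @param featureRoi integer vector mapping each feature column to its ROI
#'   (only needed for matrix inputs).
#' @return named list of [FingerprintResult-class], one per network;
#'   networks with zero ROIs are skipped with a warning.
#' @export
identifyByNetwork <- function(database, targets, networkLabels,
                              featureRoi = NULL) {
  if (is(database, "TopoFeatures")) {
    featureRoi <- SummarizedExperiment::rowData(database)$roi
    database <- sessionMatrix(database)
    targets <- sessionMatrix(targets)
  }
  if (is.null(featureRoi)) stop("featureRoi required for matrix inputs")
  out <- list()
  for (net in unique(networkLabels)) {
    rois <- which(networkLabels == net)
    cols <- which(featureRoi %in% rois)
    if (!length(cols)) {
      warning("network ", net, " has no ROIs; skipped")
      next
    }
    out[[net]] <- identifySubjects(database[, cols, drop = FALSE],
                                   targets[, cols, drop = FALSE])
  }
  out
}
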