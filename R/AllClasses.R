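#' @import methods
#' @importFrom stats cor sd var prcomp quantile rnorm runif median t.test
#'   fft lm coef predict aggregate
#' @importFrom utils head read.delim write.table strcapture
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   colData
#' @importFrom S4Vectors metadata DataFrame
#' @useDynLib topobrain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Cohort generator specification
#'
#' Parameters of the synthetic multi-subject, two-session cohort generator.
#' All randomness in cohort generation derives from \code{seed}, so an
#' identical spec always produces a bit-identical cohort.
#'
#' @slot nSubjects number of subjects.
#' @slot nRois number of regions of interest (ROIs).
#' @slot nTimepoints samples per time series.
#' @slot tr sampling interval in seconds.
#' @slot nLatents dimension q of the subject latent vector that jointly
#'   drives dynamics, group label and behaviour.
#' @slot sessionNoiseSd standard deviation of additive i.i.d. Gaussian
#'   observation noise, in signal units (0 allowed: noiseless).
#' @slot phaseJitterSd standard deviation (radians) of the session-level
#'   perturbation of oscillator phases.
#' @slot behaviorDims number p of behavioural items.
#' @slot behaviorNoiseSd standard deviation of behavioural measurement
#'   noise; controls the planted latent-behaviour canonical correlation.
#' @slot effectScale dimensionless scale of the latent effect on the
#'   per-ROI oscillator parameters.
#' @slot seed integer RNG seed.
#' @slot networks character vector of network names assigned to ROIs
#'   round-robin.
#'
#' @seealso [cohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec", representation(
  nSubjects = "integer", nRois = "integer", nTimepoints = "integer",
  tr = "numeric", nLatents = "integer", sessionNoiseSd = "numeric",
  phaseJitterSd = "numeric", behaviorDims = "integer",
  behaviorNoiseSd = "numeric", effectScale = "numeric", seed = "integer",
  networks = "character"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  cnt <- c(nSubjects = object@nSubjects, nRois = object@nRois,
           nTimepoints = object@nTimepoints, nLatents = object@nLatents,
           behaviorDims = object@behaviorDims)
  bad <- names(cnt)[cnt < 1L]
  if (length(bad)) msg <- c(msg, paste0("counts must be >= 1: ",
                                        paste(bad, collapse = ", ")))
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (object@sessionNoiseSd < 0) msg <- c(msg, "sessionNoiseSd must be >= 0")
  if (object@phaseJitterSd < 0) msg <- c(msg, "phaseJitterSd must be >= 0")
  if (object@behaviorNoiseSd < 0) msg <- c(msg, "behaviorNoiseSd must be >= 0")
  if (!length(object@networks)) msg <- c(msg, "networks must be nonempty")
  if (length(msg)) msg else TRUE
})

#' Synthetic two-session cohort
#'
#' Container for a generated cohort: per subject-session ROI-by-time signal
#' matrices, the subject latents that drive them, behavioural scores sharing
#' those latents, a binary group label, and per-ROI network labels. Both
#' sessions of a subject share all subject-level oscillator parameters and
#' differ only in session noise and phase jitter.
#'
#' @slot series named list, one ROI x time matrix per "sub-XXX_ses-S" key.
#' @slot latents nSubjects x q matrix of subject latent vectors.
#' @slot behaviors nSubjects x p matrix of behavioural items.
#' @slot group integer vector in {0,1}, the planted binary label.
#' @slot networkLabels character vector, network name per ROI.
#' @slot spec the [CohortSpec-class] that produced the cohort.
#' @slot truth list of planted generator internals (oscillator parameter
#'   matrices, behaviour loading matrix, group direction) for validation.
#' @export
setClass("SyntheticCohort", representation(
  series = "list", latents = "matrix", behaviors = "matrix",
  group = "integer", networkLabels = "character", spec = "CohortSpec",
  truth = "list"))

setValidity("SyntheticCohort", function(object) {
  ns <- object@spec@nSubjects
  if (length(object@series) != 2L * ns)
    return("series must hold exactly two sessions per subject")
  if (!all(object@group %in% c(0L, 1L))) return("group must be binary")
  TRUE
})

#' Persistence diagram
#'
#' Multiset of (birth, death) pairs for one homology dimension of one point
#' cloud under the Vietoris-Rips filtration. Essential classes are capped at
#' \code{maxEps} so that downstream landscapes are finite.
#'
#' @slot dim homology dimension (0 or 1).
#' @slot pairs numeric matrix with columns \code{birth}, \code{death}.
#' @slot maxEps the filtration cap used.
#' @slot source optional identifier (subject, session, roi).
#' @export
setClass("PersistenceDiagram", representation(
  dim = "integer", pairs = "matrix", maxEps = "numeric",
  source = "character"))

setValidity("PersistenceDiagram", function(object) {
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must have two columns (birth, death)")
  if (nrow(p)) {
    if (any(p[, 1] < 0)) return("births must be >= 0")
    if (any(p[, 2] < p[, 1])) return("death must be >= birth")
    if (any(p[, 2] > object@maxEps + 1e-12)) return("death must be <= maxEps")
    if (object@dim == 0L && any(p[, 1] != 0)) return("H0 births must all be 0")
  }
  if (!object@dim %in% c(0L, 1L)) return("dim must be 0 or 1")
  TRUE
})

#' Persistence landscape
#'
#' k-layer functional summary of a persistence diagram sampled on a fixed
#' grid: layer j at grid point t is the j-th largest tent value
#' \eqn{\Lambda_i(t) = \max(0, \min(t - b_i, d_i - t))} over diagram points
#' i. Layers are pointwise non-increasing in j.
#'
#' @slot dim homology dimension summarised.
#' @slot grid strictly increasing filtration values (length nBins).
#' @slot values k x nBins nonnegative matrix of layer samples.
#' @export
setClass("PersistenceLandscape", representation(
  dim = "integer", grid = "numeric", values = "matrix"))

setValidity("PersistenceLandscape", function(object) {
  if (ncol(object@values) != length(object@grid))
    return("values must have one column per grid point")
  if (length(object@grid) > 1 && any(diff(object@grid) <= 0))
    return("grid must be strictly increasing")
  if (any(object@values < -1e-12)) return("landscape values must be >= 0")
  k <- nrow(object@values)
  if (k > 1 && any(object@values[-k, , drop = FALSE] <
                   object@values[-1, , drop = FALSE] - 1e-9))
    return("layers must be pointwise non-increasing")
  TRUE
})

#' Subject-session feature matrix
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one feature vector
#' per subject-session (columns = subject-sessions, rows = features).
#' \code{rowData} records the layout (roi, homology dim, layer, bin — or the
#' temporal feature name), \code{colData} the subject and session, and
#' \code{metadata} the feature kind ("PL-H0", "PL-H1", "PL-both" or
#' "temporal") plus the shared landscape grid(s).
#' @export
setClass("TopoFeatures", contains = "SummarizedExperiment")

#' Cross-session fingerprinting result
#'
#' @slot accuracy fraction of subjects correctly identified.
#' @slot similarity N x N Pearson matrix, entry (i, j) = correlation of
#'   target subject i (session 2) with database subject j (session 1).
#' @slot predicted integer vector, argmax database index per target.
#' @slot correct logical vector per target subject.
#' @slot ties logical vector flagging targets whose argmax was tied.
#' @export
setClass("FingerprintResult", representation(
  accuracy = "numeric", similarity = "matrix", predicted = "integer",
  correct = "logical", ties = "logical"))

setValidity("FingerprintResult", function(object) {
  if (!isTRUE(all.equal(object@accuracy, mean(object@correct))))
    return("accuracy must equal mean(correct)")
  TRUE
})

#' First-mode CCA result
#'
#' @slot r1 first canonical correlation between the feature and behaviour
#'   principal-component matrices.
#' @slot pPerm permutation p-value, (1 + #\{r_perm >= r1\}) / (1 + nPerm).
#' @slot permNull numeric vector of permuted first canonical correlations.
#' @slot featureWeights canonical weights mapped back to feature space.
#' @slot behaviorWeights canonical weights mapped back to behaviour items.
#' @slot behaviorLoadings structure correlations: correlation of each
#'   behaviour item with the behavioural canonical variate.
#' @slot xVariate,yVariate subject scores on the first canonical pair.
#' @slot nPc,nPerm analysis settings.
#' @export
setClass("CcaModeResult", representation(
  r1 = "numeric", pPerm = "numeric", permNull = "numeric",
  featureWeights = "numeric", behaviorWeights = "numeric",
  behaviorLoadings = "numeric", xVariate = "numeric", yVariate = "numeric",
  nPc = "integer", nPerm = "integer"))

setValidity("CcaModeResult", function(object) {
  if (object@r1 < -1e-9 || object@r1 > 1 + 1e-9)
    return("r1 must lie in [0, 1]")
  if (object@nPerm > 0 && object@pPerm < 1 / (object@nPerm + 1) - 1e-12)
    return("pPerm cannot undercut the permutation floor 1/(nPerm+1)")
  TRUE
})
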