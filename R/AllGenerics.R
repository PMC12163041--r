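#' Accessors for topobrain classes
#'
#' Small accessor generics: \code{persistencePairs} returns the (birth,
#' death) matrix of a diagram; \code{landscapeValues} and
#' \code{landscapeGrid} the sampled layers and their grid;
#' \code{featureKind} the kind of a feature set ("PL-H0", "PL-H1",
#' "PL-both", "temporal"); \code{accuracy} the identification accuracy of a
#' fingerprinting result.
#'
#' @param x an object of the documented class.
#' @return see the individual methods.
#' @name topobrain-accessors
NULL

#' @rdname topobrain-accessors
#' @export
setGeneric("persistencePairs", function(x) standardGeneric("persistencePairs"))

#' @rdname topobrain-accessors
#' @export
setGeneric("homologyDim", function(x) standardGeneric("homologyDim"))

#' @rdname topobrain-accessors
#' @export
setGeneric("landscapeValues", function(x) standardGeneric("landscapeValues"))

#' @rdname topobrain-accessors
#' @export
setGeneric("landscapeGrid", function(x) standardGeneric("landscapeGrid"))

#' @rdname topobrain-accessors
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

#' @rdname topobrain-accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname topobrain-accessors
#' @export
setMethod("persistencePairs", "PersistenceDiagram", function(x) x@pairs)

#' @rdname topobrain-accessors
#' @export
setMethod("homologyDim", "PersistenceDiagram", function(x) x@dim)

#' @rdname topobrain-accessors
#' @export
setMethod("homologyDim", "PersistenceLandscape", function(x) x@dim)

#' @rdname topobrain-accessors
#' @export
setMethod("landscapeValues", "PersistenceLandscape", function(x) x@values)

#' @rdname topobrain-accessors
#' @export
setMethod("landscapeGrid", "PersistenceLandscape", function(x) x@grid)

#' @rdname topobrain-accessors
#' @export
setMethod("featureKind", "TopoFeatures", function(x)
  S4Vectors::metadata(x)$kind)

#' @rdname topobrain-accessors
#' @export
setMethod("accuracy", "FingerprintResult", function(x) x@accuracy)

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nSubjects, "subjects x", object@nRois,
      "ROIs x", object@nTimepoints, "timepoints (TR", object@tr, "s)\n")
  cat("  latents q =", object@nLatents, "| behaviours p =",
      object@behaviorDims, "| noise sd =", object@sessionNoiseSd,
      "| seed =", object@seed, "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  s <- object@spec
  cat("SyntheticCohort:", s@nSubjects, "subjects, 2 sessions,",
      s@nRois, "ROIs,", s@nTimepoints, "timepoints\n")
  cat("  networks:", paste(unique(object@networkLabels), collapse = ", "),
      "\n")
})

setMethod("show", "PersistenceDiagram", function(object) {
  cat("PersistenceDiagram H", object@dim, ": ", nrow(object@pairs),
      " pairs, maxEps = ", format(object@maxEps, digits = 4), "\n", sep = "")
})

setMethod("show", "PersistenceLandscape", function(object) {
  cat("PersistenceLandscape H", object@dim, ": ", nrow(object@values),
      " layers x ", length(object@grid), " grid points\n", sep = "")
})

setMethod("show", "FingerprintResult", function(object) {
  cat("FingerprintResult: accuracy ",
      format(object@accuracy, digits = 4), " (",
      sum(object@correct), "/", length(object@correct), " correct)\n",
      sep = "")
})

setMethod("show", "CcaModeResult", function(object) {
  cat("CcaModeResult: r1 = ", format(object@r1, digits = 4),
      ", permutation p = ", format(object@pPerm, digits = 4),
      " (", object@nPerm, " permutations, ", object@nPc, " PCs)\n",
      sep = "")
})
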