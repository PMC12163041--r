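# Shared cohort computations, evaluated lazily and cached for the whole
# test session: several acceptance properties (fingerprint recovery, group
# classification, CCA recovery) are read off the same multi-seed pipeline
# runs, so they are computed once here.

.cohortCache <- new.env(parent = emptyenv())

# one full desk-scale pipeline run: fingerprint accuracies for PL-H0,
# PL-H1 and the temporal baseline, plus classification AUCs (session-1
# features, 10 PCs)
cohortRun <- function(seed) {
  key <- paste0("run", seed)
  if (!is.null(.cohortCache[[key]])) return(.cohortCache[[key]])
  coh <- generateCohort(cohortSpec(seed = seed))
  fe <- extractTopoFeatures(coh@series, seed = 1L)
  te <- temporalFeatureSet(coh@series)
  res <- list(
    fpH0 = fpAccuracy(fe$h0),
    fpH1 = fpAccuracy(fe$h1),
    fpTemporal = fpAccuracy(te),
    aucPl = classifyBinary(sessionMatrix(fe$both, 1L), coh@group,
                           nPc = 10L, seed = 5L)$auc,
    aucTemporal = classifyBinary(sessionMatrix(te, 1L), coh@group,
                                 nPc = 10L, seed = 5L)$auc)
  .cohortCache[[key]] <- res
  res
}

cohortRuns <- function(seeds) lapply(seeds, cohortRun)

# the CCA evaluation cohort: 150 subjects give the permutation test the
# power the small fingerprinting cohort cannot
ccaPlantedRun <- function() {
  if (!is.null(.cohortCache$cca)) return(.cohortCache$cca)
  coh <- generateCohort(cohortSpec(nSubjects = 150L, nRois = 10L,
                                   seed = 901L))
  fe <- extractTopoFeatures(coh@series, seed = 1L)
  X <- (sessionMatrix(fe$both, 1L) + sessionMatrix(fe$both, 2L)) / 2
  res <- list(cohort = coh, features = fe, X = X,
              cca = ccaFirstMode(X, coh@behaviors, nPc = 20L,
                                 nPerm = 1999L, seed = 7L))
  .cohortCache$cca <- res
  res
}
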