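#' Derive a per-stage seed from a master seed
#'
#' Documented splitting rule: stage i (1-based position of the stage name
#' in the pipeline's fixed stage list) gets
#' \code{(master * 97 + i * 10007) mod (2^31 - 1)}.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
deriveSeed <- function(master, stage) {
  stages <- c("simulate", "embed", "ph", "landscape", "baseline",
              "fingerprint", "cca", "predict")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown stage: ", stage)
  as.integer((as.numeric(master) * 97 + i * 10007) %% 2147483647)
}

#' Write a cohort to a directory of delimited files
#'
#' Layout: one \code{sub-XXX_ses-S.tsv} per subject-session (first column
#' \code{roi_id}, then one column per timepoint labelled \code{t<index>},
#' tab-delimited), \code{networks.tsv} (roi_id, network),
#' \code{behaviors.tsv} (subject + item columns), \code{groups.tsv}
#' (subject, group) and \code{truth.json} (latents and planted generator
#' parameters).
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (key in names(cohort@series)) {
    x <- cohort@series[[key]]
    df <- data.frame(roi_id = seq_len(nrow(x)), x, check.names = FALSE)
    colnames(df)[-1L] <- paste0("t", seq_len(ncol(x)) - 1L)
    p <- file.path(dir, paste0(key, ".tsv"))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  nets <- data.frame(roi_id = seq_along(cohort@networkLabels),
                     network = cohort@networkLabels)
  write.table(nets, file.path(dir, "networks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  beh <- data.frame(subject = seq_len(nrow(cohort@behaviors)),
                    cohort@behaviors, check.names = FALSE)
  write.table(beh, file.path(dir, "behaviors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  grp <- data.frame(subject = seq_along(cohort@group),
                    group = cohort@group)
  write.table(grp, file.path(dir, "groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(latents = cohort@latents, truth = cohort@truth,
         spec = list(seed = cohort@spec@seed,
                     nSubjects = cohort@spec@nSubjects,
                     nRois = cohort@spec@nRois,
                     nTimepoints = cohort@spec@nTimepoints,
                     tr = cohort@spec@tr)),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(c(paths, file.path(dir, c("networks.tsv", "behaviors.tsv",
                                      "groups.tsv", "truth.json"))))
}

#' Read a cohort directory of ROI time-series files
#'
#' Reads every \code{sub-XXX_ses-S.tsv} in the layout written by
#' [writeCohort()] (user data in the same layout works identically) and
#' validates it: all matrices must share ROI count and length, contain no
#' missing values, and every subject must have both sessions. Sidecar
#' tables (networks, behaviors, groups) are read when present.
#'
#' @param path directory path.
#' @return list with \code{series} (named list of ROI x time matrices),
#'   and, when present, \code{networkLabels}, \code{behaviors},
#'   \code{group}.
#' @export
readTimeseriesDir <- function(path) {
  files <- sort(list.files(path, pattern = "^sub-[0-9]+_ses-[0-9]+\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) stop("no sub-*_ses-*.tsv files found in ", path)
  series <- list()
  for (f in files) {
    df <- read.delim(f, check.names = FALSE)
    x <- as.matrix(df[, -1L, drop = FALSE])
    if (anyNA(x)) {
      bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
      stop("missing value in ", basename(f), " at row ", bad[1L],
           ", column ", bad[2L])
    }
    key <- sub("\\.tsv$", "", basename(f))
    rownames(x) <- sprintf("roi-%03d", df$roi_id)
    series[[key]] <- unname(`rownames<-`(x, rownames(x)))
  }
  dims <- vapply(series, dim, integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    ragged <- names(series)[dims[1L, ] != dims[1L, 1L] |
                              dims[2L, ] != dims[2L, 1L]]
    stop("ragged matrices (ROI count or length differs): ",
         paste(ragged, collapse = ", "))
  }
  subj <- sub("_ses-[0-9]+$", "", names(series))
  nSess <- table(subj)
  if (any(nSess != 2L))
    stop("subjects without exactly two sessions: ",
         paste(names(nSess)[nSess != 2L], collapse = ", "))
  out <- list(series = series)
  np <- file.path(path, "networks.tsv")
  if (file.exists(np)) out$networkLabels <- read.delim(np)$network
  bp <- file.path(path, "behaviors.tsv")
  if (file.exists(bp)) {
    b <- read.delim(bp, check.names = FALSE)
    out$behaviors <- as.matrix(b[, -1L, drop = FALSE])
  }
  gp <- file.path(path, "groups.tsv")
  if (file.exists(gp)) out$group <- read.delim(gp)$group
  out
}

#' Pipeline configuration
#'
#' Validated flat configuration for [runPipeline()]; unknown keys are
#' rejected. \code{NULL} for \code{delay}/\code{m} means automatic
#' selection; \code{inputDir = NULL} means simulate a cohort with
#' [cohortSpec()] defaults at the derived seed.
#'
#' @param ... overrides of the defaults listed in the source.
#' @return named list of class "topobrainConfig".
#' @export
pipelineConfig <- function(...) {
  cfg <- list(inputDir = NULL, outDir = NULL, band = NULL, delay = NULL,
              m = NULL, landmarks = 50L, k = 5L, nBins = 20L, nPc = 10L,
              nPerm = 999L, nFolds = 5L, nRepeats = 10L, seed = 1L,
              nSubjects = 50L, nRois = 20L, nTimepoints = 300L, tr = 0.72)
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) &&
      is.character(over[[1L]]))
    over <- yaml::read_yaml(over[[1L]])
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "topobrainConfig")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when no input directory is given), feature
#' extraction (embedding, persistence, landscapes), the temporal baseline,
#' cross-session fingerprinting (H0, H1, temporal; per network when labels
#' exist), first-mode CCA of the combined topological features against the
#' behaviours, group classification (topological vs temporal AUC), and
#' behavioural regression on domain summary scores. Returns a manifest of
#' the headline numbers; when \code{outDir} is set, writes result files
#' and records their md5 checksums in \code{manifest.json}.
#'
#' @param config a [pipelineConfig()] list.
#' @return manifest list.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "topobrainConfig"))
  if (is.null(config$inputDir)) {
    coh <- generateCohort(cohortSpec(
      nSubjects = config$nSubjects, nRois = config$nRois,
      nTimepoints = config$nTimepoints, tr = config$tr,
      seed = deriveSeed(config$seed, "simulate")))
    series <- coh@series
    networkLabels <- coh@networkLabels
    behaviors <- coh@behaviors
    group <- coh@group
  } else {
    inp <- readTimeseriesDir(config$inputDir)
    series <- inp$series
    networkLabels <- inp$networkLabels
    behaviors <- inp$behaviors
    group <- inp$group
  }

  feats <- extractTopoFeatures(series, delay = config$delay, m = config$m,
                               landmarks = config$landmarks, k = config$k,
                               nBins = config$nBins, band = config$band,
                               tr = config$tr,
                               seed = deriveSeed(config$seed, "ph"))
  temporal <- temporalFeatureSet(series)

  fp <- list(
    h0 = identifySubjects(sessionMatrix(feats$h0, 1L),
                          sessionMatrix(feats$h0, 2L)),
    h1 = identifySubjects(sessionMatrix(feats$h1, 1L),
                          sessionMatrix(feats$h1, 2L)),
    temporal = identifySubjects(sessionMatrix(temporal, 1L),
                                sessionMatrix(temporal, 2L)))

  manifest <- list(
    params = feats$params,
    fingerprint = lapply(fp, accuracy))

  if (!is.null(behaviors)) {
    X1 <- sessionMatrix(feats$both, 1L)
    cca <- ccaFirstMode(X1, behaviors, nPc = config$nPc,
                        nPerm = config$nPerm,
                        seed = deriveSeed(config$seed, "cca"))
    manifest$cca <- list(r1 = cca@r1, pPerm = cca@pPerm)
  }
  if (!is.null(group)) {
    clTopo <- classifyBinary(sessionMatrix(feats$both, 1L), group,
                             nFolds = config$nFolds, nPc = config$nPc,
                             seed = deriveSeed(config$seed, "predict"))
    clTemp <- classifyBinary(sessionMatrix(temporal, 1L), group,
                             nFolds = config$nFolds, nPc = config$nPc,
                             seed = deriveSeed(config$seed, "predict"))
    manifest$auc <- list(topological = clTopo$auc, temporal = clTemp$auc)
  }

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    resPath <- file.path(config$outDir, "results.json")
    jsonlite::write_json(manifest, resPath, digits = NA,
                         auto_unbox = TRUE)
    manifest$checksums <- as.list(tools::md5sum(resPath))
    cfgPath <- file.path(config$outDir, "config.json")
    jsonlite::write_json(unclass(config), cfgPath, digits = NA,
                         auto_unbox = TRUE, null = "null")
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  manifest
}
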