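#' PCA feature reduction
#'
#' z-scores the columns and returns the top \code{nPc} principal-component
#' scores. For cross-validated modelling use the internal train/apply
#' split that [classifyBinary()] and [regressBehavior()] perform — fitting
#' the z-scoring and PCA inside each training fold — rather than this
#' whole-sample reduction.
#'
#' @param F subjects x features matrix.
#' @param nPc components kept; must be < number of subjects.
#' @return subjects x nPc score matrix.
#' @export
reduceFeatures <- function(F, nPc) {
  F <- as.matrix(F)
  if (nrow(F) <= nPc)
    stop("n_subjects (", nrow(F), ") must exceed nPc (", nPc, ")")
  pcaScores(F, nPc)$scores
}

# z-score + PCA fitted on training rows only, applied to new rows
fitReducer <- function(Xtr, nPc) {
  mu <- colMeans(Xtr)
  s <- apply(Xtr, 2L, sd); s[s == 0] <- 1
  Xs <- sweep(sweep(Xtr, 2L, mu), 2L, s, `/`)
  nPc <- min(nPc, nrow(Xtr) - 1L, ncol(Xtr))
  rot <- prcomp(Xs, center = FALSE, rank. = nPc)$rotation
  list(mu = mu, s = s, rot = rot)
}

applyReducer <- function(red, X) {
  sweep(sweep(X, 2L, red$mu), 2L, red$s, `/`) %*% red$rot
}

stratifiedFolds <- function(labels, nFolds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

#' Cross-validated penalised logistic classification
#'
#' Stratified k-fold cross-validation of a ridge-penalised logistic
#' regression (fixed penalty strength 1, intercept included) on
#' PCA-reduced features. The z-scoring and PCA are fitted inside each
#' training fold and applied to its held-out fold, so no held-out
#' statistic leaks into training. Out-of-fold class probabilities are
#' aggregated over all folds into a single ROC curve, and its AUC is the
#' primary metric.
#'
#' @param F subjects x features matrix.
#' @param labels binary vector (0/1 or 2-level factor); both classes must
#'   be present.
#' @param nFolds folds (default 5, stratified).
#' @param nPc PCA components (capped at training-fold size - 1).
#' @param seed RNG seed controlling the fold split.
#' @return list with \code{auc}, \code{prob} (out-of-fold probabilities),
#'   \code{fold}, \code{labels}, \code{seed}.
#' @export
classifyBinary <- function(F, labels, nFolds = 5L, nPc = 100L, seed = 1L) {
  F <- as.matrix(F)
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) != 2L) stop("both classes must be present")
  set.seed(seed)
  fold <- stratifiedFolds(y, nFolds)
  prob <- numeric(length(y))
  for (fd in seq_len(nFolds)) {
    tr <- fold != fd
    red <- fitReducer(F[tr, , drop = FALSE], nPc)
    Xtr <- applyReducer(red, F[tr, , drop = FALSE])
    Xte <- applyReducer(red, F[!tr, , drop = FALSE])
    fit <- glmnet::glmnet(Xtr, y[tr], family = "binomial", alpha = 0,
                          lambda = 1 / sum(tr), standardize = FALSE)
    prob[!tr] <- as.numeric(predict(fit, Xte, type = "response"))
  }
  auc <- as.numeric(pROC::auc(pROC::roc(y, prob, quiet = TRUE,
                                        direction = "<",
                                        levels = c(0L, 1L))))
  list(auc = auc, prob = prob, fold = fold, labels = y, seed = seed)
}

#' Repeated cross-validated behavioural regression
#'
#' Linear regression of a behavioural score on PCA-reduced features under
#' k-fold cross-validation repeated \code{nRepeats} times with different
#' random splits. Per repeat, out-of-fold predictions are pooled and their
#' Pearson correlation with the observed scores is the metric; the per-
#' repeat r values (mean +/- sd) are returned. PCA and z-scoring are fit
#' within training folds. Fold splits are functions of (seed, repeat)
#' only, so two feature sets evaluated with the same seed share splits and
#' can be compared pairwise by repeat ([pairedCompare()]).
#'
#' @param F subjects x features matrix.
#' @param y numeric score with positive variance.
#' @param nFolds,nRepeats cross-validation layout (default 5 x 10).
#' @param nPc PCA components (capped at training-fold size - 1).
#' @param seed base RNG seed; repeat i uses seed + i.
#' @return list with \code{r} (one per repeat), \code{mean}, \code{sd},
#'   \code{seed}.
#' @export
regressBehavior <- function(F, y, nFolds = 5L, nRepeats = 10L, nPc = 100L,
                            seed = 1L) {
  F <- as.matrix(F)
  if (var(y) == 0) stop("behavioural score has zero variance")
  rs <- numeric(nRepeats)
  for (rep in seq_len(nRepeats)) {
    set.seed(seed + rep)
    fold <- rep_len(seq_len(nFolds), length(y))[sample.int(length(y))]
    pred <- numeric(length(y))
    for (fd in seq_len(nFolds)) {
      tr <- fold != fd
      red <- fitReducer(F[tr, , drop = FALSE], nPc)
      Xtr <- applyReducer(red, F[tr, , drop = FALSE])
      Xte <- applyReducer(red, F[!tr, , drop = FALSE])
      fit <- lm.fit(cbind(1, Xtr), y[tr])
      pred[!tr] <- drop(cbind(1, Xte) %*% fit$coefficients)
    }
    rs[rep] <- cor(pred, y)
  }
  list(r = rs, mean = mean(rs), sd = sd(rs), seed = seed)
}

#' Paired comparison of per-repeat metrics
#'
#' Paired t-test between two feature sets' per-repeat metrics (paired by
#' repeat, which requires both sets to have been evaluated with identical
#' fold splits, i.e. the same seed). A zero-variance nonzero difference is
#' flagged as degenerate (infinite t) and reported with p = 0; identical
#' vectors give t = 0, p = 1.
#'
#' @param rA,rB equal-length (>= 2) metric vectors.
#' @return list with \code{t}, \code{p}, \code{meanDiff},
#'   \code{degenerate}.
#' @export
pairedCompare <- function(rA, rB) {
  if (length(rA) != length(rB)) stop("metric vectors must be equal length")
  if (length(rA) < 2L) stop("need at least two paired repeats")
  d <- rA - rB
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, meanDiff = 0, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = 0, meanDiff = mean(d),
                degenerate = TRUE))
  }
  ht <- t.test(rA, rB, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, meanDiff = mean(d),
       degenerate = FALSE)
}

#' Per-domain behavioural summary scores
#'
#' Groups behavioural items by domain, z-scores the items, and extracts
#' each domain's first principal component as its summary score, with the
#' sign aligned so the score correlates positively with the domain's item
#' mean. One-item domains pass through z-scored.
#'
#' @param Y subjects x items matrix with column names.
#' @param domainMap named character vector, item name -> domain name;
#'   every item of Y must be mapped.
#' @return subjects x domains matrix of summary scores.
#' @export
domainSummary <- function(Y, domainMap) {
  Y <- as.matrix(Y)
  un <- setdiff(colnames(Y), names(domainMap))
  if (length(un)) stop("unmapped items: ", paste(un, collapse = ", "))
  domains <- unique(domainMap[colnames(Y)])
  out <- matrix(NA_real_, nrow(Y), length(domains),
                dimnames = list(rownames(Y), domains))
  for (dm in domains) {
    items <- colnames(Y)[domainMap[colnames(Y)] == dm]
    Z <- zscore(Y[, items, drop = FALSE])
    if (length(items) == 1L) { out[, dm] <- Z[, 1L]; next }
    sc <- prcomp(Z, center = FALSE, rank. = 1L)$x[, 1L]
    if (cor(sc, rowMeans(Z)) < 0) sc <- -sc
    out[, dm] <- sc
  }
  out
}
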