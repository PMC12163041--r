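# Independent oracles used to cross-check the package implementation.
# The persistence oracle is the textbook full boundary-matrix reduction
# over GF(2): every simplex (vertex, edge, triangle) is a column in one
# global filtration order, reduced left to right with no union-find, no
# clearing and no fast paths — an algorithmically separate route from the
# package's C++ engine.

# full-reduction Rips persistence for small clouds (n <= ~25)
oracleRips <- function(cloud, maxEps = NULL) {
  d <- as.matrix(dist(cloud))
  n <- nrow(d)
  if (is.null(maxEps)) maxEps <- max(d)
  simp <- list()
  for (i in seq_len(n)) simp[[length(simp) + 1L]] <-
    list(dim = 0L, v = i, val = 0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (d[i, j] <= maxEps)
      simp[[length(simp) + 1L]] <- list(dim = 1L, v = c(i, j),
                                        val = d[i, j])
  if (n >= 3L)
    for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L))
      for (k in (j + 1L):n) {
        w <- max(d[i, j], d[i, k], d[j, k])
        if (w <= maxEps)
          simp[[length(simp) + 1L]] <- list(dim = 2L, v = c(i, j, k),
                                            val = w)
      }
  ## global filtration order: value, then dimension, then lex vertex order
  vals <- vapply(simp, `[[`, numeric(1), "val")
  dims <- vapply(simp, `[[`, integer(1), "dim")
  lex <- vapply(simp, function(s)
    paste(sprintf("%06d", s$v), collapse = ","), character(1))
  ord <- order(vals, dims, lex)
  simp <- simp[ord]
  ns <- length(simp)
  idxOf <- new.env()
  for (ii in seq_len(ns))
    assign(paste(simp[[ii]]$v, collapse = ","), ii, envir = idxOf)
  cols <- vector("list", ns)
  for (ii in seq_len(ns)) {
    s <- simp[[ii]]
    if (s$dim == 0L) { cols[[ii]] <- integer(0); next }
    faces <- if (s$dim == 1L) list(s$v[1], s$v[2]) else
      list(s$v[c(1, 2)], s$v[c(1, 3)], s$v[c(2, 3)])
    cols[[ii]] <- sort(vapply(faces, function(f)
      get(paste(f, collapse = ","), envir = idxOf), integer(1)))
  }
  lowOwner <- integer(ns)   # 0 = free
  pairs <- matrix(integer(), 0, 2)
  for (jj in seq_len(ns)) {
    col <- cols[[jj]]
    while (length(col)) {
      low <- col[length(col)]
      if (lowOwner[low] == 0L) break
      other <- cols[[lowOwner[low]]]
      col <- sort(union(setdiff(col, other), setdiff(other, col)))
    }
    cols[[jj]] <- col
    if (length(col)) {
      lowOwner[col[length(col)]] <- jj
      pairs <- rbind(pairs, c(col[length(col)], jj))
    }
  }
  mk <- function(dm) {
    sel <- pairs[vapply(pairs[, 1], function(p) simp[[p]]$dim,
                        integer(1)) == dm, , drop = FALSE]
    out <- cbind(birth = vapply(sel[, 1], function(p) simp[[p]]$val,
                                numeric(1)),
                 death = vapply(sel[, 2], function(p) simp[[p]]$val,
                                numeric(1)))
    ## essential classes: positive simplices of dim dm never used as a low
    pos <- setdiff(which(vapply(simp, function(s) s$dim,
                                integer(1)) == dm &
                           vapply(cols, length, integer(1)) == 0L),
                   pairs[, 1])
    ess <- setdiff(pos, pairs[, 2])
    if (length(ess))
      out <- rbind(out, cbind(birth = vapply(ess, function(p)
        simp[[p]]$val, numeric(1)), death = maxEps))
    out[out[, 2] > out[, 1], , drop = FALSE]
  }
  list(h0 = mk(0L), h1 = mk(1L), maxEps = maxEps)
}

# sorted multiset comparison of diagrams with a tolerance, after matching
# by sorted (birth, death) order
expectDiagramsEqual <- function(got, want, tol = 1e-6) {
  got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  expect_equal(nrow(got), nrow(want))
  if (nrow(got))
    expect_lt(max(abs(got - want)), tol)
}

# histogram MI profile computed through table()/cut(), independently of
# the package's tabulate-based estimator
oracleMIProfile <- function(x, maxLag, nBins = 16L) {
  vapply(seq_len(maxLag), function(l) {
    a <- x[seq_len(length(x) - l)]
    b <- x[(l + 1):length(x)]
    ca <- cut(a, breaks = seq(min(a), max(a), length.out = nBins + 1L),
              include.lowest = TRUE)
    cb <- cut(b, breaks = seq(min(b), max(b), length.out = nBins + 1L),
              include.lowest = TRUE)
    tab <- table(ca, cb) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    nz <- tab > 0
    sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  }, numeric(1))
}

# brute-force false-nearest-neighbour fractions via explicit loops
oracleFNN <- function(x, delay, maxDim, rTol = 15, aTol = 2) {
  sdA <- sqrt(mean((x - mean(x))^2))
  out <- rep(NA_real_, maxDim)
  for (m in seq_len(maxDim)) {
    nPts <- length(x) - m * delay
    if (nPts < 10L) break
    emb <- sapply(0:(m - 1L), function(c) x[(1 + c * delay):(nPts + c * delay)])
    emb <- matrix(emb, nPts)
    nxt <- x[(m * delay + 1L):(m * delay + nPts)]
    flags <- logical(nPts)
    for (i in seq_len(nPts)) {
      dd <- sqrt(colSums((t(emb) - emb[i, ])^2))
      dd[i] <- Inf
      j <- which.min(dd)
      st <- abs(nxt[i] - nxt[j])
      dup <- dd[j] < 1e-8 * sdA && st < 1e-8 * sdA
      flags[i] <- !dup &&
        (st / max(dd[j], .Machine$double.eps) > rTol ||
           sqrt(dd[j]^2 + st^2) / sdA > aTol)
    }
    out[m] <- mean(flags)
  }
  out
}

# convenience: per-session feature matrices -> fingerprint accuracy
fpAccuracy <- function(tf) {
  accuracy(identifySubjects(sessionMatrix(tf, 1L), sessionMatrix(tf, 2L)))
}
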