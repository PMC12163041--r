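test_that("behavioural filtering applies the three configured rules", {
  set.seed(1)
  Y <- matrix(rnorm(50 * 4), 50, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  keep <- filterBehaviors(Y)
  expect_equal(keep$kept, colnames(Y))

  ## one dominated item, one near-constant, one too missing: 7 of 10 kept
  Y10 <- matrix(rnorm(100 * 10), 100, 10,
                dimnames = list(NULL, paste0("v", 1:10)))
  Y10[, 2] <- c(rep(1, 99), 2)              # max category 99% > 0.95
  Y10[, 5] <- 3 + rnorm(100, 0, 1e-9)       # variance below floor
  Y10[1:20, 8] <- NA                        # 20% missing > 10%
  got <- filterBehaviors(Y10)
  expect_setequal(got$kept, paste0("v", c(1, 3, 4, 6, 7, 9, 10)))
  expect_equal(ncol(got$Y), 7L)
  expect_error(filterBehaviors(Y10[, 2, drop = FALSE]), "every item")
})

test_that("deconfounding centres, annihilates, and orthogonalises", {
  set.seed(2)
  X <- matrix(rnorm(40 * 3), 40, 3)
  expect_equal(deconfound(X), scale(X, scale = FALSE),
               ignore_attr = TRUE)
  C <- matrix(rnorm(40 * 2), 40, 2)
  lin <- C %*% matrix(1:6, 2, 3) + 5
  expect_lt(max(abs(deconfound(lin, C))), 1e-10)
  R <- deconfound(X, C)
  expect_lt(max(abs(crossprod(R, cbind(1, C)))), 1e-8)
  expect_error(deconfound(X, cbind(C, C[, 1])), "rank deficient")
})

test_that("first canonical correlation matches stats::cancor", {
  set.seed(3)
  X <- matrix(rnorm(80 * 6), 80, 6)
  Y <- X[, 1:3] %*% matrix(rnorm(9), 3, 3) + matrix(rnorm(80 * 3), 80, 3)
  r <- ccaFirstMode(X, Y, nPc = 3L, nPerm = 0L)
  want <- cancor(topobrain:::pcaScores(X, 3L)$scores,
                 topobrain:::pcaScores(Y, 3L)$scores)$cor[1L]
  expect_equal(r@r1, want, tolerance = 1e-10)
  ## the reported variates realise r1
  expect_equal(abs(cor(r@xVariate, r@yVariate)), r@r1, tolerance = 1e-10)
})

test_that("a copied matrix gives r1 = 1 and degenerate p at the floor", {
  set.seed(4)
  X <- matrix(rnorm(60 * 8), 60, 8)
  r <- ccaFirstMode(X, X, nPc = 4L, nPerm = 199L, seed = 5L)
  expect_equal(r@r1, 1, tolerance = 1e-9)
  expect_equal(r@pPerm, 1 / 200)
  expect_length(r@permNull, 199L)
  expect_error(ccaFirstMode(X, X, nPc = 60L), "lower nPc")
  expect_error(ccaFirstMode(X, X[1:10, ], nPc = 3L), "aligned")
})

test_that("null data give calibrated permutation p-values", {
  set.seed(6)
  ps <- replicate(40, {
    X <- matrix(rnorm(200 * 30), 200, 30)
    Y <- matrix(rnorm(200 * 25), 200, 25)
    ccaFirstMode(X, Y, nPc = 20L, nPerm = 199L,
                 seed = sample.int(1e6, 1))@pPerm
  })
  expect_gte(mean(ps > 0.05), 0.85)
})

test_that("r1 is invariant to invertible linear maps of either block", {
  set.seed(7)
  X <- scale(matrix(rnorm(50 * 5), 50, 5), scale = FALSE)
  Y <- scale(matrix(rnorm(50 * 4), 50, 4), scale = FALSE)
  base <- topobrain:::firstCanonical(X, Y)$r1
  A <- matrix(rnorm(25), 5, 5) + 5 * diag(5)
  B <- matrix(rnorm(16), 4, 4) + 5 * diag(4)
  expect_equal(topobrain:::firstCanonical(X %*% A, Y %*% B)$r1, base,
               tolerance = 1e-9)
})

test_that("permutation null quantiles agree across disjoint seed batches", {
  set.seed(8)
  X <- matrix(rnorm(120 * 10), 120, 10)
  Y <- matrix(rnorm(120 * 8), 120, 8)
  a <- ccaFirstMode(X, Y, nPc = 6L, nPerm = 600L, seed = 1L)@permNull
  b <- ccaFirstMode(X, Y, nPc = 6L, nPerm = 600L, seed = 2L)@permNull
  qs <- c(0.25, 0.5, 0.75, 0.9)
  expect_lt(max(abs(quantile(a, qs) - quantile(b, qs))), 0.05)
})

test_that("ROI contributions separate signal from noise blocks", {
  set.seed(9)
  n <- 80
  latent <- runif(n, -1, 1)
  grid <- seq(0, 1, length.out = 5)
  mkL <- function(vals, dim) new("PersistenceLandscape", dim = dim,
                                 grid = grid, values = matrix(vals, 1, 5))
  keys <- sprintf("sub-%03d_ses-1", 1:n)
  lans <- lapply(1:n, function(i)
    lapply(1:2, function(r) list(
      ## ROI 1 scales with the latent; ROI 2 is pure noise
      h0 = mkL(if (r == 1) (2 + latent[i]) * (1:5) else runif(5), 0L),
      h1 = mkL(if (r == 1) (2 + latent[i]) * (5:1) else runif(5), 1L))))
  names(lans) <- keys
  tf <- assembleFeatures(lans)
  fit <- ccaFirstMode(sessionMatrix(tf),
                      cbind(latent + rnorm(n, 0, 0.2), rnorm(n)),
                      nPc = 4L, nPerm = 99L, seed = 1L)
  contrib <- roiContributions(tf, fit, networkLabels = c("A", "B"))
  c1 <- abs(contrib$roi$contribution[contrib$roi$roi == 1])
  c2 <- abs(contrib$roi$contribution[contrib$roi$roi == 2])
  expect_gt(min(c1), 0.9)
  expect_lt(max(c2), 2 / sqrt(n) * 2.5)
  expect_error(roiContributions(tf, fit, networkLabels = "A"),
               "network label")
})

test_that("behaviour loadings rank planted items first with correct signs", {
  set.seed(10)
  n <- 120
  lat <- rnorm(n)
  Y <- cbind(pos = lat + rnorm(n, 0, 0.3),
             neg = -lat + rnorm(n, 0, 0.3),
             junk1 = rnorm(n), junk2 = rnorm(n))
  X <- cbind(lat + rnorm(n, 0, 0.3), matrix(rnorm(3 * n), n, 3))
  fit <- ccaFirstMode(X, Y, nPc = 4L, nPerm = 99L, seed = 2L)
  top <- topBehaviorLoadings(fit, k = 2L)
  expect_setequal(names(top), c("pos", "neg"))
  expect_lt(prod(top[c("pos", "neg")]), 0)  # opposite signs
  expect_length(topBehaviorLoadings(fit, k = 0L), 0L)
  expect_warning(all4 <- topBehaviorLoadings(fit, k = 10L), "item count")
  expect_length(all4, 4L)
  ## loadings are correlations: invariant to item rescaling
  fit2 <- ccaFirstMode(X, sweep(Y, 2, c(10, 0.1, 2, 5), `*`), nPc = 4L,
                       nPerm = 0L)
  expect_equal(abs(fit2@behaviorLoadings), abs(fit@behaviorLoadings),
               tolerance = 1e-6, ignore_attr = TRUE)
})
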