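test_that("two points merge once and the essential bar is capped", {
  two <- matrix(c(0, 0, 3, 0), 2, 2, byrow = TRUE)
  p <- persistencePairs(ripsH0(two, maxEps = 5))
  expect_equal(p[order(p[, 2]), ],
               cbind(birth = c(0, 0), death = c(3, 5)), ignore_attr = TRUE)
})

test_that("unit square has the hand-enumerated H0 and H1 barcodes", {
  sq <- fixtureSquare()
  h0 <- persistencePairs(ripsH0(sq, maxEps = 2))
  expect_equal(sort(h0[, 2]), c(1, 1, 1, 2))
  expect_true(all(h0[, 1] == 0))
  h1 <- persistencePairs(ripsH1(sq))
  expect_equal(nrow(h1), 1L)
  expect_equal(as.numeric(h1), c(1, sqrt(2)))
})

test_that("collinear points have no loops and tiny clouds are handled", {
  line <- cbind(c(0, 1, 2), 0)
  expect_equal(nrow(persistencePairs(ripsH1(line))), 0L)
  expect_equal(nrow(persistencePairs(ripsH1(line[1:2, ]))), 0L)
  expect_error(ripsDiagrams(matrix(numeric(), 0, 2)), "empty")
  ## n-point cloud always has n H0 bars
  set.seed(1)
  cl <- matrix(rnorm(14), 7, 2)
  expect_equal(nrow(persistencePairs(ripsH0(cl))), 7L)
})

test_that("H0 finite deaths equal the minimum-spanning-tree edge weights", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    dims <- sample(2:4, 1)
    cl <- matrix(rnorm(n * dims), n, dims)
    p <- persistencePairs(ripsH0(cl))
    finite <- sort(p[p[, 2] < max(dist(cl)) - 1e-12, 2])
    mst <- sort(as.numeric(vegan::spantree(dist(cl))$dist))
    expect_equal(finite, mst, tolerance = 1e-12)
  }
})

test_that("H1 diagrams match the independent full-reduction oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(8:20, 1)
    cl <- matrix(rnorm(n * 2), n, 2)
    got <- ripsDiagrams(cl, maxDim = 1L)
    want <- oracleRips(cl)
    expectDiagramsEqual(persistencePairs(got$h1), want$h1)
    expectDiagramsEqual(persistencePairs(got$h0), want$h0)
  }
})

test_that("noisy circle yields one dominant loop agreeing with the oracle", {
  cl <- fixtureCircle(24L, 1, 0.02, seed = 13L)
  got <- persistencePairs(ripsH1(cl))
  want <- oracleRips(cl)$h1
  expectDiagramsEqual(got, want)
  pers <- got[, 2] - got[, 1]
  expect_gt(max(pers), 1)
  expect_equal(sum(pers > 0.5), 1L)
})

test_that("noiseless circle has exactly one persistent loop", {
  cl <- fixtureCircle(60L, 1, 0, seed = 1L)
  p <- persistencePairs(ripsH1(cl))
  pers <- p[, 2] - p[, 1]
  expect_equal(sum(pers > 1), 1L)
})

test_that("diagrams are scale-equivariant and permutation-invariant", {
  set.seed(31)
  cl <- matrix(rnorm(30), 15, 2)
  base <- ripsDiagrams(cl)
  for (c in c(0.5, 3)) {
    sc <- ripsDiagrams(c * cl)
    expectDiagramsEqual(persistencePairs(sc$h1),
                        c * persistencePairs(base$h1), tol = 1e-9)
    expectDiagramsEqual(persistencePairs(sc$h0),
                        c * persistencePairs(base$h0), tol = 1e-9)
  }
  perm <- ripsDiagrams(cl[sample(15), ])
  expectDiagramsEqual(persistencePairs(perm$h1),
                      persistencePairs(base$h1), tol = 1e-12)
  expectDiagramsEqual(persistencePairs(perm$h0),
                      persistencePairs(base$h0), tol = 1e-12)
})

test_that("small perturbations move bar endpoints by at most twice their size", {
  ## bottleneck stability probed on the square fixture
  sq <- fixtureSquare()
  set.seed(41)
  delta <- 0.01
  for (rep in 1:5) {
    pert <- sq + matrix(runif(8, -delta / sqrt(2), delta / sqrt(2)), 4, 2)
    h1 <- persistencePairs(ripsH1(pert, maxEps = max(dist(pert))))
    expect_equal(nrow(h1), 1L)
    expect_lt(max(abs(h1 - c(1, sqrt(2)))), 2 * delta)
  }
})

test_that("maxmin landmarks keep small clouds intact and find corners", {
  set.seed(51)
  cl <- matrix(rnorm(20), 10, 2)
  kept <- landmarkSubsample(cl, nMax = 300L, seed = 1L)
  expect_equal(unclass(kept), cl, ignore_attr = TRUE)
  expect_error(landmarkSubsample(cl, nMax = 2L), "nMax")
  ## square corners plus near-duplicate jitter: maxmin recovers the corners
  jitter <- fixtureSquare()[sample(4, 100, replace = TRUE), ] +
    matrix(rnorm(200, 0, 0.01), 100, 2)
  cloud <- rbind(fixtureSquare(), jitter)
  lm <- landmarkSubsample(cloud, nMax = 4L, seed = 3L)
  dc <- as.matrix(dist(rbind(lm, fixtureSquare())))[1:4, 5:8]
  expect_lt(max(apply(dc, 2, min)), 0.05)
  expect_identical(landmarkSubsample(cloud, nMax = 4L, seed = 3L), lm)
})
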