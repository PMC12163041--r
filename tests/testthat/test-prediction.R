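test_that("whole-sample PCA reduction is complete and deterministic", {
  set.seed(1)
  F <- matrix(rnorm(30 * 6), 30, 6)
  full <- reduceFeatures(F, 6L)
  ## reconstruction from all PCs reproduces the z-scored matrix
  rot <- prcomp(topobrain:::zscore(F), center = FALSE)$rotation
  expect_lt(max(abs(full %*% t(rot) - topobrain:::zscore(F))), 1e-8)
  Fdup <- rbind(F, F[1:3, ])
  red <- reduceFeatures(Fdup, 3L)
  expect_equal(red[31:33, ], red[1:3, ], ignore_attr = TRUE)
  expect_error(reduceFeatures(F, 30L), "exceed")
})

test_that("planted three-factor data concentrate in three components", {
  set.seed(2)
  scores <- matrix(rnorm(100 * 3), 100, 3)
  load <- matrix(rnorm(3 * 40), 3, 40)
  F <- scores %*% load + matrix(rnorm(100 * 40, 0, 0.1), 100, 40)
  pc <- prcomp(topobrain:::zscore(F), center = FALSE)
  expect_gt(sum(pc$sdev[1:3]^2) / sum(pc$sdev^2), 0.95)
  red <- reduceFeatures(F, 3L)
  expect_equal(dim(red), c(100L, 3L))
})

test_that("classification is perfect on a wide-margin feature and errors sanely", {
  set.seed(3)
  y <- rep(c(0, 1), each = 20)
  F <- cbind(y * 10 + rnorm(40, 0, 0.1), matrix(rnorm(40 * 5), 40, 5))
  r <- classifyBinary(F, y, nPc = 6L, seed = 1L)
  expect_equal(r$auc, 1)
  expect_error(classifyBinary(F, rep(1, 40), nPc = 3L), "both classes")
})

test_that("permuted labels classify at chance", {
  set.seed(4)
  aucs <- replicate(60, {
    F <- matrix(rnorm(60 * 30), 60, 30)
    classifyBinary(F, sample(rep(0:1, 30)), nPc = 10L,
                   seed = sample.int(1e6, 1))$auc
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se)
})

test_that("identical seeds give bit-identical cross-validation results", {
  set.seed(5)
  F <- matrix(rnorm(50 * 20), 50, 20)
  y <- rep(0:1, 25)
  a <- classifyBinary(F, y, nPc = 5L, seed = 42L)
  b <- classifyBinary(F, y, nPc = 5L, seed = 42L)
  expect_identical(a$prob, b$prob)
  expect_identical(a$fold, b$fold)
  yb <- rnorm(50)
  r1 <- regressBehavior(F, yb, nPc = 5L, nRepeats = 3L, seed = 7L)
  r2 <- regressBehavior(F, yb, nPc = 5L, nRepeats = 3L, seed = 7L)
  expect_identical(r1$r, r2$r)
})

test_that("AUC is invariant to monotone transforms of the scores", {
  set.seed(6)
  y <- rep(0:1, each = 15)
  prob <- plogis(rnorm(30) + y)
  a1 <- as.numeric(pROC::auc(pROC::roc(y, prob, quiet = TRUE,
                                       direction = "<", levels = c(0, 1))))
  a2 <- as.numeric(pROC::auc(pROC::roc(y, qlogis(prob), quiet = TRUE,
                                       direction = "<", levels = c(0, 1))))
  expect_equal(a1, a2)
})

test_that("regression recovers exact linear structure and stays null-calibrated", {
  set.seed(7)
  F <- matrix(rnorm(60 * 10), 60, 10)
  y <- drop(F[, 1:3] %*% c(1, -2, 0.5))
  r <- regressBehavior(F, y, nPc = 10L, nRepeats = 4L, seed = 1L)
  expect_true(all(r$r >= 0.999))
  expect_error(regressBehavior(F, rep(1, 60), nPc = 3L), "zero variance")
  rs <- replicate(40, regressBehavior(matrix(rnorm(40 * 15), 40, 15),
                                      rnorm(40), nPc = 5L, nRepeats = 1L,
                                      seed = sample.int(1e6, 1))$r)
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(mean(rs), 3 * se)          # not positively biased
  expect_gt(mean(rs), -0.2)            # mildly negative under CV is expected
})

test_that("paired comparison handles regular and degenerate inputs", {
  r <- pairedCompare(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  d <- pairedCompare(c(0.5, 0.6, 0.7), c(0.4, 0.5, 0.6))
  expect_true(d$degenerate)
  expect_true(is.infinite(d$t) && d$t > 0)
  expect_equal(d$p, 0)
  expect_error(pairedCompare(1:3, 1:2), "equal length")
  expect_error(pairedCompare(1, 2), "two paired")
  set.seed(8)
  a <- rnorm(10, 0.5, 0.05); b <- rnorm(10, 0.4, 0.05)
  want <- t.test(a, b, paired = TRUE)
  got <- pairedCompare(a, b)
  expect_equal(got$t, unname(want$statistic))
  expect_equal(got$p, want$p.value)
})

test_that("paired comparison keeps its nominal type-I error", {
  set.seed(9)
  rej <- replicate(1000, {
    a <- rnorm(10); b <- rnorm(10)
    pairedCompare(a, b)$p <= 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("domain summaries extract aligned first components", {
  set.seed(10)
  n <- 100
  fac <- rnorm(n)
  Y <- cbind(a1 = fac * 0.8 + rnorm(n, 0, 0.3),
             a2 = fac * 0.7 + rnorm(n, 0, 0.3),
             a3 = fac * 0.9 + rnorm(n, 0, 0.3),
             b1 = rnorm(n))
  dm <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B")
  s <- domainSummary(Y, dm)
  expect_equal(colnames(s), c("A", "B"))
  expect_gt(abs(cor(s[, "A"], fac)), 0.9)
  expect_gt(cor(s[, "A"], rowMeans(topobrain:::zscore(Y[, 1:3]))), 0)
  ## negating the raw items flips nothing after sign alignment
  s2 <- domainSummary(-Y, dm)
  expect_gt(cor(s2[, "A"], rowMeans(topobrain:::zscore(-Y[, 1:3]))), 0)
  ## a single-item domain passes through z-scored
  expect_equal(s[, "B"], topobrain:::zscore(Y[, "b1", drop = FALSE])[, 1],
               ignore_attr = TRUE)
  ## two perfectly correlated items: first PC explains everything
  Yp <- cbind(c1 = fac, c2 = 2 * fac)
  sp <- domainSummary(Yp, c(c1 = "C", c2 = "C"))
  expect_equal(abs(cor(sp[, "C"], fac)), 1, tolerance = 1e-10)
  expect_error(domainSummary(Y, dm[1:3]), "unmapped")
})
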