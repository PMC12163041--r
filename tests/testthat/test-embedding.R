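test_that("delay embedding matches its definition", {
  expect_equal(unclass(delayEmbed(1:5, 1, 2)),
               matrix(c(1, 2, 3, 4, 2, 3, 4, 5), 4, 2),
               ignore_attr = TRUE)
  expect_equal(unclass(delayEmbed(1:5, 2, 2)),
               matrix(c(1, 2, 3, 3, 4, 5), 3, 2), ignore_attr = TRUE)
  expect_equal(nrow(delayEmbed(rnorm(1200), 35, 4)), 1095)
  expect_error(delayEmbed(1:5, 3, 3), "too short")
})

test_that("embedded columns are shifted copies and the count formula holds", {
  set.seed(1)
  x <- rnorm(200)
  for (tau in c(1L, 3L, 7L)) for (m in c(2L, 4L)) {
    e <- delayEmbed(x, tau, m)
    expect_equal(nrow(e), 200 - (m - 1) * tau)
    for (c in seq_len(m))
      expect_identical(e[, c], x[(1 + (c - 1) * tau):(nrow(e) + (c - 1) * tau)])
  }
})

test_that("bandpass removes DC, passes the band, rejects out of band", {
  fs <- 1 / 0.72
  tt <- (0:999) / fs
  const <- rep(3, 1000)
  expect_lt(max(abs(bandpassFilter(const, fs))), 1e-6 * 3)
  inband <- sin(2 * pi * 0.04 * tt)
  out <- bandpassFilter(inband, fs)
  mid <- 200:800  # ignore filter edge transients
  expect_lt(abs(max(abs(out[mid])) - 1), 0.05)
  fast <- sin(2 * pi * 0.2 * tt)
  att <- 20 * log10(max(abs(bandpassFilter(fast, fs)[mid])))
  expect_lt(att, -20)
  expect_error(bandpassFilter(inband, fs, low = 0.01, high = 1), "Nyquist")
  expect_error(bandpassFilter(inband[1:10], fs), "too short")
})

test_that("mutual-information delay finds the quarter period of a sinusoid", {
  set.seed(2)
  x <- sin(2 * pi * (0:1399) / 140) + rnorm(1400, 0, 0.2)
  got <- selectDelayMI(x, maxLag = 70L)
  expect_false(attr(got, "warning"))
  expect_lte(abs(as.integer(got) - 35L), 2L)
  ## returned lag is the first local minimum of the independently computed
  ## (smoothed) MI profile
  prof <- oracleMIProfile(x, 70L)
  expect_equal(attr(got, "mi"), prof, tolerance = 1e-10)
})

test_that("mutual-information delay flags unstructured noise", {
  set.seed(5)
  got <- selectDelayMI(rnorm(400), maxLag = 40L)
  expect_true(attr(got, "warning"))
  expect_equal(as.integer(got), which.min(attr(got, "miSmooth")))
})

test_that("a constructed dip in the MI profile at lag 10 is found", {
  set.seed(6)
  x <- sin(2 * pi * (0:799) / 40) + rnorm(800, 0, 0.1)
  prof <- oracleMIProfile(x, 30L)
  sm <- vapply(seq_along(prof), function(i)
    mean(prof[max(1, i - 2):min(30, i + 2)]), numeric(1))
  expect_equal(which.min(sm[1:15]), 10L)    # the dip really is at 10
  expect_equal(as.integer(selectDelayMI(x, maxLag = 30L)), 10L)
})

test_that("MI delay is invariant to affine rescaling", {
  set.seed(7)
  x <- sin(2 * pi * (0:599) / 80) + rnorm(600, 0, 0.2)
  a <- selectDelayMI(x, maxLag = 40L)
  b <- selectDelayMI(-3 * x + 11, maxLag = 40L)
  expect_identical(as.integer(a), as.integer(b))
  expect_equal(attr(a, "mi"), attr(b, "mi"), tolerance = 1e-10)
})

test_that("constant series is a degenerate input", {
  expect_error(selectDelayMI(rep(1, 100), 20), "degenerate")
  expect_error(selectDimensionFNN(rep(1, 100), 5), "degenerate")
})

test_that("false nearest neighbours recover known dimensions", {
  x <- sin(2 * pi * (0:999) / 140)
  got <- selectDimensionFNN(x, delay = 35L, maxDim = 6L)
  expect_equal(as.integer(got), 2L)
  expect_equal(attr(got, "fnn")[1:2], oracleFNN(x, 35L, 2L),
               tolerance = 1e-10)
  set.seed(1)
  noise <- rnorm(600)
  gn <- selectDimensionFNN(noise, delay = 1L, maxDim = 6L)
  expect_equal(as.integer(gn), 6L)
  expect_true(attr(gn, "warning"))
})

test_that("Lorenz trajectory embeds at dimension 3", {
  skip_if_not_installed("deSolve")
  lor <- function(t, y, p)
    list(c(10 * (y[2] - y[1]), y[1] * (28 - y[3]) - y[2],
           y[1] * y[2] - 8 / 3 * y[3]))
  out <- deSolve::ode(c(1, 1, 1), seq(0, 50, 0.02), lor, NULL,
                      method = "ode45")
  x <- out[-(1:500), 2]
  tau <- as.integer(selectDelayMI(x, maxLag = 100L))
  expect_equal(as.integer(selectDimensionFNN(x, delay = tau, maxDim = 8L)),
               3L)
})

test_that("global parameter aggregation uses the median rounded up", {
  set.seed(3)
  base <- sin(2 * pi * (0:599) / 80) + rnorm(600, 0, 0.2)
  gp <- selectGlobalParams(list(base, base, base))
  expect_equal(gp$delay, as.integer(selectDelayMI(base, 40L)))
  expect_equal(gp$m, as.integer(selectDimensionFNN(
    base, as.integer(selectDelayMI(base, 40L)))))
  ## heterogeneous periods: global pair is the per-series median rounded up
  mixed <- lapply(c(48, 80, 120), function(p)
    sin(2 * pi * (0:599) / p) + rnorm(600, 0, 0.2))
  gm <- selectGlobalParams(mixed)
  expect_equal(gm$delay, as.integer(ceiling(median(gm$perSeriesDelay))))
  expect_equal(gm$m, as.integer(ceiling(median(gm$perSeriesDim))))
  expect_error(selectGlobalParams(list()), "at least one")
})
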