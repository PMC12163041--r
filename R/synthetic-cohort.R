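#' Build a cohort generator specification
#'
#' Desk-scale defaults: 50 subjects, 20 ROIs, 300 timepoints at TR 0.72 s,
#' q = 5 latents, p = 12 behavioural items, session noise sd 0.3 (signal
#' units, oscillator amplitudes are ~1), phase jitter 0.3 rad, behavioural
#' noise sd 2.1. With these defaults the planted first canonical
#' correlation between latents and behaviours is approximately 0.7 (see
#' [plantedCanonicalCorrelation()]).
#'
#' @param nSubjects,nRois,nTimepoints cohort dimensions.
#' @param tr sampling interval, seconds.
#' @param nLatents latent dimension q.
#' @param sessionNoiseSd additive Gaussian noise sd per sample.
#' @param phaseJitterSd sd (radians) of per-session phase perturbations.
#' @param behaviorDims number of behavioural items p.
#' @param behaviorNoiseSd behavioural noise sd.
#' @param effectScale scale of the latent effect on oscillator parameters.
#' @param seed integer RNG seed; the same spec is always the same cohort.
#' @param networks network names assigned to ROIs round-robin.
#' @return a [CohortSpec-class] object.
#' @export
cohortSpec <- function(nSubjects = 50L, nRois = 20L, nTimepoints = 300L,
                       tr = 0.72, nLatents = 5L, sessionNoiseSd = 0.3,
                       phaseJitterSd = 0.3, behaviorDims = 12L,
                       behaviorNoiseSd = 2.1, effectScale = 1,
                       seed = 1L,
                       networks = c("Visual", "Somatomotor",
                                    "DorsalAttention", "VentralAttention",
                                    "Limbic", "Frontoparietal", "Default")) {
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      nRois = as.integer(nRois), nTimepoints = as.integer(nTimepoints),
      tr = tr, nLatents = as.integer(nLatents),
      sessionNoiseSd = sessionNoiseSd, phaseJitterSd = phaseJitterSd,
      behaviorDims = as.integer(behaviorDims),
      behaviorNoiseSd = behaviorNoiseSd, effectScale = effectScale,
      seed = as.integer(seed), networks = networks)
}

subjectKey <- function(i, s) sprintf("sub-%03d_ses-%d", i, s)

#' Generate a synthetic two-session cohort
#'
#' Each ROI signal is a two-harmonic oscillator
#' \deqn{x(t) = a\,[\sin(2\pi f t + \phi) + \rho\sin(4\pi f t + \psi)] +
#'   \varepsilon(t),\qquad \varepsilon \sim N(0, (\sigma a)^2)\ \mathrm{iid}.}
#' The amplitude \eqn{a = \exp(0.35\,\alpha\, z \cdot u_r)} carries most of
#' the planted individuality: it is a deterministic log-linear map of the
#' subject latent z with a fixed per-ROI direction, so each subject has a
#' stable spatial pattern of oscillation scale. The harmonic ratio
#' \eqn{\rho = 0.4 + 0.05\,\tanh(\alpha z \cdot v_r)} and the relative
#' harmonic phase \eqn{\delta = \psi - 2\phi = \delta_r +
#' 0.2\tanh(\alpha z \cdot w_r)} add milder subject-specific loop-shape
#' variation. Frequencies are fixed per ROI on a grid inside 0.01-0.08 Hz,
#' and the observation noise is proportional to the ROI's amplitude
#' (\code{sessionNoiseSd} is expressed in units of that amplitude), so
#' every scale-free statistic of the signal is distribution-matched across
#' subjects and individuality lives in the geometry of the delay-embedded
#' trajectory — the regime the topological features are designed for. The
#' base phase \eqn{\phi} is subject-stable and only jittered per session,
#' with \eqn{\psi} tracking \eqn{2\phi + \delta}, so both sessions trace
#' the same loop from a different time origin.
#'
#' Behaviours are \eqn{Y_i = C z_i + \eta}, \eqn{\eta \sim N(0,
#' \mathrm{behaviorNoiseSd}^2)}, with fixed unit-norm rows of C; the group
#' label is \eqn{g_i = 1\{w \cdot z_i > 0\}} for a fixed unit vector w. All
#' randomness derives from \code{spec@seed}.
#'
#' @param spec a [CohortSpec-class].
#' @return a [SyntheticCohort-class].
#' @examples
#' coh <- generateCohort(cohortSpec(nSubjects = 4, nRois = 3,
#'                                  nTimepoints = 80, seed = 7))
#' dim(coh@series[["sub-001_ses-1"]])
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  ns <- spec@nSubjects; nr <- spec@nRois; nt <- spec@nTimepoints
  q <- spec@nLatents; p <- spec@behaviorDims
  set.seed(spec@seed)

  ## subject latents and fixed population-level directions
  z <- matrix(rnorm(ns * q), ns, q)
  unitRows <- function(m) m / sqrt(rowSums(m^2))
  Ua <- unitRows(matrix(rnorm(nr * q), nr, q))  # amplitude direction per ROI
  Uh <- unitRows(matrix(rnorm(nr * q), nr, q))  # harmonic-ratio direction
  Ud <- unitRows(matrix(rnorm(nr * q), nr, q))  # relative-phase direction
  C <- unitRows(matrix(rnorm(p * q), p, q))     # behaviour loadings
  w <- rnorm(q); w <- w / sqrt(sum(w^2))        # group direction

  al <- spec@effectScale
  ## oscillator parameters: subjects x ROIs. Identity rides mainly on the
  ## amplitude pattern a (trajectory scale); the harmonic ratio and its
  ## relative phase add milder subject-specific loop-shape variation.
  a <- exp(0.35 * al * (z %*% t(Ua)))
  ratio <- 0.4 + 0.05 * tanh(al * (z %*% t(Uh)))
  f0 <- seq(0.02, 0.07, length.out = nr)        # ROI frequency grid, Hz
  f <- matrix(f0, ns, nr, byrow = TRUE)
  delta0 <- runif(nr, -pi, pi)
  delta <- matrix(delta0, ns, nr, byrow = TRUE) +
    0.2 * tanh(al * (z %*% t(Ud)))
  phi0 <- matrix(runif(ns * nr, 0, 2 * pi), ns, nr)

  tSec <- (seq_len(nt) - 1L) * spec@tr
  series <- vector("list", 2L * ns)
  nm <- character(2L * ns)
  k <- 0L
  for (i in seq_len(ns)) {
    for (s in 1:2) {
      ePhi <- rnorm(nr, 0, spec@phaseJitterSd)
      ePsi <- rnorm(nr, 0, spec@phaseJitterSd)
      noise <- matrix(rnorm(nr * nt), nr, nt)
      x <- matrix(0, nr, nt)
      for (r in seq_len(nr)) {
        phi <- phi0[i, r] + ePhi[r]
        psi <- 2 * phi + delta[i, r] + ePsi[r]
        x[r, ] <- a[i, r] *
          (sin(2 * pi * f[i, r] * tSec + phi) +
             ratio[i, r] * sin(4 * pi * f[i, r] * tSec + psi)) +
          spec@sessionNoiseSd * a[i, r] * noise[r, ]
      }
      k <- k + 1L
      series[[k]] <- x
      nm[k] <- subjectKey(i, s)
      rownames(series[[k]]) <- sprintf("roi-%03d", seq_len(nr))
    }
  }
  names(series) <- nm

  Y <- z %*% t(C) + matrix(rnorm(ns * p, 0, spec@behaviorNoiseSd), ns, p)
  colnames(Y) <- sprintf("item_%02d", seq_len(p))
  rownames(Y) <- sprintf("sub-%03d", seq_len(ns))
  g <- as.integer(drop(z %*% w) > 0)
  networkLabels <- rep_len(spec@networks, nr)

  new("SyntheticCohort", series = series, latents = z, behaviors = Y,
      group = g, networkLabels = networkLabels, spec = spec,
      truth = list(a = a, ratio = ratio, f = f, delta = delta,
                   phi0 = phi0, C = C, w = w))
}

#' Planted latent-behaviour canonical correlation
#'
#' Population first canonical correlation between the latent vector z and
#' the behaviours Y = Cz + eta implied by a cohort's planted loading matrix
#' and noise level: the square root of the largest eigenvalue of
#' \eqn{C^\top (CC^\top + \sigma^2 I)^{-1} C} (z has identity covariance).
#'
#' @param cohort a [SyntheticCohort-class].
#' @return the planted population canonical correlation, a scalar in [0,1].
#' @export
plantedCanonicalCorrelation <- function(cohort) {
  C <- cohort@truth$C
  s2 <- cohort@spec@behaviorNoiseSd^2
  M <- t(C) %*% solve(C %*% t(C) + s2 * diag(nrow(C))) %*% C
  sqrt(max(eigen(M, symmetric = TRUE, only.values = TRUE)$values))
}

#' Point-cloud fixtures
#'
#' \code{fixtureSquare} returns the four vertices of the unit square, whose
#' Rips homology is known in closed form: H0 finite deaths \{1, 1, 1\} and
#' a single H1 bar (1, sqrt(2)) — the 4-cycle is born when the unit-length
#' sides enter and dies when the diagonals complete the filling triangles.
#' \code{fixtureCircle} samples n points at uniform angles on a circle with
#' i.i.d. Gaussian coordinate noise.
#'
#' @return a numeric matrix of points (rows) in 2-D.
#' @export
fixtureSquare <- function() {
  matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
}

#' @rdname fixtureSquare
#' @param n number of points (>= 8).
#' @param radius circle radius.
#' @param noiseSd sd of the Gaussian coordinate noise.
#' @param seed RNG seed.
#' @export
fixtureCircle <- function(n = 60L, radius = 1, noiseSd = 0, seed = 1L) {
  if (n < 8L) stop("fixtureCircle needs n >= 8")
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  cbind(radius * cos(th), radius * sin(th)) +
    matrix(rnorm(2L * n, 0, noiseSd), n, 2L)
}
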