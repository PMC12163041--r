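---
title: "Topological signatures of brain dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological signatures of brain dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topobrain)
```

## The problem

Resting-state fMRI yields one noisy time series per brain parcel (ROI).
`topobrain` asks whether the *geometry* of each ROI's reconstructed
dynamics — rather than its conventional statistics — carries stable,
individual-specific information, and whether that information relates to
behaviour. The pipeline is: delay embedding of each ROI series into a
point cloud, Vietoris–Rips persistent homology of that cloud in
dimensions 0 (connected components) and 1 (loops), persistence-landscape
vectorisation on a shared grid, and then population-level analyses:
cross-session fingerprinting, group classification, behavioural
regression, and a permutation-tested CCA mode linking features to
behaviour.

Real multi-subject fMRI is access-restricted, so the package ships a
seeded synthetic cohort generator that plants the structure the analyses
are meant to detect. Every downstream claim the test suite makes is a
claim about recovery of that planted structure, not about the brain.

## Delay embedding

A scalar series $x_1,\dots,x_T$ is mapped to the cloud whose $i$-th
point is $(x_i, x_{i+\tau}, \dots, x_{i+(m-1)\tau})$, giving
$n = T-(m-1)\tau$ points in $\mathbb{R}^m$. One global $(\tau, m)$ pair
is used for an entire dataset: feature vectors are only comparable
across subjects if every cloud lives in the same embedding geometry.
The pair is chosen on a subsample of series and aggregated by the median
rounded up.

* $\tau$ — first local minimum of the mutual information between
  $x_t$ and $x_{t+\tau}$ (equal-width 16-bin 2-D histogram, nats). The
  raw histogram profile wobbles by a few hundredths of a nat from
  bin-edge effects, so the local-minimum rule is applied to a 5-point
  moving average of the profile; a profile whose total range is below
  0.05 nats (the estimator's noise floor) is treated as unstructured and
  flagged, returning the global minimum.
* $m$ — smallest dimension whose false-nearest-neighbour fraction drops
  below 2%, with Kennel's published tolerances ($r_{tol}=15$,
  $a_{tol}=2$). Points that revisit the trajectory within numerical
  rounding are excluded from the count: their distance ratio is noise.

An optional zero-phase 4th-order Butterworth bandpass (default
0.01–0.08 Hz, the conventional resting-state band) is applied
forward–backward with odd-reflection padding of the full series length,
which bounds the filter's edge transients. The synthetic generator
already produces band-limited signals, so the pipeline leaves the filter
off by default.

## Vietoris–Rips persistence

A simplex enters the filtration at its diameter (longest pairwise
distance); ties are broken lexicographically so results are independent
of point order. H0 is computed by Kruskal union–find: the finite deaths
are exactly the minimum-spanning-tree edge weights, and the essential
component is kept as a bar capped at the filtration limit, so an
$n$-point cloud always contributes $n$ bars. H1 comes from GF(2)
reduction of the triangle boundary matrix in filtration order, with a
dense bit-set working column and an apparent-pair fast path;
zero-persistence bars are discarded and unfilled loops are capped at the
filtration limit.

Two performance choices matter at cohort scale and change nothing
mathematically:

* The filtration is capped at the cloud's *enclosing radius*
  $\min_i \max_j d_{ij}$. Beyond that radius the complex is a cone over
  the minimising vertex, so H1 is already settled; the cap only changes
  the value at which the essential H0 bar is truncated, and that value
  is recorded in each diagram.
* Embedded clouds are reduced to 50 maxmin (farthest-point) landmarks
  before persistence in the cohort pipeline (`landmarkSubsample()`
  itself defaults to 300, and subsampling is off for clouds that are
  already small). Landmarks preserve the dominant loop structure while
  keeping the full multi-seed analyses at desk scale; the landmark count
  and seed are part of the recorded configuration.

## Persistence landscapes

Each diagram point $(b, d)$ becomes the tent
$\Lambda(t)=\max(0, \min(t-b, d-t))$, and layer $k$ of the landscape is
the $k$-th largest tent value at each grid point. The package samples
$k=5$ layers at 20 grid points (100 values per diagram, configurable,
$1\times100$ available), on one uniform grid per homology dimension
spanning $[0, \max \text{death}]$ over the whole collection. The grid is
part of the feature-set metadata and must be reused verbatim for
held-out data. With 200 ROIs and both dimensions the subject vector has
$200 \times 100 \times 2 = 40000$ entries; the desk-scale default
(20 ROIs) gives 4000.

The temporal baseline is a fixed panel of 22 conventional time-series
statistics — autocorrelation lags and decay points, periodogram shape,
distributional moments, level-crossing and run statistics, Hjorth
parameters, sample entropy, a segment-variance stationarity ratio —
plus the series mean and population standard deviation appended last,
24 values per ROI. Non-finite values are imputed with the cohort median
per feature. The panel is deliberately dominated by scale-free
statistics, mirroring how canonical time-series feature sets operate on
z-scored inputs.

## The synthetic cohort

Each ROI of each subject oscillates as

$$x(t) = a\,[\sin(2\pi f t + \phi) + \rho \sin(4\pi f t + \psi)] +
\varepsilon(t), \qquad \varepsilon \sim N(0, (\sigma a)^2),$$

with two sessions per subject that share all subject-level parameters
and differ only in phase jitter and noise. A $q=5$-dimensional latent
$z_i$ drives everything: the amplitude $a = \exp(0.35\,\alpha\,
z\!\cdot\!u_r)$ (the dominant carrier of individuality — a stable
spatial pattern of oscillation scale), the harmonic ratio
$\rho = 0.4 + 0.05\tanh(\alpha z\!\cdot\!v_r)$ and the relative
harmonic phase $\delta = \psi - 2\phi = \delta_r + 0.2\tanh(\alpha
z\!\cdot\!w_r)$ (milder loop-shape individuality). Frequencies sit on a
fixed per-ROI grid inside 0.01–0.08 Hz. Behaviours are $Y = Cz + \eta$
with unit-norm rows of $C$, and the binary group label is
$\mathbf{1}\{w\!\cdot\!z > 0\}$.

Two structural choices deserve explanation:

* **Noise is proportional to amplitude.** With a fixed absolute noise
  level, the signal-to-noise ratio itself becomes a second readout of
  the amplitude pattern, and every variance-ratio statistic (lag-1
  autocorrelation, sample entropy, spectral entropy, ...) reads the
  planted identity directly. Scaling the noise with $a$ makes all
  scale-free statistics distribution-matched across subjects, so
  individuality genuinely lives in the geometry (scale and shape) of the
  embedded trajectory — which is the regime the topological features
  claim to exploit, and the regime in which the comparison between the
  two feature families is informative rather than foregone.
* **Relative phase, not absolute phase, is a trait.** $\psi$ tracks
  $2\phi + \delta$, so both sessions trace the same closed curve from a
  different time origin; $\delta$ reshapes the loop without changing the
  power spectrum.

Default study conditions: 50 subjects, 20 ROIs, 300 timepoints at
TR = 0.72 s, $\sigma = 0.3$ (in amplitude units), phase jitter 0.3 rad,
12 behavioural items with noise sd 2.1 — calibrated in closed form
(`plantedCanonicalCorrelation()`) so the planted latent–behaviour
canonical correlation is approximately 0.7. These defaults are the
study conditions of the whole test suite and are not tuned per test.

What the generator does *not* emulate: haemodynamics, spatially
correlated or temporally autocorrelated noise, scanner drift,
non-stationary dynamics, family structure. Passing tests therefore show
that the pipeline recovers planted geometric individuality under
session-level perturbation — not that real fMRI behaves this way.

## Fingerprinting

Session-1 vectors form the database, session-2 vectors the targets;
target $i$ is assigned to the database subject with the highest Pearson
correlation, and accuracy is the fraction of self-matches. Features are
used as-is (Pearson is affine-invariant per vector pair); argmax ties
are broken toward the smallest index and flagged; a constant vector's
undefined correlations are treated as $-\infty$ similarity. Per-network
fingerprinting subsets feature columns by the ROI→network map (seven
Yeo-style names assigned round-robin in the generator).

## CCA and contributions

Features and behaviours are z-scored, reduced by PCA, and the first
canonical correlation $r_1$ between the two score matrices is computed
via QR orthonormalisation and an SVD. Significance comes from freely
permuting behaviour rows (synthetic subjects are exchangeable; no family
blocks) with $p = (1 + \#\{r_{perm} \ge r_1\})/(1 + n_{perm})$, so the
smallest attainable $p$ is $1/(n_{perm}+1)$ — $10^{-4}$ at 10,000
permutations. Because a row permutation of a centred matrix permutes its
orthonormal basis identically, each permuted $r_1$ is the top singular
value of a small crossproduct; the full null costs milliseconds.

Interpretation uses structure correlations (loadings) rather than raw
weights; both are exposed. Per-ROI contributions take the first PC of
each ROI's landscape block (sign-aligned to correlate positively with
the block's row mean — PCA signs are otherwise arbitrary), correlate it
with the canonical feature variate, aggregate per network, and compare
|H0| vs |H1| contributions per network with a two-sample t statistic.

CCA recovery is evaluated on a 150-subject, 10-ROI cohort rather than
the 50-subject fingerprinting cohort: a permutation test of a first
canonical mode read through noisy features simply does not have
$p \le 0.01$ power at $n = 50$, and the study the package emulates used
four figures more subjects than components. The null calibration
(independent Gaussian blocks, $n = 200$, 20 PCs) is checked separately.

## Supervised harnesses

Group classification: ridge-penalised logistic regression (penalty
strength fixed at 1, intercept included) on PCA scores, stratified
5-fold cross-validation, out-of-fold probabilities pooled into one ROC.
Behavioural regression: linear model on PCA scores, 5-fold
cross-validation repeated 10 times, one Pearson $r$ of pooled
out-of-fold predictions per repeat, compared across feature sets with a
paired t-test on repeats that share fold splits. In both harnesses the
z-scoring and PCA are fitted inside each training fold and applied to
the held-out fold; fitting them once globally would leak held-out
statistics into training, so the reduction-first reading of the
procedure is deliberately not implemented. Classification uses
session-1 features with 10 PCs at desk scale (the fold-training sets
have 40 subjects; more components mostly add noise directions).

Note one pooling artifact worth knowing about: with strong separation
but per-fold recalibration, pooled out-of-fold probabilities can order
imperfectly across folds even when every fold separates perfectly, so
pooled AUC slightly below 1 on separable data is not a bug.

## Numerical conventions and degenerate inputs

* Population (divide-by-$n$) standard deviation throughout the temporal
  panel; documented positions 23–24 for mean and sd.
* Constant series: degenerate-input errors in the embedding selectors;
  flagged all-zero conventions in the temporal panel; $-\infty$
  similarity in fingerprinting.
* Zero-persistence H1 bars are discarded; duplicate points yield
  death-0 H0 bars and are allowed.
* Ties in filtration values are broken lexicographically; argmax ties
  toward the smallest index, flagged.
* A paired comparison with zero-variance nonzero differences reports
  infinite $t$ with $p = 0$ and a degenerate flag.
* All randomness flows from explicit seeds; a master seed derives
  per-stage seeds by a fixed documented rule (`deriveSeed()`), and
  identical configurations reproduce results bit for bit.

## Problem sizes used by the test suite

The suite runs the full pipeline on twenty seeded default cohorts
(50 subjects × 2 sessions × 20 ROIs, 300 timepoints), one 150-subject
CCA cohort, 100-replicate null calibrations for CCA and classification,
1000 paired-t null simulations, 100 random clouds against the
minimum-spanning-tree oracle and 50 against an independent full
boundary-matrix reduction. These sizes were chosen as the smallest at
which the planted effects and calibrations are stable; the acceptance
script (`scripts/acceptance.R`) recomputes the same quantities from
scratch at the same sizes.

## Known limitations

* H2 and higher homology, witness/sparse complexes beyond maxmin
  landmarks, and persistence images or other vectorisations are out of
  scope.
* The landscape grid is global per dataset; mixing feature sets built on
  different grids is an error the metadata is meant to catch.
* The generator's oscillators are a sufficient mechanism for
  identifiability, not a model of brain dynamics; which dynamical
  property makes real individuals identifiable is an open question the
  package does not answer.
* Family-structure-aware permutation schemes are not implemented;
  synthetic subjects are exchangeable by construction.
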