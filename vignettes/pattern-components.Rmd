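---
title: "Pattern-component models: methods and design choices"
author: "patternComp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-component models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patternComp)
```

## The model

Multivariate fMRI analyses frequently summarise a region by the correlations
between the mean activity patterns evoked by different conditions
(representational similarity analysis). Sample correlations, however, are
attenuated by measurement noise, inflated by nonspecific activation shared
across conditions, and diluted by uninformative voxels — all of which differ
between regions — so they cannot be compared across regions or participants.

`patternComp` treats the measured trial-by-voxel matrix $Y$ ($N \times P$)
as a linear combination of $Q$ hidden pattern components plus noise,

$$Y = Z U + E, \qquad \varepsilon^c_p \sim N(0, I\sigma^2_\varepsilon),$$

where $Z$ ($N \times Q$) maps trials onto components and the rows of $U$
($Q \times P$) are the component patterns. The decisive step is to model the
components as *random over voxels*: the columns of $U$ are i.i.d.
$N(\mathbf a, G)$. After removing the means ($\mathbf a = Z^{+}\,
\overline{\mathbf y}$, where $\overline{\mathbf y}$ is the voxel-averaged
trial vector), each voxel column of $Y$ is $N(\mathbf 0, V)$ with

$$V = Z G Z^{\mathsf T} + I\sigma^2_\varepsilon .$$

The $Q \times Q$ matrix $G$ carries all the quantities of interest: its
diagonal is the strength ("energy") of each component over voxels, its
off-diagonal entries the similarity between components. The corrected
correlation

$$\rho_{ij} = \gamma_{ij} / (\sigma_i \sigma_j)$$

computed from an estimate of $G$ refers to the *hidden* components, and is
therefore invariant to the noise level, to a shared activation pattern
(when the model contains a common component), and to the proportion of
uninformative voxels — the three contaminants that make raw sample
correlations incomparable.

Given $\hat G$ and $\hat\sigma^2_\varepsilon$, the hidden patterns
themselves are recovered by the best linear unbiased predictor
$\hat U = G Z^{\mathsf T} V^{-1} Y$, which underlies the spatial analyses
below.

## Constraining G through a factored basis expansion

Structural hypotheses (equal variances across levels, selected zero
covariances, a common component uncorrelated with everything else) are
linear constraints on $G$ — but a constrained $G$ must stay positive
semi-definite. The package therefore parameterises the square-root factor,

$$G = A A^{\mathsf T}, \qquad A(\theta) = \sum_{h=1}^{H} \theta_h B_h,$$

with a fixed catalogue of basis matrices $B_h$ per design. PSD-ness holds
for every $\theta$, and the complete-data problem becomes linear in
$\theta$. Three builders cover the supported designs:

* `buildOneFactorial(K, n)` — unconstrained $G$ via a full lower-triangular
  $A$ ($H = K(K+1)/2$). The sign indeterminacy of $A$ is irrelevant because
  only $G$ is reported; the lower-triangular form is the canonical
  Cholesky-like representative.
* `buildCommonPattern(K, n, controlTrials, anchorPairs)` — adds a component
  loaded by every trial, constrained uncorrelated with the stimulus
  components (first row/column of $G$ zero off the diagonal). Its variance
  is identified by control trials, or — without a control condition — by
  anchoring one or more stimulus pairs at zero covariance (each anchor
  removes one off-diagonal basis matrix; with the triangular factor the
  structural zero is exact for leading pairs).
* `buildFactorial(C, L, n, nRuns)` — per-condition common components with
  free covariance $\gamma_\alpha$; per-cell level components with variances
  equal across levels within a condition and covariance $\gamma_\beta$ only
  between matching levels (encoded by per-level triangular factors with
  parameters shared across levels); optionally per-run components with the
  analogous structure, uncorrelated across runs, absorbing correlated
  estimation error within an imaging run.

## Estimation

`emFit` maximises the marginal likelihood of the mean-removed data by EM on
the reparameterisation $y_p = Z A w_p + \varepsilon_p$,
$w_p \sim N(0, I_Q)$:

* **E-step.** $\Sigma_w = (A^{\mathsf T} Z^{\mathsf T} Z A /
  \sigma^2_\varepsilon + I)^{-1}$ and $\hat W = \Sigma_w A^{\mathsf T}
  Z^{\mathsf T} Y / \sigma^2_\varepsilon$. All moments reduce to $Q$-
  dimensional matrices built from $Z^{\mathsf T} Y\,(Z^{\mathsf T}
  Y)^{\mathsf T}$, so the per-iteration cost does not grow with $P$.
* **M-step.** The expected complete-data objective is an exact quadratic in
  $\theta$; the update solves an $H \times H$ linear system, after which
  $\sigma^2_\varepsilon$ has a closed-form update. Because both updates
  jointly maximise the same quadratic, the marginal log-likelihood is
  non-decreasing — this is asserted on every fit.

Numerical choices:

* Initialisation is a method-of-moments estimate: $\hat G_0$ from the
  pseudo-inverse pattern estimates with a noise-leakage correction,
  projected onto the PSD cone and then onto the basis span by least
  squares; $\sigma^2_{\varepsilon,0}$ from the OLS residual variance. If
  the projection collapses to zero (an EM fixed point), the start is moved
  to a small multiple of the identity.
* Convergence is declared at a relative log-likelihood change below
  `tol = 1e-8` (cap `maxIter = 1000`; the scenario-grid driver uses 2000).
  Looser tolerances were observed to stop while correlation estimates were
  still moving by several hundredths, so the tight default is deliberate.
* $\sigma^2_\varepsilon$ is floored at $10^{-12}$ of the mean data variance
  to keep $V$ invertible.
* Optional restarts perturb the starting $\theta$ multiplicatively with a
  seeded generator; all randomness flows through one explicit seed and
  results are bitwise reproducible given it.
* The likelihood (and BLUP) can be evaluated through a dense
  $N$-dimensional Cholesky or the Woodbury reduction; the two routes agree
  to near machine precision and the tests assert it.

Estimation is maximum likelihood on mean-removed data. ReML would
additionally account for the $Q$ estimated mean coefficients, but the mean
here is a single number per component over $P$ voxels, so the distinction
is negligible at the voxel counts the model targets (hundreds or more).

### Behaviour near the boundary

The corrected correlation is a ratio of estimates. Two finite-sample
effects are worth knowing about, both verified against a multi-start BFGS
oracle (they are properties of the ML optimum, not of the EM):

* At high noise, the ML solution occasionally lands on the PSD boundary
  (rank-deficient $\hat G$), pinning a correlation at $\pm 1$; with a
  strong positive correlation elsewhere in $G$, weakly identified pairs
  pile preferentially at $-1$. Averaged over replicates this drags the
  mean of near-zero correlations a few hundredths negative in the
  common-activation design at $\sigma^2_\varepsilon \ge 5$.
* When a component's variance is small relative to noise (for instance,
  when 75% of voxels carry no level-specific signal and only ~25
  informative voxels remain at $P = 100$), the ratio becomes skewed and
  its mean overshoots; the effect disappears with more voxels (at
  $P = 500$ the mean is on target). `correctedCorrelations` flags
  components whose variance falls below a relative floor (default
  $10^{-6}$) and returns their correlations as NA rather than clipping;
  users should prefer a simpler model when a region does not express a
  component.

## Spatial structure

Voxels are not spatially independent. The generative extension gives each
component block $j$ its own squared-exponential autocorrelation,
$\mathrm{corr}(u_{x}, u_{x+\delta}) = \exp(-\delta^2 / 2 s_j^2)$, with the
separable covariance $G_j \otimes \Sigma_j$ per block and
$I_N \otimes \Sigma_\varepsilon$ for the noise. Inverting the full
Kronecker model is out of scope; instead the package implements the
approximate two-step procedure:

1. fit the component model ignoring spatial structure (the simulations
   below confirm that spatial smoothness leaves $\hat G$ essentially
   stable for kernels narrower than the region);
2. compute the pooled spatial autocorrelation of the BLUP rows of each
   block in distance bins, and fit the squared-exponential kernel SD $s$
   by weighted least squares.

The kernel SD is reported together with the width of the Gaussian
smoothing kernel that would induce it on white noise (kernel SD
$s/\sqrt 2$), $\mathrm{FWHM} = 2\sqrt{\ln 2}\, s$ — e.g. $s = 2$ voxels
corresponds to a FWHM of 3.33 voxels.

Estimator details, each the package's own choice where more than one
reasonable variant exists:

* Distance bins default to lattice-adapted edges (nearest neighbours,
  diagonal neighbours, then unit-width bins); the abscissa used in fitting
  is each bin's *mean pair distance*, which removes most within-bin
  curvature bias. Bins are fully user-configurable.
* Pooling weights every voxel pair equally, and rows are scaled to unit
  RMS but **not** mean-centred: the component patterns and residuals are
  zero-mean over voxels by model construction, and subtracting the sample
  mean of a smooth field over a small region (the default sphere has a
  7-voxel diameter) would bias the autocorrelation down by the field's
  average pairwise correlation — enough to halve the recovered $s$ at
  $s = 2$. A `center = TRUE` option exists for patterns with appreciable
  means.
* The noise autocorrelation is computed from the OLS residuals
  $(I - Z Z^{+}) Y$, not the BLUP residuals $Y - Z\hat U$: OLS residuals
  are pure linear combinations of noise rows and carry no leakage from the
  smooth signal components, whereas BLUP residuals contain shrinkage
  leftovers that inflate the noise kernel estimate when the true noise is
  spatially independent.
* Kernel fitting minimises the weighted squared error on the raw
  autocorrelation values (not their logs), tolerating negative sample
  values; the search is a deterministic bounded scalar minimisation on
  $[0, \max \delta]$, with degenerate inputs flagged (`all-negative`
  yields $s = 0$; an all-ones ACF pins $s$ at the upper bound).
* Known limitation (shared with the approximate procedure as such): the
  kernel estimate for a *weak* component block is biased toward the
  kernels of the stronger components mixed into its BLUP rows, and toward
  the noise kernel; the simulations assert only its ordering in the true
  value. On small regions the recovered $s$ also remains somewhat
  attenuated when the FWHM approaches the region radius.

## Synthetic data

The generators draw component patterns block by block — a unit-variance
(optionally spatially autocorrelated) Gaussian field coloured by the
square root of that block's sub-matrix of $G$, valid because cross-block
covariances are structurally zero and the spatial model is separable —
then add i.i.d. or spatially coloured Gaussian noise. Uninformative voxels
are created by zeroing the level-block components at a fraction of voxels.
Every draw is reproducible from a single seed, and the squared-exponential
Cholesky factors are cached per (coordinates, $s$).

Five turnkey scenarios reproduce the supported simulation studies; their
defaults are the study conditions and are not tuning knobs:

| scenario | design | fixed truth |
|---|---|---|
| `scenarioOneFactorial` | 3 conditions, $n=5$, $P=100$ | $\sigma_i^2 = 1$, $\rho = (0, -0.2, 0.8)$ |
| `scenarioCommonActivation` | + common component, 5 control trials | $\sigma_c^2 = 4$ |
| `scenarioTwoFactorial` | $2 \times 4$, $n=5$/cell, $P=100$ | $\sigma_\alpha^2 = 2$, $\sigma_\beta^2 = 1$, $\gamma_\beta = 0.5$ |
| `scenarioVoxelSelection` | as above, $\gamma_\alpha = 0$, $\sigma^2_\varepsilon = 4$ | fraction of voxels uninformative |
| `scenarioSpatial` | lattice sphere radius 3.5 (179 voxels) | $\sigma^2_\varepsilon = 3$, $\sigma_\alpha^2 = \sigma_\beta^2 = 1$, $\gamma_\alpha = 0.3$, $\gamma_\beta = 0.5$, $s_\alpha = 1$ |

$n = 5$ trials per cell and $P = 100$ voxels are used for the factorial
scenarios as well as the one-factorial one; these are typical values for
event-related designs with anatomically defined regions. The lattice
sphere of radius 3.5 enumerates to 179 voxels.

What the generators emulate is exactly what the model assumes: Gaussian
components, i.i.d. trials, homogeneous (or two-class) voxel populations,
separable spatial structure. Real fMRI data violate several of these —
heavy-tailed noise, temporally autocorrelated estimation error beyond the
run effect, non-Gaussian spatial profiles — so passing simulations
demonstrate correctness of the machinery and the invariances it claims,
not robustness to every property of real data. First-level time-series
modelling (HRF, drift) is out of scope: the model consumes trial-level
summary statistics.

## Worked example

```{r example}
sim <- scenarioOneFactorial(noiseVar = 5, seed = 7)
fit <- emFit(sim$data, sim$truth@model)
fit
correctedCorrelations(fit)
sampleCorrMeanPatterns(sim$data)[1, 3]
expectedSampleCorr(-0.2, 1, 1, 5, 5)
```

Even at a noise variance five times the component variance, the corrected
correlations sit near the generating values $(0, -0.2, 0.8)$ for a single
simulated region, while the sample correlation between mean patterns is
attenuated exactly as the closed form predicts.

The simulation studies themselves are driven by `runScenarioGrid`, which
simulates, fits and summarises all estimators over a parameter grid with
deterministic per-replicate seeds; `scripts/acceptance.R` runs the full
set (500 replicates per grid point for the non-spatial studies, 100 for
the spatial one — a few minutes on one CPU) and writes the headline
numbers as JSON.

## Interfaces

Datasets travel as TSV (data matrix, trial metadata, voxel coordinates),
models and fits as JSON (`readComponentModel`, `writeFit`); a thin
command-line wrapper over these functions lives at
`inst/cli/patterncomp.R` with `simulate`, `fit`, `similarity`, `spatial`
and `grid` subcommands. All outputs are written atomically and carry
provenance headers (tool version, scenario, seed). Volume formats (NIfTI)
are deliberately not consumed: the model operates on extracted
trial-by-voxel matrices, and an extraction adapter is a separate concern.

Parametric (continuous) trial regressors are accepted by the types but no
builder constructs them; Euclidean or Mahalanobis pattern distances and
model comparison by marginal likelihood are out of scope.
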