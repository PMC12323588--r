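---
title: "Methods: functional-data distances for longitudinal microbiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional-data distances for longitudinal microbiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lordist)
```

## The problem

Longitudinal microbiome studies sample the same subjects repeatedly over
time, often sparsely and on subject-specific schedules. Most
beta-diversity machinery compares *samples*; it has no natural way to
compare *subjects* through their whole temporal trajectory. This package
treats each subject-feature abundance series as noisy observations of a
smooth function of time and compares subjects by how their functions
differ, producing a subject-by-subject distance matrix that feeds the
usual downstream tools (PCoA ordination, PERMANOVA).

## The model

For subject $i$ and microbial feature $j$, observed abundances
$x_{ij}(t_{ijk})$ at times $t_{ijk} \in [0, T]$ are represented as

$$\hat{x}_{ij}(t) = \sum_{l=1}^{K} c_{ijl}\,\phi_l(t),$$

where $\phi_l$ are Fourier harmonics or cubic B-splines and the
coefficients minimize the penalized least-squares criterion
$\lVert x - \Phi c\rVert^2 + \lambda\, c^\top R\, c$ with $R$ the
order-2 roughness (curvature) penalty matrix.

Per feature, functional PCA across subjects decomposes the smoothed
curves as

$$\hat{x}_{ij}(t) \approx \mu_j(t) + \sum_{r=1}^{R} \xi_{ijr}\,\psi_{jr}(t),$$

with orthonormal eigenfunctions $\psi_{jr}$, eigenvalues
$\lambda_{jr}$ (the score variances) and subject scores $\xi_{ijr}$.
Subjects are compared per feature by the eigenvalue-weighted score
distance

$$d_j(S_i, S_{i'}) = \Big(\sum_{r=1}^{R} \lambda_{jr}\,
  (\xi_{ijr} - \xi_{i'jr})^2\Big)^{1/2},$$

and feature distances are aggregated by root-sum-of-squares,

$$D(S_i, S_{i'}) = \Big(\sum_{j=1}^{m} d_j(S_i, S_{i'})^2\Big)^{1/2}.$$

Because each $d_j$ is a Euclidean distance in a $\sqrt{\lambda}$-scaled
score space and the aggregation is itself Euclidean, $D$ is a Euclidean
distance matrix: all PCoA eigenvalues are nonnegative up to numerical
noise, and no Cailliez/Lingoes correction is ever needed for matrices
produced here.

Assumptions worth stating plainly: trajectories are smooth enough to be
captured by a handful of basis functions; all subjects share the domain
$[0, T]$ (taken as the maximum observed time); a recorded zero is an
observation, and a feature absent from a sample is a zero, not a
missing value; every feature contributes to $D$ on equal footing.

## Tunable parameters

* **Basis family** (`basis_family`, default `fourier`). Fourier suits
  trajectories without boundary trends and is the default; B-splines
  (`bspline`, cubic, clamped uniform knots) localize better. Note that
  the Fourier system is periodic with period $T$: $t = 0$ and $t = T$
  are the same design point, which matters only for unpenalized
  ($\lambda = 0$) saturated fits.
* **Number of basis functions** (`n_basis`, default `"auto"`): $K$
  equals the subject's number of time points, balancing flexibility
  against overfitting. Fourier systems come as a constant plus
  sine/cosine pairs, so an even request is rounded down to the nearest
  odd value; B-spline counts are raised to the spline order (4) when
  below it. $K$ is additionally clamped to the subject's observation
  count so the design never becomes rank-deficient.
* **Smoothing penalty** (`lambda`, default `1e-8`). The default is
  near-interpolating but numerically stabilized; it keeps runs
  deterministic. `lambda = "gcv"` selects the penalty by generalized
  cross-validation over a log grid $10^{-8} \ldots 10^{2}$ and is
  offered for noisy, densely sampled data.
* **FPCA grid** (`grid_size`, default 101 equally spaced points).
  Integrals (inner products, covariance weighting) use the trapezoid
  rule on this grid.
* **Components retained** (`n_components`, default `"auto"`): the
  smallest $R$ whose cumulative variance explained reaches
  `var_threshold` (default 0.95), with minimum 1, applied
  feature-by-feature. A fixed integer may be supplied instead.
* **PERMANOVA permutations** (`n_perm`, default 999) and `seed`. With
  the +1 convention the smallest attainable p-value is
  $1/(n_\mathrm{perm}+1) = 0.001$.

## The synthetic benchmark

`simulate_dataset()` draws a case/control cohort (defaults: 50 + 50
subjects, 10 time points on $[0, 10]$, 200 features). Each feature is
assigned uniformly to one of three taxon archetypes:

1. constant, high abundance, identical in both groups:
   $x(t) = 10 + \varepsilon_1$, $\varepsilon_1 \sim N(0, 3)$;
2. periodic, medium abundance; controls follow
   $10(\sin(\pi t + \pi/2) + 10) + \varepsilon_2$ and cases add a
   sigmoid offset and a larger swing,
   $10\!\left(\frac{\pi}{1+e^{-t}} + 4\sin(\pi t + \pi/2) + 10\right)
   + \varepsilon_2$, $\varepsilon_2 \sim N(0, 5)$;
3. low abundance; controls flat at $30 + \varepsilon_3$, cases rising
   along $40\!\left(\frac{1}{1+e^{-(t-5)}} + 0.25\right) +
   \varepsilon_3$, $\varepsilon_3 \sim N(0, 9)$.

$N(0, v)$ is read as variance $v$. Negative draws are floored at 0,
since abundances cannot be negative. The taxon-2 case formula is
implemented exactly as written above (`taxon2_variant = "literal"`); an
alternative reading in which the sigmoid multiplies the oscillation so
that the swing grows over time is available as
`taxon2_variant = "amplitude"`, because the additive form keeps the
amplitude constant while the archetype is described as having a growing
range. The literal form is the default.

Sparsity is injected by setting exactly `round(fraction * N)` of the
$N$ observation values to zero, drawn uniformly without replacement —
an exact count rather than independent Bernoulli thinning, so every
replicate carries precisely the nominal sparsity. The records remain in
the table: zeros are observations and enter the smoothing step.

Time grids are either *aligned* (all subjects share the evenly spaced
grid) or *misaligned*: each subject receives one uniform draw per
equal-width band of the domain (so 10 points means one observation in
each unit interval), which mimics cohort schedules where visits happen
roughly monthly but on different days; fully i.i.d. uniform times are
available via `misaligned_sampling = "uniform"`.

What the generator does **not** emulate: sequencing-depth variation and
count compositionality (values are Gaussian around archetype means, not
reads), overdispersed count noise, correlation between features, and
subject-level random effects. Passing the benchmark therefore shows
that the pipeline separates groups whose *temporal dynamics* differ
under sparsity and irregular sampling; it does not certify behavior
under compositional artifacts or depth confounding on real sequencing
data. Also note the archetype group differences are large relative to
their noise scales, so the benchmark's power is high; with 100 subjects
the permutation test stays at its floor even when a large majority of
values are zeroed, and the pseudo-F statistic — not the p-value — is
the informative dial along the sparsity axis.

## Numerical choices

* All integrals use the trapezoid rule (1001 points for penalty
  matrices, the FPCA grid elsewhere): deterministic and accurate to
  roughly $10^{-8}$ for the smooth integrands involved.
* The FPCA eigenproblem is solved on the quadrature-weighted grid
  covariance (sample covariance, denominator $n-1$, so eigenvalues are
  score variances); when subjects are fewer than grid points the
  equivalent $n \times n$ Gram eigenproblem is solved instead.
  Eigenvalues in $[-10^{-10}\max(1, \lambda_{\max}), 0)$ — symmetric
  eigensolver noise, which scales with $\lambda_{\max}$ — are clipped
  to 0; anything more negative raises an internal-consistency error.
* Eigenfunction signs are fixed deterministically: each is flipped so
  its integral is nonnegative, with the first grid value breaking
  exact-zero ties.
* A feature with zero variance across subjects (for example all-zero
  after sparsification) yields a valid decomposition with
  $\lambda = 0$ and zero scores, contributing nothing to distances —
  not an error.
* PCoA reports negative eigenvalues rather than correcting them;
  coordinate axes whose eigenvalues are at numerical zero (below
  $10^{-9}\lambda_{\max}$) are zero-filled.
* PERMANOVA permutes labels uniformly at random, counts the observed
  labeling once in numerator and denominator, and compares
  $F^* \ge F_\mathrm{obs}$ with exact float comparison (ties are
  measure-zero for continuous data). With the within-group sum of
  squares exactly 0, $F = +\infty$ is reported and the p-value still
  comes from the permutation distribution.
* The whole distance pipeline is deterministic given the input and
  configuration; randomness exists only in the generator and the
  permutation test, each governed by an explicit seed (replicate $r$ of
  a study uses seed $\mathrm{base} + r$ for both).

## Preprocessing filters

For count tables the package applies, in order: total-sum scaling
(`tss_normalize`), the prevalence/abundance filter
(`filter_low_abundance_features`), and the three-time-point rule
(`require_min_timepoints`). The prevalence rule removes a feature whose
relative abundance is below 0.01% in strictly more than 90% of samples,
where a sample is a (subject, time) pair and absence counts as zero;
this is the standard prevalence/abundance filter, with "strictly more
than" chosen so that a feature rare in exactly 90% of samples survives.
`filter_low_count_features` (total count < 5 across all observations)
serves count-based analyses. All filters are idempotent.

## Problem sizes used by the shipped checks

The test suite exercises the full pipeline on reduced cohorts (6–12
subjects, 4–10 features) where closed-form and brute-force oracles are
feasible, plus full-size (100 × 200) replicate runs: 20 replicates at
50% sparsity for the power floor, a 10-configuration basis sweep at
zero sparsity, and a 17-replicates-per-level sparsity ordering check.
The acceptance script runs 20 replicates at 50% sparsity and 150
replicates each at 60% and 70%, all with 999 permutations. These sizes
are the package's own choice of a thorough-but-quick default; the
generator and pipeline scale to larger replicate counts unchanged.

## Known limitations

* At least three distinct time points per subject are required;
  subjects below that are dropped, not imputed.
* All features are weighted equally in the aggregation (an optional
  user weight vector exists but defaults to 1); abundant, volatile
  features dominate $D$ because scaling one feature's values by $c$
  scales its $d_j$ by $c^2$.
* Very sparse subjects produce poorly determined curves and can appear
  as ordination outliers.
* FPCA scores are plain quadrature inner products; no
  conditional-expectation (PACE-style) scoring is attempted for
  extremely sparse designs, and the covariance surface is not
  smoothed.
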