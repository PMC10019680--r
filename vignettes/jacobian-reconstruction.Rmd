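---
title: "Reconstructing biochemical Jacobians from metabolite covariance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing biochemical Jacobians from metabolite covariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metarecon)
```

## The model

Near a metabolic steady state, small fluctuations `x` of the metabolite
concentration vector follow, to first order, a linear stochastic
(Ornstein–Uhlenbeck) process

    dx = J x dt + sqrt(2 F) dW,

where `J` is the Jacobian of the reaction-rate system evaluated at the
steady state and `F` a (diagonal, positive) fluctuation intensity. If `J`
is Hurwitz-stable, `x` has a stationary covariance `C` tied to `J` and `F`
by the Lyapunov equation

    J C + C t(J) = -2 F.

Biological replicates of a metabolite panel are, under this model,
independent draws of the stationary distribution, so their sample
covariance estimates `C`. The reconstruction problem is the inverse one:
given `C` (measured) and an assumption on `F`, recover `J`.

`J` alone is not identifiable: it has `n^2` entries, while the symmetric
Lyapunov equation provides only `n(n+1)/2` independent scalar equations.
Identifiability comes from the metabolic network. With the stoichiometric
matrix `N` (metabolites x reactions) and the elasticity matrix
`E = dr/dC` (reactions x metabolites),

    J = N E,

and `E` is sparse: a rate can depend only on the reaction's substrates
(and declared modifiers). The package therefore solves the linear system
in the *free elasticities* — the entries of `E` on that sparsity pattern —
and assembles `J = N E`, which is exactly zero outside the structural
mask. A `mode = "direct"` variant frees the masked Jacobian entries
themselves instead; it is useful for comparison but typically less
determined.

## The Monte-Carlo ensemble

`F` is never measured. The package models it as a diagonal matrix with a
base intensity per metabolite and draws it repeatedly (log-normal
multiplicative jitter, median equal to the base), solving the inverse
problem once per draw: `ensembleInvert()` summarises the resulting stack
of Jacobians by entrywise median and interquartile range (IQR). The
median is the point estimate; the IQR measures how sensitive each entry
is to the fluctuation assumption. One thousand draws is the default.

Two base choices are used in this package:

* *data-driven* (default, `defaultFluctuation()`): base = 10% of the
  observed metabolite variances. On real data nothing better is
  available; the Jacobian scale inherits this assumption (the equation is
  jointly linear, so rescaling `F` rescales `J`).
* *known-truth*: in synthetic benchmarks the generator's true `F` is
  supplied, so that deviations measure estimation error only.

Tunable parameters and defaults: `nDraws` 1000 (Monte-Carlo repeats),
`spread` 0.2 (log-scale jitter of F, dimensionless), `rel` 0.1 (base as a
fraction of metabolite variance), `ridge` 1e-8 (1/time^2; see below).

## Differential Jacobians

Two conditions give two ensembles. For every masked entry the score is

    |median_B - median_A| / max(((iqr_A + iqr_B)/2)^2, epsilon),

the absolute median shift normalised to the square of the pooled
interquartile distance. Squaring the IQR strongly penalises entries whose
estimates wobble with the fluctuation assumption, so the top of the
ranking is occupied by couplings that moved far *and* are stably
estimated. The pooled (mean) IQR keeps the score symmetric in the two
conditions; a per-condition normalisation is available behind
`normalization = "per-condition"`. `epsilon` (default `1e-6` times the
largest pooled IQR) only matters in the degenerate `spread = 0` case,
where every IQR is exactly zero. Ties in the ranking are broken by (row,
column) index, so reports are deterministic.

## Discriminant-metabolite statistics

The companion univariate/multivariate workflow mirrors standard
metabolomics practice:

* **Pareto scaling** (centre, divide by the square root of the standard
  deviation) precedes every latent-variable fit; it damps
  high-abundance dominance without amplifying noise as much as unit
  scaling.
* **PCA** for unsupervised structure; **PLS-DA** (NIPALS, two-class
  response coded -1/+1) and **OPLS-DA** (label-orthogonal components
  removed before a single predictive component) for supervised
  separation. R2X/R2Y are cumulative fit fractions; Q2 is the
  cross-validated counterpart, from stratified 7-fold CV (leave-one-out
  when a class is smaller than the fold count). The CV scheme is a
  convention choice; the commercial software this workflow usually runs
  in does not document its exact variant.
* **VIP scores** from the (O)PLS weights, normalised so that the squared
  scores sum to the number of metabolites (mean VIP ~ 1).
* **Permutation validation** (default 200 label permutations): the model
  is refit on permuted labels; the regression intercepts of permuted
  R2/Q2 against the |correlation| with the true labels must fall below
  the original statistics, and an add-one permutation p-value for Q2 is
  reported.
* **Selection rule**: VIP strictly greater than 1.0 *and* a two-tailed
  two-sample t-test p-value strictly below 0.05, on raw intensities.
  Welch's unequal-variance test is the default — the safer choice for
  the 3–6 replicates per group typical of targeted panels — with the
  pooled test behind a flag. The rule is deliberately uncorrected for
  multiplicity (a Benjamini–Hochberg column is reported alongside).

## The synthetic-data module

`serineNetwork()` encodes the de novo D-serine route (3PG -> 3PHP ->
PSer -> LSer -> DSer via PHGDH, PSAT1, PSPH, SRR, with the NAD/NADH and
Glu/KGA cofactor pairs). The pathway alone cannot support a stable
stationary state: conserved cofactor moieties make `J = N E` structurally
singular. The packaged network therefore closes the system with a
glutamate-dehydrogenase-like recycling reaction (KGA + NADH -> Glu +
NAD), D-serine degradation, first-order NAD and Glu consumption by the
rest of metabolism, and exchange inflows. Two closure choices deserve
mention because they were forced by identifiability, not chemistry
aesthetics: each cofactor needs an elasticity-bearing consumer of its own
(otherwise two elasticity columns share a single support row and the
Jacobian is rank-deficient), and every conserved pool needs a reaction
that changes its total. The GDH step is also what makes the NADH–KGA
Jacobian coupling structurally allowed — the coordinate at which a
serine-pathway lesion surfaces in the differential Jacobian.

`makeGroundTruth()` draws elasticities on the pattern (positive for
substrates, configurably signed and weaker for modifiers, magnitudes
0.5–1.5 in 1/time units) and resamples — with progressively damped
modifier strength — until the Jacobian is Hurwitz-stable; the stationary
covariance then comes from the forward Lyapunov solve. `simulateOU()`
integrates the process by Euler–Maruyama with a guard
`dt * max|eig| < 0.1` (default `dt` sits at 0.08/max|eig|). Replicates
are taken after burn-in at intervals of two slowest-mode relaxation
times by default, so they are nearly independent stationary draws — the
design the covariance estimator assumes; shorter, deliberately
autocorrelated thinning is available for studying that failure mode.
Steady-state offsets of ten stationary standard deviations keep emitted
intensities positive without touching the covariance.

The knockout analogue multiplies one elasticity by a factor
(`perturbCondition()`); the packaged two-condition default damps the
GDH KGA-elasticity to 0.3, the NADH–KGA coupling. `panelNetwork()` pads
the pathway with independent bystander metabolites to a 40-metabolite
screen; `simulateIntensityPanel()` generates simple shifted-mean panels
(baseline abundances spanning one decade, as in per-metabolite
calibrated targeted assays; 15% CV; effects of 2 within-class SD in 3 of
40 metabolites at n = 6 per class by default) for the discriminant
workflow.

What the generator does *not* emulate: nonlinear (saturating) kinetics
away from steady state, missing values, batch or drift structure,
heteroscedastic MS measurement error (a homoscedastic additive term is
available), and a curated 40-metabolite reaction network — the bystander
panel is an explicit stand-in. Green tests on these data therefore
demonstrate correctness of the estimators under the model's own
assumptions, not robustness to everything real data can do.

## Numerical choices

* The forward Lyapunov solver diagonalises `J` (complex eigenbasis),
  solves entrywise, symmetrises, and applies up to three iterative
  refinement sweeps; it refuses to return if the residual Frobenius norm
  exceeds `1e-10 * (1 + ||C||)`. No `n^2 x n^2` system is formed (that
  construction serves as the independent oracle in the tests instead).
* The inverse design uses only the upper triangle of the symmetric
  residual — `n(n+1)/2` equations — to avoid silently double-weighting
  off-diagonal equations.
* Least squares is solved through a Cholesky factorisation of the
  ridge-regularised normal equations (`ridge` default 1e-8, pure
  numerical conditioning; the equations are otherwise used as given), or
  through an SVD minimum-norm solution at `ridge = 0`, which warns when
  the system is rank-deficient. The factorisation is computed once per
  ensemble and reused across draws, since only the fluctuation side
  changes; bootstrap-resampled covariance per draw is available and
  refactors each time.
* Draws whose solve fails are skipped and counted; an ensemble errors if
  fewer than 90% succeed.
* All randomness flows through seeded substreams addressed by draw
  index, so ensembles are bit-reproducible and independent of execution
  order; the global RNG state of the session is never disturbed.

## Benchmark sizes

The shipped checks run the forward-solver comparison on 100 random
systems (n ≤ 6), the exact round trip on 50 random determinate networks
(n ≤ 8), elasticity recovery and the two-condition knockout detection at
1000 replicates and 1000 draws on the 9-metabolite serine network (10
independent seeds for the detection rate), the discriminant calibration
on 200 simulated null panels of 40 metabolites, and permutation
validation with 200 permutations — sizes chosen so the whole suite
completes in a few minutes on one core while leaving the statistical
margins wide.

## Known limitations

* The fluctuation magnitude is an assumption; only the *pattern* of the
  Jacobian, sign structure, and relative magnitudes are robust to
  rescaling it. Absolute 1/time units are only meaningful if `F` is.
* Replicate groups of 3–6, as in typical targeted studies, estimate a
  40 x 40 covariance very noisily; the Monte-carlo IQR quantifies
  sensitivity to the fluctuation assumption, not this sampling error.
  The bootstrap-covariance option addresses the latter.
* Elasticity-mode identifiability depends on the network: patterns in
  which two metabolites' elasticities live on exactly the same reactions
  are structurally confounded (`countFreeParameters()` and the
  under-determined warning surface this).
* Two-class designs only in the discriminant module; multi-class
  questions go through the one-way ANOVA route outside this package.
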