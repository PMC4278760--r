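---
title: "Methods: sandwich-variance GLMs and the in-limbo classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sandwich-variance GLMs and the in-limbo classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A thresholded statistical parametric map divides the brain into voxels that
differ significantly across conditions and voxels that do not. Reading such a
map as "region A is involved, region B is not" is the imager's fallacy: the
comparison between A and B was never tested. A voxel can miss the threshold
because its effect is absent, or merely because its signal is noisier. The
package resolves the ambiguity by adding a third class. Every non-significant
voxel is tested directly against the *least significantly activated voxel*
that survived thresholding (the comparison voxel). Voxels whose contrast is
significantly smaller are labelled **less**; voxels for which this second
test also fails are **in limbo** — they differ neither from baseline nor from
activated tissue, so the measurement is simply inconclusive there.

The pipeline has four steps:

1. fit a mass-univariate GLM and estimate each voxel's contrast, its
   variance, and cross-voxel covariances with a replication-block sandwich
   estimator;
2. threshold the resulting z-map with cluster-extent correction;
3. select the comparison voxel (minimum surviving statistic);
4. test every non-significant voxel against it (a t-test at subject level, a
   weighted-least-squares test across subjects at group level).

## Step 1: contrast, variance, covariance

For voxel $j$ with time series $y_j \in \mathbb{R}^T$ and design
$X \in \mathbb{R}^{T \times p}$ (boxcars convolved with a canonical
double-gamma HRF, peak at 6 s, undershoot at 16 s, unit-peak scaling, plus
nuisance columns), the run is cut into $q$ consecutive *replication blocks*
("subruns") of equal length $L = \lfloor T/q \rfloor$; trailing time points
beyond $qL$ are discarded. The default $q = \lfloor \sqrt{T} \rfloor$. With
block designs $X_i$ and block data $y_{ij}$,

$$\hat\beta_j = \Big(\sum_i X_i'X_i\Big)^{-1} \sum_i X_i' y_{ij},$$

which for identical blocks is exactly the OLS fit of the across-block mean
time course. (Written with the shared mean series, the estimator is only
unbiased when all blocks share one design; the pooled normal equations above
agree with it in that case and remain unbiased when block designs differ,
e.g. when the block length is incommensurate with the task cycle.) Block
residuals $r_{ij} = y_{ij} - X_i\hat\beta_j$ yield the residual covariance

$$\hat\Sigma_j = \frac{1}{q-1}\sum_i r_{ij}\,r_{ij}',$$

and the sandwich variance of a contrast $c$:

$$\widehat{\mathrm{Var}}(c'\hat\beta_j) = c' B \Big(\sum_i X_i' \hat\Sigma_j
X_i\Big) B\, c, \qquad B = \Big(\sum_i X_i'X_i\Big)^{-1}.$$

No further scaling is applied: for identical blocks the expression already
reduces to $c'(X'X)^{-1}X'\hat\Sigma X (X'X)^{-1}c/q$, the variance of a mean
of $q$ replications. The same bread with the cross-voxel meat
$\hat\Sigma_{jk} = (q-1)^{-1}\sum_i r_{ij} r_{ik}'$ gives
$\widehat{\mathrm{Cov}}(c'\hat\beta_j, c'\hat\beta_k)$; by construction
$\widehat{\mathrm{Cov}}(j,j)$ equals the variance, and the estimated
correlation of any pair lies in $[-1, 1]$ (Cauchy–Schwarz on the block
residual scores), so the pooled variance of a difference can never become
negative except for numerically identical voxels.

The estimator is robust to autocorrelation and to HRF misspecification
because nothing is assumed about the within-block error covariance; the
price is that only the $q$ replications carry inferential weight, so t
statistics use $q - 1$ degrees of freedom (configurable: the alternative
$T - p$ reading is exposed as the `dof` argument of `contrast_zmap()`).
Ordinary least squares (`fit_ols()`, variance $\hat\sigma^2 c'(X'X)^{-1}c$)
and AR-prewhitened GLS (`fit_gls_ar()`, Yule–Walker coefficients from the
OLS residuals, AR(1) default) are provided as the baselines the sandwich is
compared against; under autocorrelated noise their confidence intervals are
too short (OLS badly, GLS mildly when the AR model is wrong).

Implementation note: the per-voxel quadratic forms are evaluated through the
block scores $W_i = X_i B c$, so variances for all voxels come from one
matrix product and the covariance of every voxel with a fixed comparison
voxel is a single matrix–vector product (`sandwich_covariance_all()`).
Voxels with exactly zero variance (constant signal) are excluded from the
analysis mask with a message.

## Step 2: thresholding

`contrast_zmap()` converts $t = c'\hat\beta/\sqrt{\widehat{\mathrm{Var}}}$
to z through the probability integral transform (log-tail evaluation keeps
|t| up to the hundreds finite and monotone). `cluster_threshold()` applies a
primary threshold $z \ge u$, groups supra-threshold voxels by face
connectivity (4-connectivity in 2D, 6 in 3D; corner connectivity optional),
and assigns each cluster a family-wise p-value:

* `method = "grf"`: the Gaussian-random-field expected-cluster-count
  approximation. Expected cluster count
  $E[m] = R\,(4\ln 2)^{D/2} (2\pi)^{-(D+1)/2} u^{D-1} e^{-u^2/2}$ with
  $R$ the resel count from the per-axis FWHM; cluster sizes follow
  $P(n \ge k) = \exp\{-\beta (k^{2/D} - 1)\}$ with $\beta$ matched to the
  expected size. The size CDF is anchored at $k = 1$ so that a singleton's
  p-value equals the Euler-characteristic bound $1 - e^{-E[m]}$. The
  un-anchored textbook form assigns $P(n \ge 1) = e^{-\beta} \ll 1$ whenever
  the expected cluster size drops below one voxel (high thresholds on
  barely-smooth maps) and then calls isolated noise voxels significant; in
  the classical regime ($E[n] \gg 1$) the anchor changes nothing.
* `method = "permutation"`: a simulation null of the maximum cluster size
  over Gaussian fields matched to the estimated smoothness (white noise,
  circulant Gaussian smoothing, analytic standardisation), with
  $p = (1 + \#\{\max \ge k\})/(B+1)$. If no seed is given one is drawn and
  recorded in the result.

Smoothness is estimated from the standardized residual images: per axis,
$\lambda = E[(r_a - r_b)^2]$ over neighbouring in-mask pairs and
$\mathrm{FWHM} = \sqrt{4\ln 2/\lambda}$, floored at one voxel. On a lattice,
spatially white noise gives $\lambda = 2$, i.e. FWHM $\approx 1.18$ voxels,
not 1 — tests against "white" fields use that value. Inference is one-sided
on positive z; negate the contrast for deactivations.

## Steps 3–4: the comparison voxel and the limbo tests

The comparison voxel is the significant voxel with the smallest statistic;
ties (exactly equal minima) break to the lowest array index with a warning.
If nothing survives thresholding the run stops with a dedicated condition:
without significantly activated areas there is nothing to be in limbo
against. Averaging the least-significant cluster instead is available as an
alternative selection rule but is not the default, because the minimum voxel
gives the only interpretation under which "not in limbo" means "different
from *every* activated voxel".

Single subject: for each non-significant voxel $j$,

$$t_j = \frac{c'\hat\beta_h - c'\hat\beta_j}
{\sqrt{\widehat{\mathrm{Var}}_h + \widehat{\mathrm{Var}}_j -
2\,\widehat{\mathrm{Cov}}_{hj}}}$$

with comparison voxel $h$, one-sided at $\alpha$ (default 0.05) with $q - 1$
degrees of freedom. Rejection labels the voxel **less**; otherwise it is
**in limbo**. The covariance term matters: positively correlated voxels are
easier to tell apart (the denominator shrinks), and neighbouring voxels of
the same tissue are protected from spurious "less" labels. A voxel whose
residual blocks are numerically identical to the comparison voxel's has
pooled variance zero and raises an error rather than returning NaN.

Group level: per subject $i$, the difference
$d_i = c'\hat\beta_j^{(i)} - c'\hat\beta_h^{(i)}$ and its standard deviation
$s_i = \sqrt{\mathrm{Var}_j^{(i)} + \mathrm{Var}_h^{(i)} - 2\,
\mathrm{Cov}_{jh}^{(i)}}$ come from each subject's own sandwich fit, with the
comparison voxel selected once on the level-2 map (one-sample t of the
per-subject contrasts, z-converted with $n-1$ dof). An intercept-only WLS
fit with weight matrix $\mathrm{diag}(1/s_i)$ — i.e. precision weights
$1/s_i^2$ in the normal equations — gives the group difference; its variance
uses the weighted residual sum of squares over $n - 1$: re-estimating the
residual scale is the standard WLS choice and makes the null distribution
exactly $t_{n-1}$ when the weights are proportional to the true precisions. All-zero differences return $t = 0$ (in limbo) by convention.

No multiple-comparisons correction is applied to the limbo p-values by
default: uncorrected testing rejects most, so it yields the *minimum*
in-limbo volume — the most conservative claim about inconclusiveness.
`correction = "fdr"` (Benjamini–Hochberg) can only enlarge the in-limbo set,
which the tests assert as an invariant. Comparison-voxel selection is
per-threshold in `threshold_sweep()`: a higher threshold can select a
different comparison voxel with a different covariance pattern, which is why
the in-limbo volume need not shrink as the threshold rises — the sweep
reports the chosen voxel per row so the mechanism is visible.

## The synthetic-data generator

`synthetic_spec()` describes a square 2D brain (default 64×64, stored and
written as a single-slice 3D NIfTI so every module shares one I/O path) with
two disc-shaped regions: A (centre (21, 21), radius 6, effect 3% signal
change) and B (centre (44, 44), radius 6, effect 1.5%). The task is ten 20 s
blocks alternating with 20 s rest at TR 2 s (T = 200); BOLD is baseline 100
plus effect × unit-peak HRF-convolved boxcar inside each region plus
stationary AR(1) noise (lag-1 coefficient 0.3), optionally smoothed
spatially (rescaled to keep the marginal SD). In multi-subject mode each
subject's regions are jittered (centre SD 2 voxels, radius SD 0.5, effect SD
0.5 percent points in the group studies); overlapping discs are redrawn up
to 100 times, then error. Reproducibility is exact: every draw derives from
the root seed through fixed per-subject, per-purpose Lehmer substreams
(`il_child_seed()`), so a single subject can be regenerated without
generating the rest of the group, and generation does not disturb the
caller's RNG state.

**Choosing the noise level.** The defining feature of the single-subject
scenario is its detection regime: region A must clearly survive
thresholding, region B must not, yet B must remain statistically
indistinguishable from the weakest surviving voxel. A pre-implementation
design analysis (closed-form SE of the task contrast under this design,
plus a Monte-Carlo model of minimum-order statistics over the surviving
cluster) shows this regime is only reachable when the weak region sits near
the edge of voxel-wise detectability. With the marginal noise SD at 1.0 the
per-voxel t would be ≈ 14.5 in A and ≈ 7.3 in B — B would survive *any*
conventional threshold and no threshold separates the three classes, because
the comparison voxel hugs the cluster-forming threshold and the background
test then has a fixed deficit of about $u/\sqrt 2$ against the critical
value. The default is therefore $\sigma = 1.6$, giving expected per-voxel t
of ≈ 9 in region A and ≈ 4.5 in region B. For the same reason the recovery
study analyses its data at a cluster-forming z of 4.4 with $q = 28$ blocks
(block length 14 s — long enough that AR(0.3) correlation across block
boundaries is negligible, twice the $\sqrt T$ default to stabilise the
variance estimates; the $\sqrt T$ rule stays the package default). The group
study keeps the conventional group threshold z = 2.3; between the two
common group-map thresholds 2.3 and 3.1, a ten-seed pilot on seeds disjoint
from the recovery study retained 2.3 (the jitter ring stays attached to the
activated core). These are the package's study conditions
and are not adjusted per run.

What the generator does *not* emulate: physiological noise and motion,
scanner drift, HRF variability across tissue, anatomical structure, and 3D
geometry. Passing recovery tests therefore demonstrate the statistical
machinery (calibration, covariance handling, classification logic) under
the stated noise model — not performance on real data, where the sandwich
estimator's robustness to unmodelled autocorrelation and HRF error is the
argument for the method rather than a property the simulation can prove.

## Numerical and design choices

* Block defaulting: $q = \lfloor\sqrt T\rfloor$, trailing $T - qL$ time
  points dropped from the end; explicit `q` overrides.
* Rest-only blocks are legal (their task column is all zero); only the
  pooled design must be full rank. Rank deficiency errors name the
  collinear columns.
* Degrees of freedom: sandwich $q-1$, OLS $T-p$, GLS $T'-p$ after
  whitening, group $n-1$. The z-conversion dof is a parameter.
* Eq.-normalisations chosen for unbiasedness: $q-1$ in the residual
  covariance, $n-1$ in the WLS residual scale.
* Zero-variance voxels are masked out (with a count), not propagated as
  infinite t.
* Voxel indexing is 0-based in all exported tables and label maps
  (array order); label codes: 0 background, 1 less, 2 in limbo,
  3 activated. Output NIfTIs reuse the input header/affine unchanged.
* Null fields for the simulation-based cluster test use circulant
  (wrap-around) smoothing; for stationary null fields the boundary
  treatment only perturbs the max-cluster statistic negligibly at the
  field sizes used.
* Problem sizes in the shipped studies: 2 000 series for estimator
  calibration, 2 000 draws per correlation level for the covariance check,
  2 000 replicates for the group-test size, 50 single-subject and 20
  group-level synthetic datasets, 500 null fields for family-wise error —
  sizes at which the Monte-Carlo error of each reported rate is a few
  tenths of a percentage point, chosen so the whole battery runs on a
  laptop-class machine in a few minutes.

## Known limitations

* The sandwich estimator needs enough replications: with $q$ around 10 the
  variance estimate itself is noisy ($\chi^2$-like with $q-1$ dof) and the
  z-map is heavy-tailed; the `q` override exists precisely because
  $\sqrt T$ can be too few for classification-grade maps.
* GRF p-values assume a stationary, reasonably smooth Gaussian field; for
  2D lattices at low smoothness the permutation null is the safer choice
  (both are exposed; the anchored size CDF repairs only the singleton
  pathology, not non-stationarity).
* Group inference weights subjects by within-subject precision only; the
  residual scale re-estimation absorbs between-subject variance globally
  but not per voxel.
* Spatial registration, motion correction, slice timing and smoothing are
  assumed done upstream; no HRF basis sets beyond the canonical kernel.
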