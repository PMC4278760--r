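# inlimbo

Classify every brain voxel in an fMRI contrast as **activated**, **in
limbo**, or **significantly less activated** — instead of the usual binary
significant / not-significant map.

Binary thresholded maps invite the *imager's fallacy*: concluding that
region A is selectively involved in a task because A reached significance
and region B did not, without ever testing A against B. A voxel can miss the
threshold because there is no effect — or merely because its signal is
noisier. `inlimbo` tests every non-significant voxel directly against the
*least significantly activated voxel* that survived thresholding. Voxels
whose contrast is significantly smaller are `less`; voxels for which even
this comparison fails are `in limbo`: the data cannot tell them apart from
activated tissue, and any claim of selective activation that leans on them
is unsupported.

The package is aimed at neuroimaging researchers who want this third
category on top of a standard GLM analysis, and at methodologists who need
calibrated robust variance and cross-voxel covariance estimates for BOLD
time series.

## The statistics in one screen

For voxel *j* with design blocks *Xᵢ* ("subruns" of the run, default
`q = floor(sqrt(T))` blocks) and block residuals *rᵢⱼ*:

* coefficients: `b_j = (Σ Xᵢ'Xᵢ)⁻¹ Σ Xᵢ'yᵢⱼ` — the OLS fit of the
  across-block mean time course when blocks share a design;
* sandwich variance of a contrast `c`:
  `Var(c'b_j) = c'B (Σ Xᵢ' Σ̂ⱼ Xᵢ) B c` with bread `B = (Σ Xᵢ'Xᵢ)⁻¹` and
  meat from the block residual covariance `Σ̂ⱼ = (q−1)⁻¹ Σ rᵢⱼ rᵢⱼ'` —
  robust to autocorrelation and HRF misspecification, with `q − 1` dof;
* cross-voxel covariance: same bread, meat from
  `Σ̂ⱼₖ = (q−1)⁻¹ Σ rᵢⱼ rᵢₖ'`;
* thresholding: z-map primary threshold + cluster-extent correction (GRF
  expected-cluster-count, or a simulation null of the max cluster size);
* limbo test, subject level:
  `t = (c'b_h − c'b_j) / sqrt(Var_h + Var_j − 2 Cov_hj)` against the
  comparison voxel *h*, one-sided at α = 0.05;
* limbo test, group level: per-subject differences `d` weighted by inverse
  per-subject standard deviations in an intercept-only WLS fit, `n − 1` dof.

## Worked example

Simulate the bundled single-subject scenario (64×64 brain, strong region A
at 3% signal change, weak region B at 1.5%, ten 20 s task blocks, AR(1)
noise) and run the full pipeline:

```r
library(inlimbo)

spec <- synthetic_spec(seed = 1)
sub  <- generate_subject(spec)
cfg  <- il_config(bold = sub$bold, design = sub$design,
                  contrast = c(task = 1), z_threshold = 4.4, q = 28,
                  cluster_method = "grf")
run  <- run_subject(cfg)
run
#> <il_limbo> activated 138 | in limbo 77 | less 3881 (alpha = 0.05, none)
run$comparison
#> <il_comparison> voxel (44, 46), z = 4.414, rule = min_t_significant
```

Region A's 113 truth voxels are all inside the 138 activated voxels; the 77
in-limbo voxels sit almost entirely inside region B — B did not survive
thresholding, but it is *not* distinguishable from the weakest surviving
voxel (z = 4.41 at voxel (44, 46)), so concluding "A is active and B is not"
would be exactly the fallacy the map guards against. The remaining 3 881
voxels are significantly less activated than that comparison voxel.

Results tidy into voxel tables and plot directly:

```r
library(dplyr)
tidy(run) |> count(label)
#> # A tibble: 3 × 2
#>   label         n
#>   <fct>     <int>
#> 1 less       3881
#> 2 in_limbo     77
#> 3 activated   138
autoplot(run)    # orange = activated, green = in limbo, grey = less
```

Sweeping the cluster-forming threshold reproduces the characteristic
behaviour that the in-limbo volume need not shrink as the threshold rises —
each threshold may pick a different comparison voxel:

```r
threshold_sweep(cfg, c(3.1, 4.4, 5.5))[
  , c("z_threshold", "n_activated", "n_in_limbo", "comparison_voxel")]
#>   z_threshold n_activated n_in_limbo comparison_voxel
#> 1         3.1         211        273            42,46
#> 2         4.4         138         77            44,46
#> 3         5.5         110         83            44,41
```

Group analyses (`run_group()`) take per-subject BOLD images on a common
grid, form the level-2 z-map across subjects, and apply the WLS limbo test
with each subject's sandwich variances and covariances as precision weights.
A thin command-line driver is installed under
`system.file("cli", "inlimbo", package = "inlimbo")` with verbs `simulate`,
`run`, and `sweep` (NIfTI/TSV in, NIfTI/TSV/JSON out; exit code 2 signals an
empty significant set).

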