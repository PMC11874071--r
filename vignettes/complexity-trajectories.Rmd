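---
title: "Developmental trajectories of regional brain signal entropy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developmental trajectories of regional brain signal entropy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(entrajectory)
```

entrajectory implements a cross-sectional pipeline for tracing how the
complexity of resting-state brain activity changes from childhood to young
adulthood, and how it differs between a clinical ("case") group and
controls. This vignette is the package's own account of the method: the
model at each stage, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the problem left them open.

## Sample entropy as a complexity measure

The per-voxel measure is sample entropy,

$$\mathrm{SampEn}(m, r) \;=\; -\ln\frac{A}{B},$$

where $B$ counts unordered pairs of distinct $m$-length templates of the
series whose Chebyshev (maximum absolute coordinate) distance is at most
$r$, and $A$ counts the same for $(m{+}1)$-length templates. Both counts
run over the $N-m$ template start points and exclude self-matches, so every
$(m{+}1)$-match is also an $m$-match, $A \le B$, and the estimate is
non-negative wherever defined. Low values mean a regular, repetitive
signal; high values mean irregularity.

Conventions for degenerate inputs are fixed so results are reproducible
bit-for-bit:

* the tolerance is $r = r_{\mathrm{frac}} \times \mathrm{SD}$ of each
  voxel's own (coarse-grained) series, with the sample ($n-1$) SD — this
  per-series normalization is the standard convention and makes the
  estimate exactly invariant under affine transforms $a x + b$;
* a constant series returns 0 (the $r \to 0^+$ limit in which all
  templates match at every length);
* when $A = 0$ or $B = 0$ the estimate is undefined: the voxel is flagged,
  excluded from regional averages, and counted in `n_voxels_dropped`.

Coarse-graining (the multiscale-entropy scale factor) replaces the series
by non-overlapping block means of length $\tau$ before counting; the
default $\tau = 1$ leaves the series unchanged, and the parameter exists
only because the analysis is defined over it.

**Parameter defaults.** `m = 1`, `r_frac = 0.15`, `scale = 1`. The
embedding dimension follows the validity rule that the series must be
longer than $10^m$: multi-site resting-state archives contain epochs as
short as 77 samples, which admits $m = 1$ only, and `select_m()` encodes
exactly that rule (the largest $m$ with $10^m$ strictly below the shortest
series length). For long i.i.d. Gaussian series with these defaults the
estimate converges to the closed form
$-\ln\!\big(2\Phi(r_{\mathrm{frac}}/\sqrt2) - 1\big) \approx 2.4714$, which
the test suite uses as an analytic anchor.

The pairwise template counting — the one $O(N^2)$ hot loop — is compiled
(Rcpp); the test suite checks it exactly against an independent plain-R
counting oracle on short series.

## Regional aggregation

Voxels are assigned to 90 regions of an anatomical parcellation (odd ids
left hemisphere, even ids right; the lookup table ships with the package).
A region's value is the arithmetic mean of its defined voxel entropies.
The whole-brain summary is, by default, the **unweighted mean of the 90
regional means**, so small subcortical regions contribute equally with
large cortical ones; a voxel-weighted alternative is available
(`whole_brain = "voxel"`) because the choice is a genuine convention, not
a consequence of the measure. Masking accepts an explicit gray-matter mask
and otherwise defaults to voxels with nonzero temporal variance; the run
log records which was used.

## Age-window trajectories

Subjects are grouped into overlapping 5-year windows advancing by 1 year —
"6 to 10", "7 to 11", ..., "26 to 30", 21 windows in all. Membership is
evaluated on continuous age with the half-open rule
$\mathrm{lo} \le a < \mathrm{lo} + \mathrm{width}$, so the window labelled
"26 to 30" admits ages up to (but excluding) 31; this reconciles integer
window labels with fractional ages (a cohort whose oldest member is 30.78
still lands in the last window). An interior-aged subject belongs to
exactly width/step = 5 windows; subjects outside all windows are reported,
never silently dropped.

Within every window-by-group cell:

1. **Outlier screening** uses Rosner's generalized extreme studentized
   deviate (GESD) test: iteratively remove the point with the largest
   studentized deviation, compare each statistic $R_i$ with its critical
   value $\lambda_i$ from the $t$ distribution, and declare the largest $i$
   with $R_i > \lambda_i$ points outliers. The test's parameters are not
   dictated by the protocol, so they default to $\alpha = 0.05$ and
   $k_{\max} = \lceil 0.1\,n \rceil$ (at least 1), both configurable and
   logged. Cells with fewer than 4 values are not screened. Removing
   flagged points can only reduce a cell's SD, which the suite checks as a
   property.
2. **Normality** is recorded per cell by a one-sample Kolmogorov–Smirnov
   statistic against a normal with the cell's own mean and SD. It is
   reported for context only and never gates the parametric test, because
   the analysis applies $t$ tests throughout.
3. **Summaries**: mean, SD, SEM $= \mathrm{SD}/\sqrt{n}$, $n$, and the
   number of removed outliers. Conventions: a single-subject cell reports
   SD 0 and a missing SEM and is excluded from tests; an empty cell
   reports $n = 0$ with a missing mean.

**Group tests.** The per-cell case-vs-control comparison is a two-sided
independent $t$ test, pooled-variance (Student) by default — the classical
reading of "independent t test" — with Welch available by configuration.
Because consecutive windows overlap, each subject recurs in 5 windows, and
the Bonferroni family is the overlap factor: $0.05/5 = 0.01$ for the
whole-brain trajectory and $0.05/(5 \times 90)$ for the regional family.
The package always computes the exact quotient ($1.1\overline{1} \times
10^{-4}$ for the regional family) rather than a rounded value.

**Differential curves.** Per region (and for the whole brain), the case
mean minus the control mean in every window. A value is missing whenever
either group mean is missing — never imputed as zero, since zero is a
meaningful "no difference" value in these curves.

## Clustering differential curves

Regions with similar case-minus-control trajectories are grouped by
complete-linkage agglomeration on Euclidean distances between their
differential curves (rows with any missing window are excluded with a
logged list rather than imputed). Complete linkage guarantees monotone
non-decreasing merge heights. The number of clusters is chosen by the
maximum of the Calinski–Harabasz index

$$\mathrm{CH}(k) = \frac{B/(k-1)}{W/(n-k)}$$

over a configured range (default 2–6), falling back to $k = 2$ when the
scan is flat or degenerate; a clustering with zero within-cluster
dispersion is reported as infinite and flagged. Heatmap display order is
the deterministic dendrogram leaf order. The original analysis environment
used a proprietary rank-2 ellipse seriation for display; the clusters
themselves come from Euclidean distance plus complete linkage, which is
what is implemented, and leaf order is the deterministic stand-in for the
display ordering (a design decision, since seriation affects only
presentation).

Per-cluster mean differential curves are reported with their extreme
values and window positions (the peak/trough reading of the trajectories),
and the two clusters' trendlines can be compared by a $t$ test. The
pairing structure of that comparison is not fixed by the protocol, so both
variants are provided; the paired-by-window variant is the default and the
output labels which was used. A window-by-window Pearson correlation
matrix of mean entropy profiles across regions accompanies the clustering.

## Behavioral association

Candidate regional-entropy predictors are screened for collinearity by
iterative variance inflation factors: $\mathrm{VIF}_j = 1/(1 - R_j^2)$
from regressing predictor $j$ on the others, dropping the largest while it
exceeds the threshold (default 10 — the conventional cutoff, configurable;
exactly collinear predictors have infinite VIF and are dropped first). The
full per-round trace is returned so the screening is auditable.

Each behavioral scale is then regressed on the surviving regions plus age
and sex (sex coded male = 0, female = 1, configurable):

$$\text{score} = b_0 + \textstyle\sum_r b_r X_r + b_{\text{age}}\,\text{age}
  + b_{\text{sex}}\,\text{sex} + \varepsilon.$$

The "1000 bootstrapping strategy for 85% of participants" is read as 1000
resamples each drawing $\lfloor 0.85\,n \rfloor$ subjects **without**
replacement — the 85% figure only makes sense as a subsample size — with
the classical with-replacement bootstrap available by configuration.
Numerical conventions:

* full-sample OLS supplies the point estimates, $R^2$, $F$, and the model
  $p$; whether the original analysis's per-coefficient $p$ values were
  bootstrap-based or OLS-based is ambiguous, so both are reported
  (`p_ols` and the sign-flip `p_boot`), and the significance flag at the
  corrected level $0.05/(\text{number of predictors})$ uses `p_ols`;
* `p_boot` $= 2\min\{P(\beta^* \le 0), P(\beta^* \ge 0)\}$, floored at
  $1/n_{\text{boot}}$ so it is never exactly zero;
* the subsample spread understates the full-sample sampling error, so the
  reported `boot_se` carries the m-out-of-n correction
  $\sqrt{m/(n-m)}$ ($\approx 2.38$ at 85%), making it an estimate of the
  full-sample standard error; the percentile CI is left on the raw
  subsample distribution;
* resamples with singular designs are skipped and counted, with a warning
  above 10%;
* missing behavioral scores give complete-case analysis per response,
  with counts logged.

With `subsample_frac = 1` and `replace = FALSE` every "resample" is a
permutation of the full sample, so the bootstrap reproduces the
full-sample fit exactly — a useful identity test. The type-I error of the
reported `p_ols` at the corrected level is calibrated by simulation in the
acceptance suite (null responses across 500 seeds); the sign-flip
`p_boot` is conservative by construction under subsampling and is not the
calibrated quantity.

Which candidate regions enter the screening is configuration (default:
the bilateral posterior cingulate and left amygdala entropies, the trio
that survives screening in the motivating analysis); how a candidate set
would be pre-selected from all 90 regions is upstream feature selection
and out of scope.

## The synthetic cohort generator

Every stage is testable without any imaging download because the package
generates cohorts with the statistical structure the analysis assumes.

* **Voxel model.** Each voxel's series is a standardized AR(1) process
  $x_t = \phi x_{t-1} + \varepsilon_t$ — the minimal stationary process
  with a single irregularity knob. Higher $\phi$ means a smoother series
  and lower sample entropy; the mapping is monotone, which the suite
  verifies. No hemodynamics, drift, motion, or physiological noise are
  modelled, so passing tests demonstrate the statistical machinery, not
  robustness to fMRI artifacts.
* **Templates.** The control group's $\phi$ falls linearly with age from
  0.85 (age 6) to 0.60 (age 30), so control entropy rises monotonically
  through development. The case group's entropy is offset from the
  control's by a smooth spline gap curve: negative in childhood, peaking
  positive in adolescence (~14 y), negative again in adulthood. Two
  region classes carry different gap curves — a gentle "subcortical"
  template (peak +0.015, trough −0.02 nats; the median/posterior
  cingulate, hippocampal, parietal, paracentral, and basal-ganglia ids)
  and a steeper "cortical" template (peak +0.07, trough −0.09 nats) for
  the remaining regions — emulating the qualitative two-cluster
  developmental picture. Because the entropy-vs-$\phi$ response of the AR
  process is strongly nonlinear (flat below $\phi \approx 0.15$, slope
  about −3 nats per unit $\phi$ near 0.9), gap curves specified in entropy
  units are mapped to coefficients through a measured response table
  (3000 replicates per $\phi$ level at the default series length),
  inverted monotonically — not through a constant slope.
* **Magnitudes.** The planted gaps are a few times larger than the
  hundredth-of-a-nat group differences a thousand-subject cohort can
  resolve: a desk-scale cohort needs effects its own power can detect, and
  matching real effect sizes is explicitly not a goal of the generator.
  The default sizes — 150 subjects per group, a 9×9×10 voxel grid (9
  voxels per region), 120 timepoints per series (comfortably above the
  77-sample floor), per-subject regional $\phi$ jitter of SD 0.01 —
  were fixed prospectively by sizing the planted template separation
  against the measured window-cell standard errors so that exact cluster
  recovery is expected, and then frozen.
* **Determinism.** Everything is a pure function of the root seed: each
  stage and each subject draws from a named substream derived from
  (seed, name), so any stage can be regenerated alone, and identical
  seeds give byte-identical outputs down to the written TSVs.
* **Behavioral scores** are generated from a known linear model on
  selected regional entropies, age, and sex, with configurable
  coefficients and residual SD, so the regression stage has a planted
  truth to recover (exactly, when the residual SD is zero).

## Pipeline, configuration, and outputs

`run_pipeline()` executes cohort → entropy profiles → trajectories and
tests → differential curves → clustering → behavioral association,
writing every table as TSV with a stable column order, serializing the
resolved configuration into the output directory, and keeping a run log
of the seed, parameter values, and everything dropped along the way
(unassigned subjects, undefined voxels, excluded curves, removed
outliers). A stage failure leaves a `FAILED` marker naming the stage and
keeps partial outputs. The YAML configuration is the single source of
truth; `cli_main()` is a thin argv wrapper over it with stage subcommands
(`simulate`, `entropy`, `trajectories`, `cluster`, `associate`,
`run-all`).

## Problem sizes in the test suite

The suite exercises: exact oracle equivalence for the entropy counts (100
series up to length 60), the Gaussian closed form (50 series of length
5000, within 2%), GESD against a step-by-step oracle (200 samples),
complete linkage against brute-force agglomeration (6-point sets),
Calinski–Harabasz model selection (50 seeded planted-k sets, ≥95%
required), regression recovery (n = 400 within 3 rescaled bootstrap SEs)
and null calibration (500 seeded null data sets at the corrected level
0.01), and one full end-to-end run at the generator defaults checking the
planted whole-brain sign pattern and exact recovery of the planted
two-cluster region partition. These sizes are the package's chosen
trade-off between statistical resolution and a test suite that runs in a
few minutes on a single CPU.

## Known limitations

* The design is cross-sectional; within-subject (longitudinal) modelling
  and mixed-effects alternatives are out of scope.
* Preprocessing (motion correction, registration, nuisance regression) is
  treated as upstream; inputs are assumed preprocessed and spatially
  aligned to the label volume.
* Site/protocol covariates are not modelled in the regression stage.
* The AR(1) generator validates the machinery, not fMRI realism; effect
  sizes in real cohorts are an order of magnitude smaller than the
  planted ones, and real group differences may not survive correction at
  realistic sample sizes.
* No small-sample bias correction is applied to the entropy estimates
  beyond the parameter-validity rule for $m$.
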