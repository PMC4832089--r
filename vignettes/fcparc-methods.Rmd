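---
title: "Connectivity-based parcellation with fcparc: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based parcellation with fcparc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fcparc)
```

## What the package does

`fcparc` partitions an anatomical mask — the motivating application is the
cingulate cortex in resting-state fMRI — into subregions with distinct
*connectivity fingerprints*: for every voxel of the mask, the vector of
correlations between its time course and every grey-matter voxel in the
brain. Voxels whose fingerprints are similar are grouped by average-linkage
hierarchical clustering; the number of clusters is selected by asking at
which dendrogram cut level the group solution best describes *individual*
subjects, measured by the silhouette statistic. The group solution is then
back-projected: each subject is re-clustered at the chosen K, subject
clusters are matched to group clusters through a Dice-overlap procedure, and
the matched clusters are accumulated into a probabilistic atlas with a
winner-take-all labeling. Finally, seed-to-voxel connectivity maps of the
resulting parcels are compared between groups with a permutation-based
general linear model that supports age interactions and voxel-dependent
grey-matter covariates.

Every stage is validated against synthetic phantom cohorts with known
ground truth; the phantom generator is itself part of the package.

## Pipeline and assumptions

The toolkit assumes spatially aligned input: one 4-D NIfTI series per
subject, already registered to a common space, with binary masks for the
seed region, grey matter, white matter and CSF, a 6-column motion-parameter
table, and a covariate table (group, age, IQ, scanning centre). Spatial
normalisation, segmentation and realignment estimation are upstream of the
package. An optional isotropic Gaussian smoothing step is provided but off
by default.

### Denoising

1. **Scrubbing.** Framewise displacement is the sum of absolute backward
   differences of the six rigid-body parameters, rotations converted to arc
   length on a 50 mm sphere; DVARS is the root-mean-square volume-to-volume
   signal change expressed as percent of the within-mask grand mean. A
   volume is censored when FD > 0.5 mm *or* DVARS > 0.5 % (strict
   inequalities; values at the threshold survive). Only flagged volumes are
   removed; neighbour augmentation is available via `scrub(augment =)` but
   defaults off.
2. **Nuisance regression.** The 24-parameter motion model (parameters,
   one-volume time shift with zero-filled first row, and both squared) plus
   the first three principal components from the white-matter and CSF masks
   are projected out by least squares over the retained volumes only;
   censored volumes are excluded, not interpolated. Collinear confounds are
   dropped with a warning via rank-revealing QR.
3. **Band-pass.** An order-2 Butterworth band-pass (0.009-0.2 Hz) applied
   forward and backward (zero phase). The wide upper edge deliberately
   retains the 0.1-0.2 Hz band.

The order is scrub, regress, filter. Whether filtering should precede
regression is genuinely ambiguous in practice; both orders are supported
(`filter_first = TRUE` filters data and confounds identically before the
fit) and the resolved order is recorded in the stage log. Filtering after
censoring treats the retained series as contiguous; this is an
approximation we accept in exchange for never fabricating data by
interpolation.

### Fingerprints and clustering

Correlations are Fisher r-to-z transformed (`atanh`), with `|r| = 1`
clipped to `1 - 1e-7` so self-correlations stay finite — the seed mask is
part of grey matter, so the diagonal is included rather than excluded; the
clip constant is configurable. Group fingerprints are the fixed-effects
(elementwise) mean of the subject z-matrices, transformed back to r. The
fingerprint distance is `1 - r(row_i, row_j)` (correlation distance), the
standard choice for connectivity fingerprints; Euclidean distance is
available.

Cut levels are spaced uniformly in merge *height* between the smallest and
largest merge, endpoints excluded, so every level yields between 2 and n-1
clusters. For each level the group labeling is scored against every
subject's own fingerprint distances with the classic silhouette
`s(i) = (b - a) / max(a, b)` (singletons score 0), and the across-subject
one-sample t-statistic versus zero forms the selection profile.

**Local maxima on runs.** Because neighbouring levels frequently share a
labeling — on a clean dendrogram the planted K occupies a wide band of
heights — the t profile is piecewise constant. Declaring maxima per level
with strict inequalities would therefore never fire inside such a band. We
collapse consecutive equal t values into runs and call a run a maximum when
it strictly exceeds both neighbouring runs; endpoint runs are never maxima,
a flat profile yields none (with a warning). All maxima are reported;
nothing is auto-picked on anatomical-plausibility grounds. `parcellate_group()`
additionally exposes the highest-t maximum as `best` for convenience.

The silhouette is computed by applying the *group* labels to *individual*
distance matrices, i.e. it measures how well the group solution describes
each subject, not how well each subject clusters per se; single-subject
solutions are obtained separately by re-clustering each subject's own
fingerprints and cutting at the group K.

### Matching, replication, atlas

Group and subject clusters are matched by building the joint element set of
both cluster collections with distance `1 - Dice` between group-subject
pairs and 1 within each side, clustering it with average linkage, scanning
every distinct cut height, and keeping the cut that maximises the number of
two-element clusters containing exactly one element from each side (ties:
lowest height). No minimum-overlap cutoff is enforced by default
(`min_dice` exists but is 0): a group cluster simply matches its best
subject counterpart or none. Replication of a group cluster is the
percentage of subjects with a match; a chi-squared test probes group
differences in match frequency.

Probability maps count, per voxel and group cluster, the fraction of *all*
subjects whose matched cluster covers the voxel — unmatched subject
clusters carry no group identity and are excluded, the only coherent
reading of binarise-and-sum. Winner-take-all assigns a voxel to the argmax
cluster when that probability strictly exceeds the threshold (default
0.25, applied before the argmax); exact ties go to the lowest cluster index
and are recorded in a tie mask, so the tie rule is deterministic and
auditable.

### Group inference

Seed maps (Fisher-z of the correlation between the unweighted mean seed
time course and each grey-matter voxel) enter a GLM with intercept, centre
dummies (reference-coded), mean FD, full-scale IQ, natural-log age
(continuous covariates mean-centred), deviation-coded group, group x
log-age, and optionally grey matter and group x grey matter, where the GM
regressor is *voxel-dependent*: the design matrix changes at each analysed
voxel to carry that voxel's per-subject GM value.

Inference is by Freedman-Lane permutation: the data are residualized
against the nuisance portion of the model, residual rows are permuted, the
full model is refit, and the tested coefficient's t is recorded.
Permutations are restricted to within scanning centre (exchangeability
blocks), since centres may differ in scale and noise. Voxelwise family-wise
error uses the max-statistic null; cluster-level FWE thresholds the z map
at 3.1 (configurable), labels face-connected (6-connectivity; 18/26
available) components, and compares observed extents with the permutation
null of maximal extents. All p-values use `(1 + exceedances)/(1 + n_perm)`.
Cluster correction is deliberately permutation-based rather than based on
Gaussian-random-field theory: the parametric cluster inference it replaces
is exactly the step most criticised in the cluster-failure literature, and
the permutation route makes one fewer distributional assumption. The
default is 10,000 permutations; studies in this package's tests use 500,
which bounds attainable p at 1/501 and is ample for calibration checks.

Seed-type comparisons (`network_strength()`) average each subject's map
within a network mask per seed type and test the seed-type effect with a
repeated-measures ANOVA (`aov` with an `Error(subject/seed_type)` stratum),
with group and group x seed-type terms when groups are supplied.
`sphere_grid_effects()` tiles a cluster's probability map with
non-overlapping fixed-radius spheres greedily from the probability peak
outward, and reports per-sphere group effect sizes (pooled-SD Cohen's d)
and the across-sphere correlation between network strength and map
probability.

## The phantom model

`phantom_spec()` plants K parcels inside a seed slab and K disjoint
network targets elsewhere. Parcel-k and network-k voxels share a latent
series `L_k`; each voxel is `sqrt(s) L_k + sqrt(1-s) E_v` with unit-variance
idiosyncratic `E_v`, plus white measurement noise of SD `noise_sd`. Thus the
expected voxel-to-voxel correlation across the parcel-network pair is `s`
in the noise-free limit (this is the `signal_corr` parameter) and
`s / (1 + noise_sd^2)` otherwise. Latent and idiosyncratic series are AR(1)
with coefficient 0.3 by default, mimicking the autocorrelation of
band-limited BOLD; measurement noise is white. In-brain voxels ride on a
baseline of 1000 units so the DVARS percent normalization has a realistic
denominator.

Motion spikes are *steps*: at each spike frame the head position jumps by
1 mm and the global in-brain intensity by 20 units (2 % of baseline), and
both stay. A step perturbs exactly one backward difference, so FD-based
and DVARS-based scrubbing each flag exactly the spike frames — which is
what makes the scrubbing-recovery contract exact. The residual level shift
is captured by the motion regressors.

Cohorts (`cohort_spec()`) add two groups, uniform ages (default 7-40
years), Gaussian IQ, round-robin centre assignment within group, and a
random number of spikes per subject (so mean FD varies and is estimable as
a covariate). A planted group difference in the connectivity-age slope is
defined on the scale the GLM tests — the Fisher-z of the parcel-mean seed
map at the target — as `z_i = baseline_z + slope_g (log age_i - centre)`
with `slope_A - slope_B` equal to the requested interaction; the generator
inverts this analytically through seed averaging and noise attenuation to
a per-subject latent coupling, so least squares on realized maps recovers
the planted slope without attenuation bias.

**Calibration studies.** Family-wise-error calibration runs the
group-by-age contrast on null cohorts (no planted group effect) and
counts rejections at the 0.05 level, voxelwise and cluster-level. The
subject seed maps are smoothed at 6 mm FWHM (`smooth_map_volume()`)
before entering the GLM: cluster-extent inference presumes spatially
smooth statistic fields, and on unsmoothed phantom maps — voxelwise
independent by construction — suprathreshold clusters are so rare that
the discrete extent null cannot resolve rates near the nominal level.
Smoothing does not affect exchangeability, so the permutation test
remains exact; it restores the spatial autocorrelation that real,
smoothed BOLD maps always have.

**Study sizes.** Parcellation studies use the default phantom: 20
subjects, K = 6, `signal_corr = 0.7`, `noise_sd = 1`, 200 volumes — noisy
enough that individual solutions differ, structured enough that the
silhouette profile selects K = 6. GLM studies use `glm_phantom_spec()`: a
compact two-parcel grid with 12,000 volumes per subject. The long series
is a deliberate design choice, not realism: the per-subject Fisher-z
standard error is about `1/sqrt(T)`, and at T = 12,000 it (~0.01) is small
against the planted between-subject effect (0.02 z per log-year over a
log-age SD of 0.5 at n = 50 per group gives a planted t near 5), so the
studies measure the inference machinery rather than within-subject
sampling noise. `make_cohort(subject_fn =)` streams subjects through a
reducer so these cohorts never hold all 4-D arrays simultaneously.

**What the phantom does not emulate** — and hence what passing tests do
not show about real data: hemodynamic response shapes, spatially
structured physiological noise, scanner drifts and multi-band artifacts,
registration error, partial-volume mixing at parcel borders, non-binary
anatomical priors, and realistic between-subject anatomical variability
(subject variation enters only through noise, motion and the planted
covariate effects). Results on phantoms demonstrate correctness of the
algorithms under the stated model, not performance on any particular
scanner's data.

## Numerical choices and degenerate inputs

- Correlation clipping at `1 - 1e-7` (so `fisher_z(1)` is about 8.0);
  configurable, logged in the matrix object.
- Zero-variance voxels (e.g. flattened by censoring) are excluded from
  fingerprint indices with a count, never imputed.
- Silhouette is undefined at K = 1 (error) and 0 for singletons; levels
  with zero across-subject variance get a flagged, undefined t.
- `scrub()` errors when every volume would be censored;
  `regress_nuisance()` requires at least two retained volumes.
- Dice of two empty sets is defined as 0 with a warning; empty clusters
  are excluded from matching with a warning.
- Winner-take-all ties: lowest cluster index, tie mask reported.
- Permutation p-values are never 0 by construction; contrasts not present
  in the design raise an estimability error; rank-deficient designs name
  the collinear columns.
- The degenerate all-equal-heights dendrogram yields a single-solution
  warning.

## Known limitations

- Average linkage is the only clustering backend (no k-means/spectral/ICA)
  and K selection is silhouette-based only.
- The permutation GLM fits one tested contrast at a time; F-tests over
  multiple columns are not implemented.
- Band-pass after censoring treats the series as contiguous (see above).
- The sphere tiling is greedy, not optimal packing; with coarse voxels the
  number of spheres depends on the probability map's peak ordering.
- `run_pipeline()` orchestrates simulated cohorts end to end; applying the
  toolkit to real data means calling the module functions directly with
  your own NIfTI inputs, as shown in the README.
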