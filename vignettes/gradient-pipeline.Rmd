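---
title: "Functional gradient analysis on synthetic multi-site cohorts: models, parameters and design choices"
author: "fcgrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional gradient analysis on synthetic multi-site cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis

`fcgrad` implements a complete functional-brain-gradient pipeline for
parcellated resting-state fMRI and a synthetic cohort generator that
plants known ground truth underneath it, so that every stage can be
validated without access to restricted clinical imaging data.

The pipeline follows the standard gradient-analysis chain:

1. **Connectivity.** Pearson correlation between all parcel time-series
   pairs, Fisher z-transformed (`compute_fc()`); correlations at
   numerically |r| = 1 are clipped to 1 - 1e-7 before `atanh`.
2. **Thresholding.** Each row independently retains its
   `floor(density * (P - 1))` largest entries by signed value
   (`threshold_rows()`, default density 0.10; 0.20 as sensitivity
   re-run). The result is intentionally not symmetrized: the next step
   compares row profiles.
3. **Affinity.** Cosine similarity between thresholded rows
   (`cosine_affinity()`). Negative similarities pass through by
   default.
4. **Embedding.** Diffusion-map embedding (`diffusion_embed()`):
   nonnegativity shift if needed, `D^-alpha W D^-alpha` density
   normalization (alpha = 0.5), row-normalization to a Markov matrix,
   eigendecomposition through the symmetric conjugate, the trivial
   constant eigenvector dropped, components scaled by
   `lambda / (1 - lambda)` (automatic multi-scale diffusion time;
   a fixed power is available via `diffusion_time`).
5. **Reference and alignment.** The reference gradient set is the
   embedding of the element-wise mean of the control-group Fisher-z
   matrices (`build_reference()`); each subject is mapped onto it by
   orthogonal Procrustes rotation without scaling
   (`procrustes_align()`), which absorbs sign flips, component swaps
   and rotations.
6. **Harmonization.** Parametric empirical-Bayes location/scale
   (ComBat) site correction (`combat_adjust()`), applied to the
   parcel-wise score table of each gradient and, optionally, to the
   derived-metric table, with group, age, sex and mean framewise
   displacement preserved through the design matrix.
7. **Differentiation metrics.** Per subject: network means of each
   gradient; gradient range (max - min); and, in the (g1, g2) plane,
   each network's centre as the coordinate-wise median of its member
   parcels, within-network dispersion as the mean Euclidean distance
   from that centre to all members, and between-network dispersion as
   the centre-to-centre distances -- 7 within- and 21 between-network
   scores for a seven-network scheme.
8. **Inference.** One-way F-tests of explained-variance ratios across
   groups (comparability check); parcel-wise fixed-effects linear
   models with covariates for regional t-maps; Mann-Whitney U tests on
   confound-regressed metrics (exact enumeration up to pooled n = 12,
   tie- and continuity-corrected normal approximation otherwise;
   eta^2 = Z^2/N); Benjamini-Hochberg correction within declared
   families.
9. **Clinical.** Subjects with strictly more than 30% missing clinical
   entries are excluded; the rest are imputed with group-wise medians;
   Spearman correlations between metrics and scores are BH-corrected
   across the full matrix.
10. **Spatial association.** Spin-permutation nulls
    (`spin_permutation_indices()`): per permutation a uniform random
    rotation is applied to left-hemisphere centroids and its
    x-mirrored counterpart to the right hemisphere; each parcel
    inherits the value of the nearest rotated parcel within its
    hemisphere. Receptor-style maps are z-scored and averaged within
    receptor type; t-map-by-receptor correlations get two-sided spin
    p-values with the +1 correction, then BH.

## The synthetic cohort: what it emulates

`synthesize_cohort()` draws, per subject, a 200-volume parcel
time-series whose population covariance is a squared-exponential
kernel over a planted 2-D latent gradient geometry plus a diagonal
nugget (`latent_kernel()`): parcels close in gradient space
co-fluctuate, so the affinity/embedding chain can recover the planted
axes. Default cohort structure mirrors a four-group, multi-site
clinical design: groups HC/ROP/ROD/CHR-P with full-scale sizes
376/243/212/240 scaled by a configurable factor (0.1 by default, 107
subjects), three sites with multiplicative kernel-amplitude scales and
additive Fisher-z edge offsets, age/sex/mean-FD covariates, and
clinical scores generated as Gaussian linear readouts of each
subject's planted metrics with missing-at-random holes.

### Geometry of the planted gradients

Parcel centroids are a golden-angle Fibonacci lattice; following the
surface-analysis convention each hemisphere lives on its own complete
sphere, with right-hemisphere centroids the mirror images of a second
lattice. Networks are contiguous z-bands within each hemisphere, so
they are spatially coherent -- a prerequisite for spin nulls to be
meaningful.

The two latent gradients are smooth functions of the centroids:
gradient 1 is the polar harmonic `z`, gradient 2 the within-hemisphere
longitude (mirror-symmetric across the midline). This pair was chosen
deliberately: together with the z-ordered lattice it tiles a
near-uniform rectangle in latent space, and on a uniform rectangle the
leading diffusion eigenfunctions are approximately linear in the
coordinates, so the embedding can recover the planted axes with high
linear fidelity. Two Cartesian harmonics of the same sphere (say `z`
and `y`) do not have this property -- their joint density concentrates
on an annulus and the leading eigenfunction becomes the ring angle --
and in our development experiments that choice capped recovery
correlations near 0.9 and could even disconnect the thresholded
affinity graph. Small per-parcel scatter (sd 0.03) adds regional
heterogeneity and breaks the exact left/right twin degeneracy; network
offsets are available (`network_offset_sd`) but default to 0 because
the z-banded networks are already separated along gradient 1, and
large offsets open gaps in the latent cloud that the k-nearest-row
thresholding cannot bridge.

Latent scales default to (1, 0.8): gradient 1 carries the larger
spread so the embedding returns it as the leading component.
The kernel defaults (`amp = 1`, `lengthscale = 0.75`, `nugget = 0.3`
in latent-sd units) give realistic FC magnitudes and keep every
covariance matrix strictly positive definite (verified by Cholesky at
construction).

### Planted effects

The default effect configuration plants one effect family per patient
group, so each is recoverable in its own contrast without
interference:

* ROP: ventral-attention (VAN) mean shift of -0.15 on gradient 1;
* CHR-P: somatomotor (SMN) mean shift of +0.25 on gradient 1;
* ROD: within-network dispersion of DAN and VAN scaled by 0.6
  (applied about each network's coordinate-wise median, so the planted
  within-network dispersion scales exactly by the factor), and a
  gradient-1 range reduction implemented as *tail compression*:
  deviations beyond the 80th percentile of |score - mean| continue
  with slope 0.5.

Two of these choices deserve explanation. First, planting the SMN and
VAN shifts in the same group makes them interfere: the embedding
responds globally to local perturbations, and in development runs the
two opposing shifts partially cancelled through the map's global
re-equilibration. Second, the range effect is tail compression rather
than a global multiplicative shrink because a global shrink changes
all pairwise latent distances, which raises the affinity eigenvalues;
under the `lambda/(1-lambda)` diffusion-time scaling the resulting
amplitude inflation can cancel -- or even reverse -- the planted range
reduction and contaminate the other gradient's range. Compressing only
the tails targets exactly what the range metric measures while leaving
the bulk geometry, and hence the spectrum, essentially unchanged.

Effect magnitudes are free parameters of the generator: the source
study design reports effect sizes only on the order of eta^2 ~ 0.01,
which is far below what a ~100-subject smoke-scale cohort can resolve,
so the defaults are calibrated to be recoverable at that scale instead
and are not asserted to match any published magnitude.

## Numerical and statistical choices

* **Thresholding ties** at the k-th value keep the lowest parcel id
  (deterministic across platforms); the diagonal is excluded from
  selection and from cosine norms.
* **Disconnected graphs** (two eigenvalues at 1 within 1e-10) are an
  error: they signal over-aggressive thresholding.
* **Sign convention**: each embedding column is flipped so its
  largest-magnitude entry is positive; Procrustes then resolves
  residual reflections.
* **ComBat**: the classic parametric formulation, iterated conditional
  posterior updates to a relative tolerance of 1e-4. The
  empirical-Bayes shrinkage preserves feature grand means and
  idempotence only up to a fraction of the per-feature sampling error
  (exactly as the reference implementation does); the `eb = FALSE`
  least-squares branch restores grand means exactly and is exactly
  idempotent. Singleton sites are an error -- such subjects must be
  excluded, as a site whose parameters cannot be estimated cannot be
  corrected.
* **Mann-Whitney**: midrank ties; exact enumeration for pooled
  n <= 12 computes the two-sided p as the probability of a U at least
  as far from `n_a n_b / 2` as observed (the exact distribution is
  symmetric); the approximate branch applies tie and continuity
  corrections.
* **FDR families** are declared explicitly: per gradient x contrast
  for parcel maps; per metric family x contrast for network tests
  (network means per gradient, within-dispersion, between-dispersion,
  range); per correlation matrix for clinical analyses; per
  association table for receptor tests.
* **Spin nulls**: nearest-neighbour reassignment (duplicates allowed)
  is the default for speed; a greedy one-to-one variant is available.
  Rotations are Haar-uniform via QR with sign fixing. The smooth-map
  generator used for calibration draws i.i.d. coefficients on an
  orthonormal real spherical-harmonic basis (l = 1, 2) plus a small
  rough component, evaluated on hemisphere-canonical coordinates; both
  properties matter, since exchangeability of spun copies requires a
  rotation-invariant, mirror-consistent map law. Calibration
  simulations in the test suite hold the type-I error of
  `spatial_correlation_test()` at alpha = .05 within Monte-Carlo
  tolerance of the nominal level.
* **Null-calibration scope.** The global-null check asks that the five
  planted-effect comparisons stay clean (no q < .05) in at least 90%
  of 20 seeded null runs. The scope is deliberate: a whole-run "zero
  findings anywhere" requirement is unattainable for *any* correctly
  calibrated implementation, because with ~20 BH families at
  alpha = .05 the probability of a completely clean run is roughly
  0.95^20 ~ 0.36 (each family's BH under its global null is a Simes
  test with familywise error alpha). The per-family and whole-run
  multiplicity behaviour is exercised in the test suite.

## Open design points, resolved

* Whether thresholding keeps signed-largest or absolute-largest
  values: signed-largest, matching the common toolchain convention; at
  10% density negative edges are effectively discarded.
* Whether the control mean FC is averaged before or after Fisher z:
  the Fisher-z matrices are averaged.
* Whether group membership is preserved in the ComBat design: yes by
  default (standard practice, so disease effects are not removed),
  switchable.
* Whether metrics are computed from harmonized scores: yes, and the
  metric table can be harmonized again (`harmonize_metrics`).
* Correlation type for clinical screens: Spearman, consistent with the
  rank-based group tests; Pearson available.
* Which map is spun in the association test: the t-map, switchable.

## What passing tests do and do not show

The generator produces stationary Gaussian time series with a known
covariance; real rs-fMRI has autocorrelation, motion artefacts,
non-Gaussian tails and vastly richer spatial structure. The synthetic
receptor maps are smooth random fields, not measured PET tracer maps
(files derived from them are labelled synthetic). Group effects are
planted directly in gradient geometry, so recovering them validates
the *pipeline machinery* -- embedding fidelity, alignment,
harmonization, test calibration -- not any clinical claim. At smoke
scale the embedding's global response to a local perturbation also
produces collateral shifts in unperturbed networks; the recovery
checks therefore assert that planted comparisons dominate their own
FDR families, not that collateral effects vanish. On the synthetic
geometry gradient 2 (longitude) has no network polarity, so the
convenience labels from `label_gradients()` are only meaningful for
gradient 1.

Problem sizes used throughout the tests and the acceptance script --
100-200 parcels, 20-107 subjects, 200 volumes, 500-1000 spins, 20
replicate runs -- were chosen as the smallest sizes at which each
property is comfortably resolved by Monte-Carlo; all scale linearly
upward through the configuration objects.
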