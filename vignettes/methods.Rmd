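---
title: "Methods: landmark morphometrics of the larval zebrafish face"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark morphometrics of the larval zebrafish face}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, conventions and numerical choices
behind `fishface`, in the spirit of the methods sections of the mature
morphometrics toolkits.

## The landmark system

The default schema places 26 landmarks on the rostrally imaged larval
face: 4 on the midline (glabella, labiale superius, labiale inferius,
gnathion) and 11 bilateral pairs (frontotemporale, olfactory placodes,
medial and lateral eye canthi, zygia, superior and inferior neuromasts,
crista philtri, chelion, oral laterals, gonion). Eight landmarks — just
under a third of the total — sit on the oral cavity, because mouth shape
is both geometrically complex and disproportionately affected in
craniofacial phenotypes; concentrating landmarks there buys resolution
where variation is expected. The sided structure is formalized as a pair
involution (every left landmark names its right partner and vice versa),
which the object-symmetry machinery relies on. The schema is data, not
code: it ships as a YAML file and custom schemas (different landmark
counts, e.g. for lateral views) are accepted anywhere, provided the
involution holds.

Coordinates follow the ImageJ convention: origin top-left, y increasing
downward. All measurements are defined by absolute values or symmetric
formulas, so no reported quantity depends on this orientation; wireframe
rendering flips y so faces are drawn upright. Computations run in the
input units (pixels by default); a dataset records one unit for all its
specimens, and mixing units is an error rather than a silent conversion.

The exact anatomical identity of sided landmarks in published usage is not
fully specified in accessible sources; the shipped schema is therefore a
reconstruction consistent with the named landmark families, and the
catalog marks each measurement's provenance (`named` vs `reconstructed`)
so users can audit or replace definitions without touching code.

## The measurement catalog

The 39 default measurements comprise 22 distances, 8 angles (the vertex is
always the second listed landmark — the catalog convention resolving the
ambiguity of "the angle of the connecting point"), 3 polygon areas and 6
composites. Areas use the shoelace formula for any number of vertices; for
triangles this is exactly the classical determinant formula, and the
generalization covers the mouth polygon (8 vertices). Composites are sums,
means, or absolute left-minus-right differences of previously defined
features; the catalog loader rejects forward references, so evaluation
order is well defined. Angles are computed via the law of cosines with the
cosine clamped to [−1, 1], making collinear configurations return exactly
0° or 180° instead of NaN.

Per-feature group statistics use the classical fixed-effects one-way ANOVA
(no Welch correction, matching common practice in prism-style analyses)
with Tukey HSD post hoc tests, and a Bonferroni familywise correction at
α/n_features. For the default α = 0.05 and 39 features the threshold is
0.05/39 = 0.001282…, displayed rounded to five decimals (0.00128) but
compared at full precision.

## Feature-space multivariate analysis

PCA is an exact eigendecomposition of the covariance (`raw`) or
correlation (`zscore`) matrix. Component signs are fixed by making the
largest-magnitude element of each loading vector positive, so results are
bit-reproducible across platforms. Kaiser retention uses the dual rule:
eigenvalue > 1 for correlation PCA, eigenvalue ≥ mean eigenvalue for
covariance PCA (the ≥ resolves the all-equal tie case in favour of
retention). Varimax rotates the retained orthonormal loading block with
Kaiser row-normalization (the `stats::varimax` default); rotating the
orthonormal block — rather than eigenvalue-scaled loadings — keeps the
rotated loadings orthogonal and conserves communalities and the block's
total variance, which are the invariants the tests check. Rotated
components are reordered by explained variance and re-sign-fixed.

The PC-score classifier is a logistic regression of a two-level group on
selected scores. For a single score the decision threshold −β₀/β₁ (the
score where the fitted probability crosses 0.5) is reported, mirroring the
practice of quoting a single PC cutoff for mutant classification. Perfect
separation is detected from the glm convergence warning and handled by a
small ridge-penalized Newton refit (penalty 0.01, intercept unpenalized),
flagged in the result; no Wald p-value is reported for penalized fits.

## The Procrustes engine

All 2D superimposition is implemented over complex numbers: a
configuration is a complex vector z, rotation is multiplication by a unit
phase, and the optimal rotation aligning z to a consensus c is the closed
form z·conj(s)/|s| with s = Σ z_j·conj(c_j). This is exact (no iterative
rotation solve), excludes reflections by construction, and makes the
permutation loops fast. GPA centres each configuration, scales to unit
centroid size, and iterates rotation-to-consensus until the consensus
changes by less than 1e-10 (cap 100 iterations; typical convergence is 3–5
iterations). The final consensus is aligned to its principal axes with a
deterministic 180° disambiguation (the landmark farthest from the centroid
gets positive x). Orthogonal tangent projection at the consensus is on by
default; it is what makes exactly four shape dimensions (two translations,
scale, rotation) carry zero variance, an identity the shape-PCA tests
assert at 1e-12 of the leading eigenvalue. Distances between mean shapes
are always reported as Procrustes distances — the square root of the
summed squared differences between optimally superimposed unit-size
shapes — computed in shape space, not tangent space.

Object symmetry follows the reflected–relabelled-copy construction: each
specimen enters a joint GPA together with its mirror image (x negated,
left/right labels swapped). Because the joint set is closed under this
reflection, its consensus is symmetric; the implementation symmetrizes it
exactly — including a half-angle rotation that places the mirror axis
vertically — before a final alignment pass. The symmetric component is
then the average of a specimen's two aligned copies and is bilaterally
symmetric to numerical precision; the asymmetric remainder reconstructs
the aligned original exactly and is odd under the reflection. No
principal-axes turn is applied here, since a 90° turn would map the mirror
axis onto the horizontal and break the pairing symmetry.

CVA and DFA operate on the tangent-space coordinates projected onto the
principal components spanning the covariance rank (eigenvalue >
1e-10 × the largest), further capped at n − g dimensions so the pooled
within-group covariance is invertible; a singular covariance after
reduction is an error advising more specimens. Canonical axes come from
the symmetric whitened between-group eigenproblem. Mahalanobis distances
between group means use the pooled within-group metric; note that with
group sizes near the landmark count this metric is estimated at its rank
limit and distances inflate by the classical inverse-Wishart factor
√((n−g)/(n−g−r−1)) — the tests verify the analytic limit after this
correction, and practical guidance remains that n per group should exceed
the landmark count. Permutation tests shuffle group labels (within the
pair, for pairwise CVA statistics), recompute the statistic — including
the within-group covariance for Mahalanobis — and use the (b+1)/(n_perm+1)
estimator, so p is never zero and the smallest reportable p at the default
n_perm = 10,000 is 1/10,001. Seeds are mandatory and recorded. Across the
pairwise DFA comparisons the pipeline applies a Bonferroni correction at
α divided by the number of pairs.

## The synthetic-data generator

The generator is the package's study-design surrogate: a bilaterally
symmetric face-like template (300 units wide, mouth landmarks on a convex
ellipse) plus named, zero-net-translation, symmetric deformation presets
(`mouth_elongation`, `face_narrowing`, `stage_3to4`, `mutant`). A
specimen is template + effect-scaled preset + symmetric individual
variation (mirrored per pair; midline landmarks vary in y only) +
fluctuating-asymmetry noise (+ an optional explicit directional-asymmetry
field), then a random similarity pose, then isotropic digitization noise.
Default magnitudes emulate a typical confocal study: digitization error 2
units (≈0.7% of face width), individual variation 3 units, fluctuating
asymmetry 1 unit, pose jitter ±10° rotation, ±10% scale, ±20 units
translation (mounting variation that careful protocols reduce but never
eliminate), and group sizes near 30. Ground truth (true group mean shapes
and their Procrustes distances) is emitted with every dataset, and tests
compare against it rather than re-deriving truth from the sample.

What the generator does not emulate: correlated landmark-placement errors
(a user mislocating a whole structure), stage-dependent allometry,
non-Gaussian outliers, and the image-segmentation step itself. Passing
tests therefore demonstrate calibration and power under the assumed noise
model, not robustness to systematically mislabelled real images — the
validation report (`validate_dataset`) exists precisely to catch the
gross versions of those errors (side swaps, outliers, duplicates).

The latent-factor feature generator produces 39 features from 6 orthogonal
factors with simple structure and unit noise. Factor 1 carries about a
third of the features (mirroring the mouth's share of the landmarks) so
the leading principal component estimates it cleanly even at n = 60 —
with equally sized blocks the factor eigenvalues nearly tie and the
leading eigenvector mixes factors at these sample sizes, which is an
estimation artefact, not a property of the classifier under test. With
loading 3 and unit noise, communalities are 0.9, block eigenvalues sit
near 13 and 4.6 and the residual eigenvalues near 0.1, so Kaiser retention
returns exactly 6 robustly. A group displaced by δ on factor 1 has Bayes
accuracy Φ(δ/2).

## Problem sizes and numerical conventions in the test suite

The suite runs the null calibration of the DFA permutation test at 500
simulated null datasets (n = 20 per group, 999 permutations), the CVA
size check at 150 datasets (99 permutations), the feature-ANOVA size
check at 400 replicates × 3 features, the power/recovery analysis at
n = 30 per group with the mouth displacement at five times the
digitization noise, and asymmetry recovery at n = 100 with digitization
noise at one fifth of the injected effect — sizes chosen to keep
Monte-Carlo error well inside the asserted tolerance bands (±3 binomial
standard errors for rates; 10% relative for recoveries). Oracle
comparisons use independent implementations: a rotation-grid search for
Procrustes distances, permutation re-implementations for ANOVA/Tukey
p-values, `vegan::procrustes` and `MASS::lda` as external cross-checks.

Degenerate inputs are errors, not warnings: all-collinear configurations
(GPA), constant features under z-scoring, catalogs referencing missing
landmarks (rejected at load, not per specimen), groups below the minimum
size. Ties and sign conventions (PCA signs, principal-axis 180°, Kaiser
ties) are all resolved deterministically so that identical inputs and
seeds yield bit-identical outputs.

## Limitations

2D landmarks only; no semilandmarks, no thin-plate-spline deformation
grids, no Euclidean distance-matrix analysis, no 3D. The Mahalanobis
metric degrades gracefully but noticeably when group sizes approach the
landmark count (see above). The shipped catalog reconstructs measurement
definitions where published naming is incomplete; real-data measurement
values therefore depend on the user confirming the catalog against their
own landmarking protocol.
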