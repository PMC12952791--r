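---
title: "ethokit: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ethokit: models, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

ethokit reimplements, as a library and CLI, the computational core of a
pose-based behavior phenotyping workflow for the laboratory mouse: keypoint
features, sparse-label classifier training, ethogram post-processing,
bout-level agreement via a bipartite graph, strain-level aggregate
phenotypes, and a set of quantitative-genetics utilities. This vignette
records the models it implements, the conventions it fixes, and the design
choices made where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## Pose representation and features

A `PoseSequence` holds 12 keypoints per frame (nose, ears, base neck,
forepaws, mid spine, hind paws, base tail, mid tail, tip tail) with
per-keypoint confidences, at a stated frame rate (default 30 fps, emulating
an 800 x 800 px top-down open-field recording). The keypoint ordering is a
package convention: the upstream platform does not publish one, so it is
documented once here and embedded in the HDF5 dialect
(`/poseest/points`, `/poseest/confidence`, attributes `fps` and
`keypoint_names`). Coordinates use the standard image convention: origin
top-left, x rightward, y downward, pixels, frames indexed from 0.

Low-confidence keypoints (below 0.3 by default) are linearly interpolated
across gaps of at most 5 frames; longer gaps mark frames invalid rather
than inventing coordinates. Interpolating short dropouts preserves bout
continuity downstream; 5 frames is a sixth of a second at 30 fps, short
relative to any bout the classifiers target.

The per-frame feature set is fixed in code (89 features): all 66 pairwise
keypoint distances, 12 keypoint speeds, centroid speed, the body-axis
heading (base tail to base neck) with its angular velocity, and 8 internal
joint angles. Velocities are reported per second (scaled by fps) so feature
values are comparable across frame rates. The original platform defers its
full feature list to supplementary material that is not reproduced here, so
equivalence with that exact set is not claimed; the documented stand-in
spans the same families (distances, linear and angular velocities) and is
embedded in every exported classifier archive for portability.

Window features append, for each base feature, its mean, standard
deviation, minimum, maximum, and median over frames `[t - w, t + w]`.
Windows clamp at the sequence ends and derivatives fall back to one-sided
differences there, so every frame keeps a feature row and ethograms align
1:1 with frames. Invalid frames are excluded from windows (the current
frame is always kept so rows stay finite).

## Ethograms, bouts, and post-processing

Label tracks are ternary: behavior, not-behavior, or unlabeled. Bouts are
maximal runs of behavior frames with 0-based inclusive ends. Unlabeled
frames break bouts in ground-truth tracks; classifier predictions are
always binary — a documented asymmetry.

Post-processing is stitch *then* filter, in that order. Stitching merges
neighboring bouts whose gap (count of non-behavior frames between them) is
*strictly* less than the threshold, transitively, which equals morphological
closing on the frame track; the test suite checks that equivalence against
a brute-force oracle. Filtering keeps bouts of at least the minimum length.
Both operations are idempotent in combination, stitching never decreases
behavior frames, and filtering never increases them. No default thresholds
are imposed: the source workflow selects them per behavior by a
hyperparameter scan, which `scan_stitch_filter()` provides.

## Frame metrics and the ethograph

Frame-level statistics (confusion counts, accuracy, precision, recall, F1,
Cohen's kappa) are computed over frames labeled in both tracks. Degenerate
conventions: F1 is 0 when precision + recall is 0; kappa is 1 for two
identical constant tracks and 0 for two different constant tracks. ROC
curves are traced over unique score thresholds (ties cross simultaneously),
AUROC is the trapezoidal integral, and TPR at an FPR budget takes the "at
most" reading: the best TPR among curve points with FPR no larger than the
budget.

The ethograph is a bipartite graph whose sides are the bout lists of two
annotators or classifiers. Three choices here are interpretations, fixed
and documented because the source material motivates but does not fully
specify them:

* **Edge weight** is interval intersection-over-union. "Fraction of bout
  overlap" never states a denominator; IoU is the symmetric choice the
  motivating detection literature uses.
* **Per-bout overlap** is the maximum weight over incident edges (0 for a
  missed bout) — the standard detection-matching convention when a bout
  overlaps several partners.
* **Agreement** is the mean of the two per-side fractions of bouts whose
  best overlap strictly exceeds the threshold `w*` (0.5 unless stated), so
  the statistic is symmetric under swapping annotators. Two empty tracks
  agree perfectly (1); an empty side is vacuously in agreement, so
  empty-vs-nonempty scores 0.5.

Agreement is monotone non-increasing in `w*`; the scan over (stitch,
filter, `w*`) grids reports the full table and the argmax.

## Classifiers

Training data are per-video (feature matrix, ethogram) pairs; only labeled
frames on valid pose frames are used, and a fit requires at least 100
labeled frames across at least 2 videos with both classes present. The
environment this package targets ships no tree-ensemble library, so the
ensembles are implemented natively on a single histogram-based
regression-tree learner (at most 256 quantile bins per feature, the
split-finding strategy of modern boosting libraries):

* `random_forest` — bagged probability trees, per-node feature subsampling
  (`sqrt(p)`), leaf = class fraction; 100 trees, depth cap 25.
* `gradient_boost` — Newton boosting on logistic loss, depth 3, learning
  rate 0.1, 100 trees (scikit-learn-flavored defaults).
* `xgboost` — Newton boosting with L2 leaf regularization (lambda 1), depth
  6, learning rate 0.3, 100 trees (xgboost-flavored defaults).

All randomness flows through R's RNG, so a seed makes training,
cross-validation splits, and prediction exactly reproducible.
Cross-validation folds are grouped by video — consecutive frames are highly
correlated, and frame-level splits would leak temporal context between
train and test. The decision threshold is fixed at 0.5;
stitching/filtering is the sanctioned post-processing path rather than
threshold tuning. Class imbalance can optionally be addressed with
inverse-frequency sample weights (off by default). Classifier archives are
single JSON files embedding the algorithm, window size, feature list,
behavior name, training summary, and serialized trees; import reproduces
predictions exactly.

## Aggregate phenotypes and strain statistics

Each behavior yields nine aggregate phenotypes: {total duration (minutes),
bout count, mean bout length (seconds)} x {first 5, 20, 55 minutes}. The
bin-boundary convention is stated and tested rather than inherited: a bout
belongs to a bin when its onset falls in the bin; duration truncates at the
boundary; mean bout length uses the full lengths of the bouts counted. The
unit of mean bout length (seconds) is a package choice; the source leaves
it implicit.

Strain-level z-scores average animals within strain, then standardize each
phenotype across strains with the sample (n-1) standard deviation — the
formula as published does not specify the divisor, so the choice is
documented and the worked example in the tests pins it. Masking flags
`|z| > 1` by default. Sex effects use the Wilcoxon rank-sum test (the
natural reading of "nonparametric rank test") per (strain, phenotype) cell
with at least two animals per sex, Benjamini-Hochberg correction across all
tested cells, `-log10(p)` as the score, and signed rank-biserial
correlation as the effect size. Dataset imbalance metrics (SI, GI, AGI)
follow their defining formulas exactly.

## Genetics

Genotypes are inbred di-allelic calls coded 0/1 with missing allowed. QC
retains SNPs with minor allele frequency at least 0.10 and missingness at
most 0.05, then mean-imputes the surviving missing calls (the source is
silent on imputation; mean imputation is the conventional default for
moment-based estimators).

The association engine is deliberately a fixed-effect least-squares scan
(genotype plus optional covariates — sex, weight, coat color — with Wald
p-values). The mixed-model engine used upstream is an external binary; the
content this package owns (QC, permutation thresholds, the power recipe,
effect-size formula, LD grouping) is engine-agnostic, and the `ScanResult`
contract allows an LMM engine drop-in. Permutation thresholds shuffle the
phenotype, record each permutation's minimum p, and take the empirical
alpha-quantile without smoothing — the "corrected p-value of 0.05" reading.

The GWAS power simulation follows the standard recipe: prefilter SNPs at
nominal p < 0.05 against the base phenotype, sort by position, pick evenly
spaced causal SNPs, add an effect of size
`sqrt(PVE * Var(y) / (AF * (1 - AF)))`, re-scan, and report the detected
fraction. Greedy QTL grouping starts at the smallest-p unassigned
significant SNP and extends contiguously along the chromosome, stopping per
direction at the first SNP with `r^2` to the peak below 0.2; whether the
original procedure allows skipping low-correlation SNPs inside a block is
unstated, so strict contiguity is implemented and flagged.

Heritability and genetic correlation are Haseman-Elston regressions on the
GRM (`K = ZZ'/M` with population-scaled standardized genotypes, so the mean
diagonal is exactly 1): the slope of off-diagonal phenotype cross-products
on off-diagonal kinship, clamped to [0, 1]; the cross-trait slope
normalized by the geometric mean of the two single-trait slopes gives rg,
undefined (flagged NA) when either slope is non-positive. These are
moment-based substitutes for the REML estimates used upstream: testable at
desk scale, unbiased under the simulated architecture, with larger sampling
variance than REML.

## What the synthetic generators emulate — and what they do not

`synth_pose` drives a rigid 12-keypoint mouse through a semi-Markov
alternation of idle stretches and scripted bouts: turns rotate the body
axis at a stated angular speed (default 2 rad/s), grooming holds the
centroid still with 7 Hz nose/forepaw oscillation (the generator enforces
the sampling-rate guard: oscillation below fps/2), rearing contracts the
outline. Keypoint jitter defaults to 0.3 px, the sub-pixel error scale of a
modern pose estimator; the end-to-end acceptance scenario deliberately uses
2 px — the upper end of realistic pose error — so that per-frame features
are noisy and temporal windows have information to add. Idle motion is a
gentle meander (about 0.1 rad/s heading wander) with smooth steering away
from walls, so no idle kinematics masquerade as turning.

These kinematics are deliberately simple. They make scripted behaviors
separable in the documented feature space, which is what the tests need;
they do not model biomechanics, posture variability across strains, social
context, or pose-estimation failure modes beyond confidence dropout. A
green end-to-end test therefore establishes that the pipeline is wired
correctly and that the learners can exploit kinematic structure — not that
any classifier reaches a particular accuracy on real mice.

`synth_annotator_pair` reproduces the two artifact families the agreement
framework targets: systematic boundary dilation/jitter (one annotator
labeling more frames per bout than the other) and spurious 1-3-frame
bouts. False bouts are placed at least two frames clear of true behavior so
they remain short, distinct, and exactly removable by filtering — which
gives the stitch/filter tests a constructive oracle.

`synth_panel` builds inbred strain genotypes (optionally in LD blocks
sharing a founder haplotype), a genetic value from a scripted causal set
scaled to variance h2, and animal phenotypes with residual variance 1 - h2.
Default shape (60 strains, ~10 animals each) mirrors a large strain survey;
recovery tests use 200 strains x 1 animal for estimator calibration.

## Numerical choices and degenerate inputs

* Strict inequalities where the source wording says "less than" (stitch
  gaps) and "greater than" (bout overlap vs `w*`).
* Empty-graph conventions for bout agreement as above; F1 and kappa 0/0
  cases as above.
* Zero-variance z-score columns return z = 0 with a degenerate flag rather
  than NaN.
* Constant SNPs scan to p = 1 with a flag; exact fits produce the smallest
  representable p rather than dividing by a zero standard error.
* HE slopes are clamped ([0,1] for h2, [-1,1] for rg) after estimation; the
  raw slope is preserved as an attribute.
* Window statistics always include the current frame, so no row of a
  feature matrix is empty even inside long pose gaps.

## Known limitations

* The feature set is a documented stand-in, not the upstream supplementary
  list; trained classifiers are not interchangeable with upstream archives.
* The association scan ignores population structure; on real strain panels
  a kinship-aware engine should be dropped in before interpreting p-values.
* Haseman-Elston estimates have higher variance than REML; at 200 strains a
  single h2 draw has a standard deviation near 0.2 (the estimator is
  unbiased, and the acceptance tests bound the mean error over 50
  replicates by 0.1).
* Multi-animal pose files, multi-class ethograms, and probabilistic (HMM)
  smoothing are out of scope.
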