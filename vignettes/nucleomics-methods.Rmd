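---
title: "Methods: nuclear morphometry and multi-omics integration for NSCLC"
author: "NucleoMics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclear morphometry and multi-omics integration for NSCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The pipeline

NucleoMics implements an end-to-end analysis for non-small-cell lung
cancer that joins three data channels per patient — nuclear morphometry
measured on H&E histology tiles, encoded clinical characteristics, and
gene-level genomic factors (copy-number classes, somatic-variant synonymy
classes, mRNA expression) — into one per-nucleus design matrix, screens
factors by Pearson correlation with the task label, and trains tuned
classifiers for two tasks: subtype discrimination (LUAD vs LUSC) and
overall-survival status at 1, 2 and 3 years.

The stages, and the functions that implement them:

1. **Tile preparation** (`tileImage`, `isBlank`, `histogramMatch`) —
   fixed-size tiles in row-major grid order, blank-tile exclusion, and
   per-channel histogram matching to a reference image for stain
   normalization.
2. **Nucleus segmentation** (`trainSegmenter`, `predictSegmenter`,
   `binarizeAndLabel`) — a compact U-shaped encoder–decoder produces a
   per-pixel foreground probability; 8-connected components of the
   thresholded map become nucleus instances.
3. **Quality filtering** (`otsuThreshold`, `filterInstances`) — per tile,
   Otsu cuts on the instance area and compactness histograms remove
   fragments: instances with area strictly below the area threshold or
   compactness strictly above the compactness threshold.
4. **Feature extraction** (`extractFeatures`) — the 20-feature nuclear
   vector per retained instance.
5. **Assembly** (`encodeClinical`, `survivalLabel`, `cnvCode`, `snvCode`,
   `balancePatient`, `splitPatients`, `assembleDataset`) — factor
   encoding, balancing to 200 rows per patient, patient-level 60/20/20
   splitting.
6. **Screening** (`screenFactors`) — retain factors with |r| > 0.05 and
   p < 0.05 against the task label.
7. **Modeling** (`searchSpace`, `tuneModel`, `runExperiment`) — tune each
   classifier family on validation accuracy, refit on the training
   partition, evaluate once on the test partition.

A synthetic cohort generator (`cohortSpec`, `generateCohort`,
`renderTile`, `simulateFeatureCohort`, `writeCohort`) emulates all six
inputs with a plantable class signal so the whole pipeline runs and is
verified at desk scale.

# The 20 nuclear features

For a nucleus with pixel set $S$, area $A = |S|$ and perimeter $P$:

* **Color (6):** per-channel mean and population variance of the RGB
  values inside $S$, measured on the histogram-matched tile.
* **Morphology (12):** $A$; $P$; circularity $4\pi A / P^2$ (1 for a
  disc); compactness $C = P^2/A$ (minimal, $4\pi$, for a disc; higher
  for irregular shapes); eccentricity $E = \sqrt{a^2-b^2}/a$ of the
  moment-equivalent ellipse; and the seven Hu invariants $\varphi_1
  \ldots \varphi_7$ built from normalized central moments
  $\eta_{pq} = \mu_{pq} / \mu_{00}^{(p+q)/2+1}$.
* **Texture (2):** mean and population variance of the diagonal detail
  subband (cD) of a one-level 2-D discrete wavelet transform of the
  masked, grayscale bounding-box patch.

Choices the definitions leave open, fixed here:

* **Perimeter estimator.** $P$ is the arc length of the closed outer
  boundary walked through boundary-pixel centers (unit steps for axis
  moves, $\sqrt2$ for diagonal moves; Moore-neighbor tracing; interior
  holes filled first). A rasterization study with the package's own
  ellipse renderer shows this walk overestimates the perimeter of smooth
  discs by roughly 4–6% at radii 15–45 px, so measured circularity of
  round nuclei sits near 0.90–0.95 rather than 1.0, and measured
  compactness slightly above $4\pi$; for small or jagged shapes the walk
  can also *under*-estimate (a 5×5 square has $P=16 < 20$), so discrete
  circularity may exceed 1. All shape tests use tolerances derived from
  this study. The product identity Circularity × Compactness $= 4\pi$
  holds exactly by construction.
* **Moments on the silhouette.** Hu invariants and eccentricity are
  computed on the binary silhouette, not intensity, since they are
  morphology descriptors. Coordinates are taken relative to the
  silhouette bounding box, which makes translation invariance exact in
  floating point; rotation/scale invariance holds to raster tolerance
  (1% relative for shapes of a few hundred pixels, checked at 90° where
  the lattice is exact).
* **Eccentricity construction.** $a \ge b$ are the semi-axes of the
  ellipse with the same second central moments as the silhouette
  (eigenvalues of the second-moment matrix); for degenerate silhouettes
  (single pixels, 1-px lines) the minor eigenvalue is clamped at a small
  positive value and the result flagged.
* **Wavelet.** Haar (db1), one level, computed per nucleus on the masked
  bounding-box patch by default; a per-tile scope is available
  (`scope = "tile"`), since the definition is ambiguous about whether
  texture is a nucleus or a tile property. Odd-length signals are
  extended by repeating the final sample.
* **Variances** are population variances (divide by $N$) throughout.
* The Hu formulas follow the standard invariant set; two of the commonly
  reprinted fourth- and seventh-invariant expressions circulate with
  bracketing typos, so every value is verified against a naive
  double-loop evaluation of the defining sums in the tests.

# Segmentation and the adaptive quality filter

The segmenter is a deliberately small U-shaped fully-convolutional
network implemented natively in R: per level one 3×3 convolution + ReLU,
2×2 mean pooling between levels, nearest-neighbor upsampling with skip
concatenation on the way up, a 1×1 sigmoid head, trained with Adam on
pixel-wise binary cross-entropy. Defaults are 4 levels and 16 base
channels; the tests and the acceptance script use 3 levels and 8 base
channels on 64-px tiles, which trains in well under a minute on one CPU
while reaching Dice ≥ 0.9 on held-out synthetic tiles. Training is
deterministic given the config seed; checkpoints round-trip through
`saveSegmenter`/`loadSegmenter`.

Fixed post-processing choices: probability threshold 0.5 (configurable);
8-connected foreground components; Otsu on 64 equal-width bins spanning
the observed range of each feature, ties broken toward the smallest
threshold; strict inequalities in the filter, so boundary-equal
instances are kept. If a feature is degenerate (all values equal), that
criterion is skipped with a message and the other still applies — with
both degenerate, everything is kept.

Two practical notes on the filter's behavior. First, Otsu always finds a
cut: on a tile whose instances are homogeneous (as pure synthetic
renders are) the filter will split them anyway, and because the kept set
is the *intersection* of the area rule and the compactness rule it can
legitimately be empty. The filter earns its keep on real segmenter
output, where debris is small *and* irregular. Second, with the
boundary-walk estimator very small compact specks (2×2) can have
discrete compactness below $4\pi$, so tiny round debris is caught by the
area rule, not the compactness rule.

# Factor encoding and assembly

Clinical strings map to integers over closed vocabularies
(case-insensitive): sex 1/2; race 0–4 with anything unmapped becoming 0
("Unreported" — the only field with a fallback); T1–T4 → 1–4 and TX → 5;
N0–N3 → 1–4 and NX → 5; M0 → 1, M1 → 2, MX → 5; Stage I–IV → 1–4. Any
other unmapped value is an error naming the field and value.

Survival labels at horizon $h \in \{365, 730, 1095\}$ days (the day
counts are a package choice): death before $h$ → 1; survival to $h$ or
beyond → 2; alive but censored before $h$ → 0 ("unknown"). Unknown rows
are kept as a third class by default (`dropUnknown = FALSE`), matching
three-class confusion reporting; they can be excluded.

CNV amplitudes discretize as $t<0.1 \to 0$, $0.1<t<0.9 \to 1$,
$t>0.9 \to 2$; the defining intervals are open, so the boundary values
0.1 and 0.9 are assigned to the lower class by a documented tie rule.
Somatic variants binarize by a closed two-list vocabulary
(non-synonymous → 1, synonymous → 0); unlisted classifications error
rather than silently coding 0. mRNA values pass through unchanged.

The gene panel is the 27 recurrently mutated genes shared by the two
subtypes; the default factor panels take the first 15 for CNV and first
26 for mRNA (both arguments), giving the documented design widths: 20
nuclear + 26 mRNA = 46 columns for the subtype task, and 20 + 7 clinical
+ 15 CNV + 27 SNV + 26 mRNA = 95 for the survival tasks.

Balancing draws exactly 200 rows per patient: a uniform subset without
replacement above the target, originals plus uniform duplicates below
it. Splitting is at patient level, stratified by subtype by default,
with validation and test taking $\lfloor 0.2 n \rfloor$ patients per
stratum and training the remainder. This remainder rule is chosen
because it reproduces the reference cohort arithmetic exactly: 525 + 727
patients yield 752/250/250 overall and 315/437 training patients per
subtype, hence 250,400 balanced records with 150,400 (63,000 LUAD) in
training. (The alternative "round the training fraction" rule misses the
437 by one.) Reported held-out compositions in the source material
(145/105 per split) are inconsistent with these totals — the arithmetic
gives 105 LUAD / 145 LUSC per held-out split — and the package follows
the arithmetic.

# Screening and modeling

Screening computes Pearson r and the two-sided t-test p-value of every
factor against the numeric task label and retains |r| > 0.05 with
p < 0.05. It runs on the training partition only (leakage hygiene; the
partition screened is configurable) and on per-nucleus rows by default —
matching the record-level structure of the balanced dataset — with a
patient-mean aggregation flag. Ordinal encodings (stage, T, N, M) are
treated as numeric. Degenerate (constant) factors are reported with a
flag, never silently dropped. The factor–factor correlation matrix is
attached, with |r| > 0.8 pairs flagged for heatmap annotation.

Four classifier families stand behind one adapter interface: gradient
boosted trees (xgboost), random forest (randomForest), AdaBoost
implemented here as SAMME / SAMME.R over depth-limited rpart weak
learners (no boosting package with both dialects is a package
dependency; the algorithm is ~80 lines and fully tested), and a
feedforward network via nnet. nnet trains a single hidden layer with
BFGS, so the two-layer (100, 100) configurations of stochastic-solver
MLPs map to single-hidden-layer sizes {50, 100} and the per-step
learning-rate parameters are not exposed; inputs are standardized inside
the adapter. The random-forest adapter maps `n_estimators` → `ntree`,
`min_samples_leaf` → `nodesize`, and caps `maxnodes` at `2^max_depth`
for shallow settings; `min_samples_split` has no randomForest
equivalent and is recorded but inert. Only one gradient-boosting dialect
is provided.

Tuning maximizes validation accuracy over the declared space —
exhaustively when the grid fits in the trial budget, otherwise by seeded
uniform sampling — and logs every trial. The chosen configuration is
refit on the training partition and evaluated once on the test
partition. Metrics: global accuracy; precision, recall and F1 per class,
macro-averaged (one-vs-rest) for both the 2-class and 3-class tasks so
the two tasks share one scheme; ROC by threshold sweep with trapezoidal
AUC, which equals the Mann–Whitney rank statistic and macro-averages
one-vs-rest for multiclass. Wall-clock fit time is logged but never
asserted, being hardware-dependent. Evaluation is per record (per
nucleus); a patient-level majority vote is easy to add on top of the
probability output but is not the default.

# The synthetic generator

`generateCohort` draws patients of both subtypes with: clinical strings
from the encoding vocabularies (sex skewed male in class 2, as in real
squamous cohorts); exponential survival with per-class rates (medians
about 3.0 and 2.3 years) and independent censoring (a censored patient
reports a uniform fraction of the unobserved event time; default
censoring 0.4); negative-binomial nuclei-per-patient counts centred at
200 (size 3), the balancing target; and three gene tables over the
27-gene panel — folded-normal CNV amplitudes, a 15% per-gene mutation
rate with classification strings drawn from the closed vocabulary, and
log-scale expression with gene-specific baselines. Patient counts
default to 525 + 727.

Nuclei are filled ellipses: log-normal major semi-axis (median 9 px),
truncated-normal axis ratio, uniform orientation, hematoxylin-purple
stain color, over an eosin-pink background with Gaussian pixel noise and
a uniform per-tile stain shift. Patient-level random effects on size,
shape and color induce the within-patient correlation that makes
patient-held-out evaluation meaningfully harder than row-held-out — the
reason the planted-signal experiments need ~200-patient cohorts rather
than 200 rows. Class-2 mean shifts (`classEffect`) plant the signal:
area and eccentricity in within-class SD units of the latent geometry,
color in 8-bit units, expression in SD units on a configurable subset of
genes. All four at zero give a null cohort in which any feature-based
classifier should sit at chance.

Rendering enforces non-overlap by rejection sampling with a separation
margin, so the ground-truth mask has exactly one 8-connected component
per placed nucleus; a tile that cannot fit the requested count reports
the shortfall explicitly. Ellipses give analytically known area,
perimeter (Ramanujan) and eccentricity, which is what makes the
renderer usable as a measurement oracle.

`simulateFeatureCohort` is the cohort-scale fast path: it draws the
same latent geometry/color parameters and converts them to the
20-feature vector analytically (even Hu invariants from the ellipse's
normalized moments, odd ones near zero) with a small lognormal
measurement jitter standing in for rasterization. Screening and
modeling experiments use this path; the renderer-based path is
exercised end-to-end at tile scale in the segmentation and feature
tests. Note the two paths differ slightly in perimeter convention
(analytic Ramanujan vs boundary walk), which is irrelevant to the
class-separation structure.

What the generator does **not** emulate: realistic H&E texture and
chromatin structure, touching/overlapping nuclei, slide-level batch
effects beyond a uniform stain shift, coherent dependence of survival on
stage/age, or the real covariance of genomic factors. Passing tests
therefore demonstrate the pipeline's correctness and its ability to
recover planted effects under the stated noise model — not clinical
performance on real cohorts.

# Problem sizes and numerical choices

The test suite and acceptance script choose desk-scale problem sizes:
64–192 px tiles, 8-patient rendering cohorts, 12 training tiles and 25
epochs for the segmenter (3 levels, 8 base channels, learning rate
0.01 — the loss trace shows 15 epochs is not yet converged for some
initializations, 25 is), 200-patient cohorts with 30 nuclei per patient
for the screening/modeling recovery experiments, and 100 replicates for
the Monte-Carlo checks. The full suite runs in a few minutes on one CPU.

Other fixed numerical choices: Otsu tie-break to the smallest
maximizing edge; histogram-matching maps each value to the smallest
reference value whose CDF reaches the source CDF (making self-matching
the identity and the operation idempotent at 8 bits); blank tiles are
those with more than 90% of pixels having all channels ≥ 220 (both
configurable; the criterion has no reference definition, so it is a
documented package choice); grayscale for texture uses Rec. 601 luma;
random seeds thread through every stochastic step and library code
restores the caller's RNG state.

# Known limitations

* The segmenter is a compact native implementation intended for
  contract testing and desk-scale experiments, not a competitive
  large-scale trainer; it has no augmentation, batch norm, or GPU path.
* Touching nuclei are not split (no watershed); the generator
  deliberately never produces them.
* The filter's intersection rule can empty a homogeneous tile (see
  above); real use assumes debris-contaminated segmenter output.
* Survival in the generator depends on subtype only, so the 3-class
  survival tasks are learnable only through subtype-correlated factors.
* `min_samples_split` is inert in the random-forest adapter; only one
  gradient-boosting dialect is available; the tabular-attention and 1-D
  convolutional families are not implemented (the adapter interface
  accepts additional families).
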