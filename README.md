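# NucleoMics

Nuclear morphometry and multi-omics integration for lung cancer
subtyping and survival prediction.

## What it is for

Distinguishing the two major non-small-cell lung cancer subtypes —
adenocarcinoma (LUAD) and squamous cell carcinoma (LUSC) — and flagging
patients at high short-term risk are everyday clinical questions that
histopathology answers slowly and subjectively. NucleoMics implements a
reproducible pipeline for researchers working with TCGA-style inputs
(H&E tiles, clinical tables, GISTIC copy-number output, MAF variant
calls, expression matrices) that:

1. tiles and stain-normalizes histology images (per-channel histogram
   matching to a reference image);
2. segments cell nuclei with a compact U-shaped encoder–decoder and
   cleans the result with an adaptive per-image Otsu filter on instance
   area and compactness (`C = P²/A`; a disc attains the minimum `4π`,
   fragments score high);
3. measures 20 features per nucleus — RGB mean/variance, area,
   perimeter, circularity `4πA/P²`, compactness, moment-ellipse
   eccentricity `E = √(a²−b²)/a`, the seven Hu moment invariants, and
   the mean/variance of the diagonal (cD) subband of a one-level Haar
   wavelet transform;
4. encodes clinical factors (sex, race, age, T/N/M, stage) and
   survival status at 1/2/3 years (0 unknown / 1 death / 2 survival),
   discretizes CNV amplitudes (0: t<0.1, 1: 0.1<t<0.9, 2: t>0.9) and
   variant synonymy (non-synonymous = 1), and joins everything by
   patient id into per-nucleus records balanced to 200 rows per patient
   with a stratified patient-level 60/20/20 split;
5. screens factors by Pearson correlation with the label (keep |r| >
   0.05 and p < 0.05) and
6. trains and compares tuned classifiers (gradient boosted trees,
   random forest, AdaBoost SAMME/SAMME.R, feedforward network) with
   accuracy, macro precision/recall/F1, confusion matrices, ROC and
   AUC.

A first-class synthetic cohort generator emulates all six inputs —
rendered tiles with exact ground-truth masks and LabelMe-style polygon
annotations, plus clinical/CNV/SNV/mRNA tables — with plantable subtype
and survival signal, so every stage runs and is verified without any
data download.

## Worked example

```r
library(NucleoMics)

## a 40-patient synthetic cohort with the default class separation
spec <- cohortSpec(nPatientsClass1 = 20, nPatientsClass2 = 20,
                   nucleiMean = 60, nucleiDispersion = 5, seed = 7)
co <- generateCohort(spec)

## render one tile, emulate noisy segmenter output, quality-filter it
rt <- renderTile(co, 1, 12, seed = 3, tileSize = 192)
pred <- rt$mask
set.seed(1)
for (k in 1:8) {                      # thin diagonal fragments
  r <- sample(180, 1); c <- sample(180, 1)
  pred[cbind(r:(r + 5), c:(c + 5))] <- 1
}
ns <- filterInstances(binarizeAndLabel(pred, tileId = "demo"))
ns
#> NucleusSet demo with 19 instances
#>   kept: 10 | area thr: 112.3 | compactness thr: 20.15

feat <- extractFeatures(rt$tile, ns, patientId = "SYN-0001")
round(feat[1, c("Area", "Perimeter", "Circularity", "Compactness",
                "Eccentric", "Hu0")], 2)
#>   Area Perimeter Circularity Compactness Eccentric  Hu0
#> 1  131     41.21        0.97       12.97      0.73 0.17
```

The 19 labeled instances are the 12 rendered nuclei plus the planted
fragments; the adaptive thresholds (area ≥ 112.3 px, compactness ≤
20.15) drop the fragments and two undersized nuclei, and each kept
nucleus gets its 20-feature row — this one is a fairly round
(circularity 0.97), moderately elongated (E = 0.73) nucleus of 131 px.

```r
## assemble, screen, model (feature-level fast path at cohort scale)
ft <- simulateFeatureCohort(co, seed = 8)
ads <- assembleDataset(ft, co, task = "subtype", target = 60, seed = 9)
ads
#> AssembledDataset task = subtype : 2400 rows, 46 factor columns
#>   patients: 40 ( test:8, train:24, validation:8 )

sc <- screenFactors(ads)
sum(sc$retained)
#> [1] 29

rep <- runExperiment(ads, families = c("xgboost", "randomForest"),
                     budget = 4, seed = 10)
rep
#> EvalReport task = subtype
#>   xgboost      acc 0.7500  auc 0.8125  f1 0.7500  (0.02s fit)
#>   randomForest acc 0.8750  auc 0.8125  f1 0.8730  (0.14s fit)
```

The subtype design matrix has the documented 46 columns (20 nuclear +
26 mRNA); 29 factors pass the |r| > 0.05, p < 0.05 screen on the
training partition; both families are tuned on validation accuracy and
evaluated once on the 8 held-out test patients (480 records). At this
deliberately small cohort size the patient-held-out AUC of about 0.81
reflects the planted moderate effect; the acceptance script below runs
the calibrated 200-patient versions where the strong-signal AUC
exceeds 0.9.

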