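# nashudc

Distinguishing non-alcoholic steatohepatitis (NASH) from simple steatosis
on multi-sequence liver MRI, with histology (SAF score) as the reference
standard.

NAFLD patients need a non-invasive way to tell benign simple steatosis
from NASH, which progresses to fibrosis. `nashudc` implements two
independent MRI readouts of the same examination and the statistics to
compare them:

* **Conventional quantification** over nine circular liver ROIs:

  - relative liver enhancement
    `RLE = (PostSI − PreSI) / PreSI`
    between unenhanced and gadoxetic-acid hepatobiliary-phase T1
    (hepatocyte dysfunction lowers RLE), and
  - dual-echo chemical-shift fat fraction
    `FF = (SIin − SIopp) / (2·SIin) × 100`
    (steatosis raises FF),

  plus the clinical panels FIB-4, NFS, ALBI and APRI.

* **Unsupervised deep clustering (UDC)**: 16×16 texture patches inside
  the liver mask are embedded by a convolutional autoencoder trained
  jointly with k-means in latent space (a deep clustering network,
  objective `‖x̂ − x‖² + λ‖z − c_a‖²`, k = 10). A sliding window
  histograms the cluster assignments over the whole liver into a
  10-component signature per sequence; unenhanced T1 + hepatobiliary
  phase concatenate to a 20-component feature vector, chemical shift
  contributes 10 more. A cross-validated Random Forest classifies NASH
  versus simple steatosis and regresses each SAF component (steatosis
  0–3, inflammation 0–2, ballooning 0–2, fibrosis 0–4; NASH ⇔ S ≥ 1 and
  inflammation ≥ 1 and ballooning ≥ 1).

* A **diagnostic-statistics layer**: empirical ROC with Youden-optimal
  cutoff and sensitivity/specificity/PPV/NPV/accuracy, DeLong tests of
  correlated AUCs, two-way mixed absolute-agreement ICC, χ² and pooled
  t tests, and univariate plus backward-elimination linear regression.

* A **seeded synthetic cohort generator** (no patient data are
  distributed): SAF grades drawn from published class-conditional
  frequencies, analytically invertible signal models for RLE and FF, and
  grade-parameterised texture processes, so the whole pipeline can be
  exercised and tested end to end. There is also a small trainable
  encoder–decoder liver segmenter with an Otsu fallback.

The neural components are implemented in base R matrix algebra and run
in seconds-to-minutes on a single CPU at desk scale.

## Worked example

```r
library(nashudc)

cfg <- pipeline_config(
  seed   = 7,
  cohort = cohort_config(n_subjects = 20, class_mix = 0.6),
  n_patches = 300, k = 4,
  dcn = dcn_config(pretrain_epochs = 2, joint_epochs = 2),
  ntree = 100, segmentation_mode = "otsu")
report <- run_pipeline(cfg)
print(report)
```

```
==== NASH vs simple steatosis pipeline report ====
Cohort: 20 subjects (10 NASH / 10 simple steatosis)
Segmentation (otsu): Dice 1.000, recall 1.000, precision 1.000
Inter-reader ICC(A,1): RLE 1.000, FF 1.000
udc_score  steatosis 0.11 +/- 0.12 | NASH 0.93 +/- 0.12 | t-test p = 1.018e-11
rle        steatosis 1.57 +/- 0.08 | NASH 1.21 +/- 0.16 | t-test p = 4.189e-06
ff         steatosis 14.45 +/- 13.02 | NASH 30.61 +/- 13.19 | t-test p = 0.013
ROC udc       AUC 1.000 (CI 1.00-1.00), acc 100.0%, sens 100.0%, spec 100.0%
ROC rle       AUC 0.990 (CI 0.96-1.00), acc 95.0%, sens 100.0%, spec 90.0%
ROC ff        AUC 0.860 (CI 0.70-1.00), acc 80.0%, sens 90.0%, spec 70.0%
ROC combined  AUC 1.000 (CI 1.00-1.00), acc 100.0%, sens 100.0%, spec 100.0%
Backward elimination: RLE keeps {steatosis,inflammation,ballooning,fibrosis}; FF keeps {steatosis}
```

Reading the report: the out-of-fold Random Forest score (`udc_score`)
averages 0.11 in simple steatosis versus 0.93 in NASH; mean RLE is lower
(1.21 vs 1.57) and mean FF higher (30.6% vs 14.5%) in NASH, in the
clinically expected directions. Each ROC block reports the AUC with its
DeLong 95% CI and the confusion metrics at the Youden-optimal cutoff.
At this deliberately small scale the 20-subject cohort separates almost
perfectly; `pipeline_config()` defaults (60 subjects, 2,000 patches,
k = 10) give a more realistic AUROC near 0.9.

A command-line front end with the same stages is installed at
`inst/cli/nashudc` (`simulate`, `segment`, `quantify`, `udc-train`,
`udc-signature`, `predict`, `stats`, `report`, `run`).

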