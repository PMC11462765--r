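---
title: "ECG-gated montages and convolutional screening for therapy-related cardiomyopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECG-gated montages and convolutional screening for therapy-related cardiomyopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(echomontage)
```

## The problem

Childhood cancer survivors exposed to anthracyclines or chest radiotherapy
undergo lifelong echocardiographic surveillance for treatment-related
cardiomyopathy, conventionally defined by depressed left-ventricular systolic
function: shortening fraction (SF) at or below 28% or ejection fraction (EF)
at or below 50%. By the time these indices fall, remodeling is often
irreversible. This package implements a screening pipeline that asks whether
a compact convolutional network can separate survivors who go on to develop
cardiomyopathy from at-risk survivors who do not, using only parasternal
short-axis (PSAX) cine loops — including loops acquired years before the
index diagnosis.

The pipeline covers: reading multiframe ultrasound DICOMs with a
synchronized ECG; extracting four ECG-gated still frames per clip; removing
burned-in annotations by sector masking; assembling standardized 2×2
grayscale montages; applying the clinical case/non-case labeling rules;
patient-level cross-validated training of a two-block convolutional
classifier; and comparing the two montage formats with the combined 5×2-fold
cross-validation F-test. Because real clinical echocardiograms of this kind
are not publicly available, a synthetic ultrasound phantom generator stands
in for them in every test.

## ECG gating and the montage formats

For each clip, R peaks are detected on the ECG and the R-R interval is
divided into fixed fractions that approximate cardiac phases without
requiring any wave other than the R wave to be discernible:

* one third of the R-R approximates the end of the T wave (near end-systole),
* one half approximates the middle of the T-P segment,
* two thirds approximates the onset of the next P wave.

A **Type 1** montage samples a single cycle at fractions 0, 1/3, 1/2, 2/3 of
the first complete R-R interval; a **Type 2** montage samples fractions 0 and
1/3 of each of the first two consecutive cycles. Each landmark maps to the
frame with the nearest acquisition time; exact ties break toward the earlier
frame so results do not depend on frame rate. Frame indices are 1-based, the
R convention (language-neutral descriptions of the same rule are often
0-based; only the labeling differs, never the frame selected). Clips with no
ECG, an uninterpretable ECG, or fewer R peaks than the format needs (two for
Type 1, three for Type 2) fail quality control with explicit reason codes.
Deliberately, *poor image quality is not an exclusion*: the pipeline is
meant for real-world surveillance data.

The four prepared frames are tiled row-major (position 1 top-left through
position 4 bottom-right, in landmark order), then the montage is scaled by
`min(target_w/w, target_h/h)` and symmetrically zero-padded to exactly
1200 × 900 pixels, the standard model input. A reduced-resolution working
mode (e.g. 300 × 225, applied after standardization) exists for CPU-bound
experiments; full resolution remains the default.

### R-peak detection

The detector is ordinary signal plumbing, not a contribution: a sample is a
peak when it is a local maximum exceeding
`baseline + threshold_frac × (max − baseline)` (baseline = median amplitude,
`threshold_frac = 0.5`), with a 200 ms refractory period during which the
larger of two competing candidates wins. On high-SNR traces — phantom ECGs,
or the clean burned-in tracings the clinical inclusion rules already demand —
this recovers every R peak to within one sample across 50–150 bpm. Noisy or
pathological ECGs would need a proper QRS detector; such clips are expected
to fail QC as uninterpretable rather than be silently mis-gated.

### Sector masking

Burned-in text, scale bars and ECG strips must not reach the classifier.
The masking algorithm is a gap-fill of our own design (the goal — "only the
2D image components" — is specified upstream, the method is not): static
annotations have zero temporal variance while insonated tissue moves and its
speckle decorrelates, so the per-pixel variance across frames is thresholded
(at 0.2% of the maximum variance), small components are removed, the largest
connected component is kept, and its convex hull is taken as the imaging
sector (a circular sector with opening angle below 180° is convex). Moving
overlays such as an ECG sweep form separate components and are discarded
with the rest. A user-supplied mask is accepted for data where this
heuristic fails. Masked frames are converted to grayscale with Rec.601
luminance weights (0.299, 0.587, 0.114) — deterministic and standard — and
zeroed outside the sector.

## Cohort labeling

A survivor is a **case** when SF ≤ 28% or EF ≤ 50% on at least two
echocardiograms with at least one after completion of cancer therapy, or on
exactly one occasion followed by initiation of chronic heart-failure
therapy. The cardiomyopathy index date is the date of the earliest
qualifying echo. A **non-case** has SF ≥ 30% and EF ≥ 55% wherever measured
and no qualitative concern on any report. Survivors matching neither
definition (e.g. a single SF of 29%) are indeterminate and excluded, since
they satisfy neither printed definition. The HF-therapy clause accepts
therapy started any time on or after the qualifying echo; no upper bound is
imposed because none is defined clinically.

Case montages are then resampled by lead time Δ = index date − echo date:
all of Δ ≥ 0; pre-diagnosis only (Δ > the at-diagnosis window, 0 days by
default and configurable to e.g. 30); Δ ≥ 365; and Δ ≥ 730 days (inclusive
day-count boundaries). Non-case montages are retained in every subset, so
the four subsets are nested for case montages and the case counts are
non-increasing — the same structure the sequential-model design produces on
clinical data. Cumulative anthracycline/anthraquinone exposure is expressed
in doxorubicin equivalents with the standard factors: daunorubicin 0.5,
idarubicin 3.0, epirubicin 0.67, mitoxantrone 10.0.

## The classifier

The network is intentionally small: two principal blocks of
[2D convolution → batch normalization → ReLU], each followed by max pooling,
then flatten → fully connected → ReLU → a 2-unit softmax giving the case
likelihood. Defaults: 3×3 kernels, stride 1 with same-padding, pool 2,
8 and 16 filters, 32 dense units. These are configuration values, not
claims about any particular published model; the parameter count is a pure
function of the configuration and is verified against closed-form layer
arithmetic in the tests.

Training minimizes the cross-entropy with Adam (learning rate 1e-3, batch
16 by default), with two safeguards that matter at this scale: a linear
learning-rate warmup over the first 25 optimizer steps and global
gradient-norm clipping at 5. Without them, Adam's early sign-dominated
steps through the very high fan-in flatten-to-dense layer can drive every
dense unit's pre-activation negative in the first few updates, after which
ReLU passes no gradient and the model is permanently stuck at a constant
prediction — we observed exactly this failure on phantom runs. Inputs are
standardized to zero mean and unit variance using statistics of the
training montages, stored with the fitted model and re-applied at
inference. Validation loss is evaluated every epoch; the weights of the
best-validation epoch are kept (early stopping, patience 5 by default).
Class imbalance is *not* reweighted by default — imbalance effects are a
finding, not a nuisance — but class weights are available in the
configuration. Thresholded metrics use the argmax rule (case iff
p(case) ≥ 0.5).

All data movement through the conv/pool layers is implemented in compiled
code (im2col plus BLAS matrix products); batch-norm statistics,
fully-connected layers, softmax and Adam live in R. Gradients of every
layer are checked against central finite differences in the test suite.

### Splits

The study design states both a 70:15:15 train/validation/test split and a
"10-fold cross-validation framework" without reconciling them. We implement
the folds as **ten repeated stratified random 70:15:15 patient-level
resamples** (Monte-Carlo cross-validation with holdout subsets), which
honors both statements; classic grouped k-fold is available as an
alternative mode (`mode = "kfold"`). Splits are always at the patient
level: every montage of a patient inherits the patient's role, so no
patient's studies can straddle train and test. Role totals use the floor
rule (train gets the floor; the remainder is divided val-then-test), and a
controlled-rounding allocation keeps the case fraction within one patient
per role.

## Evaluation

Per fold: AUROC (trapezoidal over the full ROC, identical to the
Mann-Whitney pairwise statistic with ties counted one half), AUPRC as
average precision (the step-wise sum of precision × recall increments —
chosen over interpolated trapezoids because it is the standard estimator
for imbalanced screening data and is deterministic), plus accuracy, F1,
PPV and NPV from the confusion matrix. Metrics with a zero denominator are
undefined; fold summaries (mean ± sample SD, n−1 denominator) exclude them
with a warning rather than imputing. Both curve areas are verified against
independent oracles (exhaustive pairwise comparison; explicit threshold
enumeration), and AUROC additionally against pROC.

### Comparing the montage formats

The two input formats are compared with the combined 5×2-fold
cross-validation F-test: five replications of patient-level stratified
2-fold CV, both models trained on the same folds; with fold-wise accuracy
differences $p_i^{(j)}$, replication means $\bar p_i$ and variances
$s_i^2 = (p_i^{(1)}-\bar p_i)^2 + (p_i^{(2)}-\bar p_i)^2$,

$$F = \frac{\sum_{i=1}^{5}\sum_{j=1}^{2} (p_i^{(j)})^2}{2\sum_{i=1}^{5} s_i^2}$$

referred to the upper tail of F(10, 5). The implementation is transcribed
from the combined-F-test literature and verified against an independently
coded oracle to 1e-12; the statistic is invariant to swapping the two
models.

One distributional note, established while validating the test: under a
null of i.i.d. normal accuracy differences the statistic decomposes exactly
as $F = \tfrac12 F_{5,5} + \tfrac12$ (each replication's squared sum splits
into an independent mean and variance part), so its true size at nominal
α = 0.05 is `pf(2*(qf(.95,10,5)-.5), 5, 5, lower.tail=FALSE)` ≈ 0.0175.
The test is conservative under this idealized null — consistent with how
the 5×2-CV testing literature characterizes it — and the calibration test
in this package asserts exactly that property rather than a nominal-size
band the statistic cannot attain.

## The phantom

Real pediatric echocardiograms with longitudinal outcomes are sensitive and
non-public, so the package carries a synthetic PSAX phantom that makes every
stage testable: a bright myocardial annulus around a dark cavity inside a
fan-shaped sector on black background, with two papillary bumps on the
endocardial border, multiplicative gamma-distributed speckle (the standard
first-order ultrasound texture model), optional sepia colorization
(a monotone color map, so grayscale conversion preserves intensity ranks),
an optional static text block and a moving ECG strip burned in, and a
synchronized ECG with triangular R deflections at cycle starts. The cavity
radius follows $r(t) = r_{ED} - (r_{ED}-r_{ES})\,g(\varphi)$ with $g$ a
Gaussian pulse in cycle phase peaking at 1/3 — so end-systole coincides
with the end-of-T-wave landmark — and the ground-truth fractional
shortening $(r_{ED}-r_{ES})/r_{ED}$ is recorded along with the true R
times, sector polygon, annotation pixels and per-frame radii. Everything is
bitwise-reproducible under a seed.

The cohort generator layers the clinical structure on top: case patients
draw fractional shortening from 15–28% and non-cases from 32–45%, straddling
the 28%/30% thresholds with a deliberate gap that mirrors the indeterminate
band and keeps labels unambiguous; recorded SF values are written so the
labeling rules recover the intended labels exactly; cases get an index date
well after therapy completion with earlier echoes spread over two or more
years so that all four timing subsets are populated (guaranteed when a case
has at least four echoes); case records with fewer than two qualifying
echoes use the HF-therapy pathway; and doxorubicin-equivalent doses are
sampled higher for cases. One deliberate asymmetry: *all* clips of a case
patient are rendered with case-range shortening, including pre-diagnosis
studies whose recorded SF is normal. That encodes the working hypothesis of
the whole enterprise — a structural imaging signature precedes the measured
SF decline — and is what makes pre-diagnosis prediction learnable on
phantom data. Real pre-diagnosis echocardiograms are harder: performance on
the phantom bounds what the pipeline can do, not what any clinical model
will achieve.

What the phantom does not emulate: probe-dependent point-spread functions,
rib shadowing and lung artifact, operator fanning, arrhythmia, view
mislabeling, and inter-reader SF variability. Passing tests therefore
demonstrate the correctness of the machinery (gating, masking, montage
geometry, labeling, splits, metrics, the F-test) and the trainability of
the classifier on clean structure, nothing more.

## Numerical choices and problem sizes

Tolerances and tie-breaks are fixed and documented where behavior could
otherwise drift: earlier-frame tie-breaking in landmark mapping; symmetric
zero-padding with the odd pixel going right/bottom; bilinear interpolation
for all resizes; Rec.601 luminance; batch-norm epsilon 1e-5 with running
statistics (momentum 0.9) at inference; average midranks for AUROC ties.
Degenerate inputs (flat ECGs, single-class training sets, zero-variance
clips, all-identical accuracy differences) raise classed errors rather than
producing numbers.

The shipped test and acceptance runs use phantom clips of 160 × 120 pixels,
montages standardized to 1200 × 900 and reduced to 300 × 225, cohorts of up
to 120 patients, three Monte-Carlo folds for the end-to-end discrimination
check (training up to 10 epochs, patience 4), and a 16-patient cohort at
80 × 60 for the montage-format comparison. These sizes were chosen so a
single-CPU machine reproduces everything quickly while leaving each check
statistically meaningful; the pipeline itself has no such limits.

## Known limitations

The DICOM layer is a minimal explicit-VR little-endian dialect sufficient
for the clips this package writes and reads (verified against an
independent reader); it is not a conformant general DICOM implementation,
and embedded-ECG extraction from vendor-specific waveform or curve modules
of real machines will generally require the sidecar pathway. The R-peak
detector assumes high SNR. The masking heuristic assumes a convex sector
and moving tissue. The classifier is a feasibility-scale architecture;
nothing here is a clinical device.
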