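---
title: "Inter-patient heartbeat classification: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-patient heartbeat classification: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgbeats)
```

## The problem

Ambulatory (Holter) ECG recordings contain tens of thousands of heartbeats,
of which a small fraction are arrhythmic. The AAMI practice groups beats
into five classes - normal and bundle-branch beats (N), supraventricular
ectopic beats (SVEB), ventricular ectopic beats (VEB), fusion beats (F),
and unknown/paced beats (Q, discarded here) - and the clinically honest way
to evaluate a classifier is the *inter-patient* paradigm: the patients whose
recordings train the model never appear in the test set. Under that
protocol, per-patient morphology differences dominate, hand-crafted feature
sets degrade, and the heavy class imbalance (roughly 89% N, 2.8% SVEB, 7%
VEB, 0.8% F in the MIT-BIH arrhythmia database) pushes naive training
toward the majority class. This package implements a hybrid classifier
that addresses both problems: a small one-dimensional CNN learns beat
morphology, four RR-interval features carry rhythm context, and focal loss
re-weights training toward hard minority beats.

## The pipeline

### Baseline wander removal

Respiration and electrode motion put a low-frequency drift under the trace.
It is estimated with two cascaded running medians: a 200 ms window first
deletes the narrow deflections (QRS complexes, P waves), then a 600 ms
window deletes T waves; what survives both passes is the baseline, which is
subtracted from the signal. Median filtering is preferred over linear
high-pass filtering because medians do not smear QRS energy into
neighbouring samples. No other conditioning is applied - no high-frequency
denoising, no per-segment rescaling - so the morphology the network sees is
as close to the recorded signal as possible.

Numerical choices: window widths are converted to odd sample counts
(`round(width_ms * fs / 1000)`, plus one if even; 73 and 217 samples at
360 Hz) so the median lies on the sample grid; edges are handled by
reflecting `floor(w/2)` samples at each end, which avoids the spurious
edge dips that zero padding creates. The running median itself is
`stats::runmed` (an exact algorithm), applied to the padded signal; the
test suite checks it elementwise against a brute-force sliding-window
median on hundreds of random signals. Within half a window of a record
edge the reflected median of a drifting signal is biased - the tests
therefore measure drift suppression away from the edges, and beats whose
segment window would cross a record edge are dropped anyway.

### Segmentation

Each annotated R-peak anchors one fixed-length segment: 90 samples before
the peak, the peak, and 109 samples after it, i.e. the half-open window
`[r - 90, r + 110)` in 0-based coordinates, 200 samples (556 ms at 360 Hz).
R-peak detection is out of scope: labeled peaks are taken as given, which
matches how the reference databases are annotated. Beats too close to a
record edge are dropped rather than padded - padding would fabricate
morphology - and the drop count is reported; on 30-minute records this
loses at most a couple of beats per record.

### RR-interval features

Four per-beat rhythm features: the previous RR interval, the post RR
interval, their ratio, and the local RR interval (mean of the 10 intervals
preceding the beat). The first three capture instantaneous rhythm -
a premature beat shows a short previous interval and, with the usual
compensatory pause, a ratio below one - while the local RR summarises the
recent rate. Because resting heart rate differs between patients, the
record's mean RR interval (over all of that record's intervals) is
subtracted from the three interval features; the ratio, already
dimensionless, is left alone. Each record is normalized by its own mean,
so no quantity crosses patients and the inter-patient protocol is intact.

Edge rules (the data leave them open, so they are fixed here once): the
first beat of a record has no previous interval and the last has no post
interval; both are imputed with the record mean, which after centering is
exactly zero - a neutral value. A beat with fewer than 10 preceding
intervals averages the ones available. All features are in seconds, not
samples, so they are comparable across sampling rates.

### Network

The morphological branch takes the raw 200-sample segment through three
blocks of (1D convolution, batch normalization, ReLU) with un-padded
kernels of 11, 16 filters, stride 3; then 5/32/1; then 3/64/1, each block
followed by max-pooling (window 3, stride 2). Kernels shrink and filters
grow with depth, the usual funnel for short 1-D signals. The final 5 x 64
activation map flattens to 320 features, the 4 RR features are
concatenated (324), and a 64-unit ReLU dense layer feeds the 4-class
softmax. The whole network - 30,276 trainable parameters plus 224 running
batch-norm statistics - trains jointly, so the convolutional features are
shaped by the same gradient as the classifier head ("one-step training").

Two details were genuinely open and are fixed as follows. The block order
is convolution, then batch normalization, then ReLU, following the
layer-table order of the reference design (its prose mentions ReLU before
normalization; the table is taken as authoritative since it carries the
shape and parameter accounting). The hidden dense layer is given a ReLU
(the table lists no activation); a linear hidden layer would collapse the
head to a single affine map and waste the layer. Batch-norm epsilon is
1e-3 and the running-statistics momentum 0.99; initialization is
Glorot-uniform under a caller-supplied seed.

### Losses

With one-hot target $t$ and softmax output $p$, cross-entropy is
$CE = -\sum_i t_i \log p_i$. Focal loss reshapes it with a modulating
factor, $FL = -\sum_i t_i (1 - p_i)^\gamma \log p_i$: confidently correct
examples (mostly majority-class N beats) contribute almost nothing, so the
gradient concentrates on hard and minority beats. The
$\alpha$-balanced variant multiplies each class's term by a weight
$\alpha_i$. The package trains with plain focal loss at $\gamma = 2$ by
default; $\gamma = 0$ recovers cross-entropy exactly, which the tests
exploit as an identity. Probabilities are clipped to $[10^{-7}, 1]$ before
the log; batches are reduced by the arithmetic mean so the learning-rate
scale is independent of batch size; logarithms are natural.

### Training

Adam (beta 0.9/0.999, epsilon 1e-7), batch size 512, 50 epochs, initial
learning rate 0.001 multiplied by 0.1 every 10 epochs (0-based epochs, so
decays land at epochs 10, 20, 30, 40), and an l2 penalty of 1e-3 on
convolution and dense kernels only - not biases, not batch-norm scale or
shift. Beats are reshuffled every epoch from the run seed; the final
partial batch is kept. Runs are bit-reproducible given the seed.

One implementation note: the exponentially averaged batch-norm statistics
trail the weights, and in short runs (tens of optimizer steps) the stale
running statistics can make inference-mode predictions collapse even when
training-mode accuracy is high. After the last weight update the package
therefore re-estimates all running means and variances with a pass over
the training set and stores those; this replaces the momentum average
entirely and makes inference consistent at any run length.

The forward and backward passes are written in vectorized R: convolutions
are im2col gathers followed by BLAS matrix products, max-pooling tracks
argmax positions for its backward scatter, and batch normalization
backpropagates through its batch statistics. Every gradient path is
checked against central finite differences in the test suite.

### Evaluation

From the 4 x 4 confusion matrix (rows ground truth, columns predictions,
order N, SVEB, VEB, F) each class gets positive predictive value
$PPV_i = TP_i/(TP_i + FP_i)$, sensitivity $SE_i = TP_i/(TP_i + FN_i)$,
one-vs-rest accuracy $ACC_i = (TP_i + TN_i)/total$ and
$F1_i = 2 \cdot PPV_i \cdot SE_i/(PPV_i + SE_i)$ (defined as 0 if
$PPV_i + SE_i = 0$, a case real data never produces). Two different
"accuracies" circulate in this literature and both are reported under
distinct names: the unweighted mean of the four one-vs-rest accuracies,
and the overall (trace/total) accuracy. `evaluate()` additionally refuses
to score any record that appeared in training - the inter-patient
guarantee is enforced, not assumed. Displayed tables round half-up to two
decimals; stored values are unrounded.

The package bundles the reference confusion matrices reported for this
architecture on the MIT-BIH DS2 test set (focal and cross-entropy
training), so the whole metric pipeline can be exercised and checked
against the published per-class figures without any signal data
(`reference_confusion_matrices()`, or `ecgbeats reproduce-metrics` from
the command line).

## MIT-BIH handling

A minimal WFDB reader (header, format-212 signal, MIT annotation file)
selects the MLII lead - if a record lacks that lead the call fails rather
than silently substituting another - converts ADC units to millivolts,
and keeps beat annotations only. The symbol-to-class mapping is: N, j, e,
R, L to N; a, S, J, A to SVEB; E, V to VEB; F to F; Q, f, / excluded, and
any symbol outside the table excluded with a warning. The four paced
records (102, 104, 107, 217) are excluded entirely, and the remaining 44
records follow the canonical de Chazal partition into 22 training (DS1)
and 22 test (DS2) records, adopted here by citation as the standard
inter-patient protocol. Whether published beat counts include beats whose
segment window overflows the record edges is not documented anywhere we
know of; this package counts mapped annotations (edge drops affect only
segment extraction), which reproduces the published per-split totals.

## The synthetic generator

The generator exists so that every downstream stage is testable without a
database download. It emulates exactly the properties the pipeline
consumes: beats laid out at jittered RR intervals (mean 0.8 s, jitter sd
0.04 s); class labels drawn i.i.d. with the MIT-BIH-like imbalance
(0.895, 0.0275, 0.0695, 0.008) by default; premature classes advanced
toward their predecessor (SVEB by factor 0.60, VEB by 0.75) with the
following beat kept on schedule, so a premature beat is followed by a
compensatory pause; class-specific morphology as mixtures of Gaussian
bumps (a full P-QRS-T for N; a small early P for SVEB; a wide, P-less QRS
with discordant T for VEB; a ventricular/normal blend for F); sinusoidal
baseline wander with periods of 3.3 s and 7.6 s at 0.15 mV; and white
noise at 0.03 mV. Cohorts draw per-record resting rate and electrode gain
from cohort-level distributions, so a record split is a genuine
inter-patient split. All bump parameters are implementation constants
documented in the source; they were chosen once for physiological
plausibility (QRS around 1 mV and 60-80 ms wide for normal beats, wider
for ventricular ones) and are not calibration targets.

What the generator deliberately does not model: true cardiac dynamics (no
differential-equation beat model), electromyographic or powerline noise,
atrial-fibrillation-like irregular rhythms, annotation errors, or the
within-class morphological diversity of real patients. Consequently the
synthetic classes are more separable than real MIT-BIH classes - SVEB is
hard (it differs from N mainly through timing), but VEB and F are easy.
Passing the synthetic end-to-end checks therefore demonstrates that the
pipeline wiring, gradients, and imbalance handling work, and that focal
loss does not hurt minority recall; it does not certify the published
real-data operating point, which requires the actual database.

## Problem sizes used in the checks

The synthetic end-to-end checks use 12 training and 6 test "patients" of
300 s each (about 6,800 beats, roughly 0.8% of them F-class), trained for
10 epochs - sizes chosen so the whole suite runs comfortably on a
single CPU while keeping at least the minority-class counts that make the
imbalance question meaningful. The directional focal-versus-cross-entropy
comparison averages over five seeds. The learnability smoke test uses a
smaller, better-separated six-record cohort with reduced noise and a
batch size of 64, matching its purpose: verifying that a separable
problem is learned within a few epochs.

## Known limitations

- The published MIT-BIH operating point can only be reproduced with the
  real database present locally; the package never downloads data.
- Training in base R is two orders of magnitude slower than a GPU
  framework; the default 50-epoch schedule on the full DS1 (about 51,000
  beats) is an overnight run on one core, though the scaled-down runs used
  in the checks take about a minute each.
- Single-lead only (MLII), by design; two-lead fusion is out of scope.
- The WFDB reader covers what the MIT-BIH arrhythmia database uses
  (format 212, MIT annotation files); it is not a general WFDB
  implementation.
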