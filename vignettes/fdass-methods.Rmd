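---
title: "Methods: from action-unit streams to DASS severity bands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from action-unit streams to DASS severity bands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdass)
```

## The model

`fdass` implements a three-layer pipeline for estimating Depression
Anxiety Stress Scale (DASS) severity from facial behaviour coded in the
Facial Action Coding System (FACS).

**Layer 1 — action-unit coding.** A frontal-face frame is reduced to 72
nonrigid appearance parameters (the appearance-model fitting itself is
out of scope here; the package takes the 72-vector as a data contract,
and its synthetic generator produces such vectors). A bank of 31
independent multiclass support-vector classifiers — one per catalog AU —
maps the 72-vector to an intensity level on the ordinal FACS scale O
(absent), A, B, C, D, E (maximum). The catalog (`au_catalog()`) holds
the 31 AUs that carry intensity coding: eight upper-face units, twenty
lower-face units and the three cheek units; AU41, AU42 and AU46 are
excluded because FACS does not code them with intensity. Geometry
support for this layer is the eye/mouth block detector
(`detect_blocks()`): the strongest row of the binary face mask's white-
pixel profile in each half of the face is taken as the block median and
validated against the anthropometric bands 2/20–9/20 (eyes) and
11/20–15/20 (mouth) of face height.

**Layer 2 — the facial matrix.** Levels are normalized to fixed reals
(O = 0, A = 0.2, B = 0.4, C = 0.6, D = 0.8, E = 0.9; note the
deliberately non-uniform top step, kept exactly as specified) and
appended, one column per frame, to a 31-row facial matrix. Every 30
columns — one second of video at the default 30 fps — form a tumbling
31 × 30 window.

**Layer 3 — the severity network.** Each window, flattened column-major
to a 930-vector (frames contiguous), feeds a feedforward network
930 → 75 → 65 → 3 with tanh on the first hidden layer and logistic
sigmoid on the second hidden layer and the output layer. The three
outputs in (0, 1) are banded into the five severity levels at thresholds
0.15 / 0.3 / 0.6 / 0.8. Hidden biases are fixed at zero throughout
training; only the output bias is trained. Weights are initialized by
the Nguyen–Widrow rule: every neuron's incoming weight vector is scaled
to magnitude $0.7\,h^{1/n}$ (for $h$ neurons fed by $n$ inputs), with
random directions under the seed. A disorder variant with hidden sizes
30 and 25 emits three outputs thresholded at 0.5 as binary MDD / GAD /
PTSD flags.

Training minimizes the average absolute relative error
$$\mathrm{AARE} = \frac{1}{N}\sum \left|\frac{y^{\mathrm{des}} -
y^{\mathrm{est}}}{y^{\mathrm{est}}}\right|,$$
by full-batch gradient descent with classical momentum at the published
operating point: learning rate 0.2, momentum 0.4, at most 7000 epochs,
stopping early once the training AARE falls below 0.02. An 80:20
train/validation split tracks generalization.

**Decision logic.** Per second, a window yields one band triple — by the
network, or by the AU-signature shortcut: if all four of a scale's
signature AUs (depression {AU6, AU12, AU15, AU26}, anxiety {AU2, AU9,
AU25, AU45}, stress {AU1, AU6, AU12, AU15}) reach level D or E inside
the window, that scale is assigned Extremely Severe directly. The
rule-based classifier then emits the first band triple repeated for five
consecutive seconds as the final output, or `Undefined` if no such run
occurs.

**Questionnaire ground truth.** The 42-item self-report is scored by
summing each scale's 14 items (scores 0–3) and banding the raw sum:
depression 0–9 / 10–13 / 14–20 / 21–27 / 28+, anxiety 0–7 / 8–9 /
10–14 / 15–19 / 20+, stress 0–14 / 15–18 / 19–25 / 26–33 / 34+. The
instrument's item-to-scale map is configuration (the clinical mapping is
not reproduced here); the default assignment, used only by the
generator, is items 1–14 / 15–28 / 29–42.

## Numerical and design choices

* **Relative-error denominator.** The AARE divides by the *estimated*
  output. Sigmoid outputs are never exactly zero, but denominators are
  clamped at $\varepsilon = 0.05$ so early-training estimates cannot
  blow up the loss; band targets are encoded as banding-interval
  midpoints (0.075 / 0.225 / 0.45 / 0.7 / 0.9), which are strictly
  positive, so desired values never sit at zero either.
* **Gradient normalization.** The training loss is the mean over all
  output components and samples, and the gradient is of exactly that
  mean (verified against central finite differences to ~1e-8 relative
  error on toy networks). A per-pattern update mode is available
  (`train_config(batch = "sample")`); full batch is the default.
* **Band endpoints.** The printed banding intervals share endpoints
  ([0, 0.15], [0.15, 0.3], ...). They are resolved lower-inclusive —
  0.15 is Mild, 0.3 is Moderate, 0.6 is Severe — except that 0.8
  belongs to Severe, because Extremely Severe is "over 0.8" (strict).
  This makes the partition of [0, 1] total and unambiguous.
* **Argmax ties** in block detection break to the smallest row index;
  rows are 0-based and row fractions are `row / H`. The upper/lower
  split is at one half of mask height; the printed bands then act as
  validation. An empty half flags the block invalid instead of raising,
  so streaming callers can skip a frame.
* **Window flattening** is column-major (each frame's 31 values
  contiguous). Any fixed order works; this one keeps frames intact.
* **Aggregator equality** compares the whole band triple; a run is five
  identical consecutive *triples*, and the first qualifying run wins
  regardless of later contradictions.
* **Shortcut scope.** The four signature AUs must reach level D
  anywhere within the window (columns may differ); a strict same-frame
  mode is available (`same_frame = TRUE`).
* **Classifier kernel.** The AU bank's default is a *linear* kernel
  (LIBSVM, one-vs-one, features standardized to training moments). In
  the package's feature model each AU's evidence lives in a
  low-dimensional direction of a space shared with 30 other AUs'
  signals of equal scale; an isotropic radial kernel cannot downweight
  the other signals and its held-out accuracy saturates far below the
  linear machine's. The kernel remains a pluggable argument.
* **Disorder targets.** The binary disorder variant encodes its 0/1
  flags as 0.1/0.9 for training, because the relative-error loss
  requires strictly positive targets; predictions are thresholded at
  0.5, with the exact-0.5 tie resolved to 0.

## What the synthetic generator emulates

No public corpus links FACS intensity streams to DASS severity, so the
generator is a first-class module that produces every input the
pipeline consumes: cohorts (with at most one disorder per subject, a
disorder forcing its matched scale to at least Severe, and per-session
band random walks of ±1 step with probability 0.4 each way — a mean
drift of 0.8 bands), AU streams, 72-dimensional feature vectors,
binary face masks and band-consistent questionnaire responses. All
generators are pure functions of their arguments and a seed.

**Severity signal.** Severity expresses itself as episodic bursts of
the scale's four signature AUs at level D or E. Per one-second window,
an episode occurs with probability 0.02 / 0.8 / 0.9 / 0.95 / 0.99 by
severity rank and covers a fraction 0.1 / 0.15 / 0.35 / 0.6 / 0.9 of
the second. Both the chance and the duration grow with rank, so a
single window carries rank information — without this, no per-window
predictor could distinguish intermediate bands at all. Baseline
activity flips any AU on at low intensity with probability 0.05 per
frame, which makes chance co-occurrence of a full four-AU signature
essentially the fourth power of a small number.

**Emotions.** An induced emotion activates its classical FACS prototype
AUs (e.g. happiness AU6 + AU12) in bursts capped at level C,
independent of severity. An emotion associated with a scale (happiness
and sadness for depression, surprise and disgust for anxiety, sadness
and disgust for stress) elicits that scale's expression — its episodes
become fully reliable — while a non-associated emotion dominates the
face and masks the expression, multiplying the episode probability by
0.25. This is the mechanism by which restricting training to a scale's
associated emotions yields cleaner training data than pooling all six:
pooling adds streams whose windows frequently lack the severity signal
their labels promise. The masking factor was set once, when the
mechanism was designed; without masking, the 6× larger pooled training
set simply outweighs the cleaner filtered one.

**Noiseless training windows.** For controlled network experiments,
`generate_training_windows()` builds windows whose band targets are a
deterministic monotone function of the signature-AU window means: rank
1–5 places level-E bursts in 0 / 7 / 15 / 22 / 30 of the 30 columns
(depression filling from the left, stress from the right, so the AUs
the two scales share carry the union while each scale's private AU
stays exact). This *prevalence coding* — severity as how much of the
second is covered, rather than as a graded level held for the whole
second — mirrors the episodic stream model and makes the window-mean →
target map nearly linear. Under it, batch gradient descent at the
published learning rate and momentum reaches the 0.02 AARE stopping
criterion in roughly 1200–1700 epochs; under the alternative
level-coding design the same optimizer stalls well short of the target
within the 7000-epoch cap, so prevalence coding is the package's
canonical noiseless task.

**Feature vectors** place AU $j$'s level redundantly in coordinates $j$
and $31 + j$ at a default cluster separation of 6 noise standard
deviations (the last ten coordinates are pure noise) — appearance
parameters never isolate one muscle in a single coordinate, and the
redundancy is what keeps the level decodable after per-coordinate
standardization.

**What it does not emulate:** photorealistic faces, appearance-model
fitting error, head pose, frame drops, co-articulated (additive) AUs,
inter-rater coding noise, or any clinically validated link between
facial behaviour and DASS constructs. Passing recovery tests on this
generator demonstrates that the pipeline's machinery is correct and
that its training procedure can extract a signal *of the constructed
form*; it says nothing about real patients.

## Evaluation protocols

`run_protocol()` reproduces the two methodologies: *intrasubject*
(leave one session of a subject out, training on the subject's other
sessions) and *intersubject* (leave one subject out, training on the
rest), each crossed with training/testing on emotion-induced (DSC),
random-condition (DSR) or both sample sets, optionally restricting
training to a set of emotions. Per fold a fresh network is trained on
the training split's windows (targets are the session's bands as
midpoints) and test samples are run through the full per-second
pipeline. It reports one-vs-rest confusion counts and accuracy /
sensitivity / specificity per scale and band — a metric with a zero
denominator is reported as not applicable, never zero — along with
per-window multiclass accuracy, the average seconds of stream consumed
before a decision, and the fold manifest for leak auditing. `Undefined`
aggregator outputs are excluded from the confusion counts and reported
as an undecided rate: folding them into false positives or negatives
would distort all three metrics silently.

Protocol studies default to reduced hidden sizes, because training a
75/65 network in every fold is costly; the test suite uses hidden
layers of 6–20 neurons, streams of 5–6 seconds, cohorts of 4–10
subjects and epoch budgets of 30–7000 depending on what the check
needs, and the acceptance experiments use 200 windows at the full
published architecture. These sizes are the package's own choices for
desk-scale experiments.

## Known limitations

* The printed accuracies of the original study were computed on a
  private 128-subject clinical corpus; they are not reproducible here
  and are not targets. Synthetic recovery results are ceiling-style
  checks, not clinical claims.
* The AARE's asymmetric gradient (division by the estimate) pulls
  outputs upward early in training; binary-flag training therefore
  needs to run to convergence before the 0.5 threshold separates
  classes.
* The eye-block heuristic takes the *maximum* of the white-pixel row
  profile in the upper face half, exactly as specified for the
  skin-mask input; on masks where eyes appear as holes rather than
  filled rows the peak row can sit elsewhere, which the fractional-band
  validation is there to catch.
* One face per stream; dropped frames are not interpolated; windows are
  tumbling (no sliding stride).
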