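---
title: "Grading stertor from laryngeal stethoscope audio: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading stertor from laryngeal stethoscope audio: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the signal
model, the network and its ordinal loss, the evaluation protocol, what the
synthetic generator does and does not emulate, and the numerical and
design choices made where the problem left them open.

## The clinical task

Brachycephalic obstructive airway syndrome (BOAS) is graded 0 (none) to 3
(severe) under the respiratory functional grading scheme, largely from
respiratory noise auscultated over the larynx before and after an exercise
test. The dominant acoustic marker is stertor: an intermittent,
low-frequency, snoring-like sound produced by soft-palate vibration, with
a tonal fundamental and harmonics concentrated below roughly 300 Hz.
Grades 0/1 are "BOAS negative", grades 2/3 "BOAS positive" — the boundary
at which intervention is considered. The package grades stertor per
recording and maps it one-to-one onto a BOAS grade per encounter; stridor
(the higher-frequency inspiratory noise of laryngeal pathology) is carried
in the data model but deliberately not modelled — too few moderate/severe
stridor examples exist relative to stertor for supervised training, and
moderate/severe stertor usually accompanies it.

## Front end

Audio is mono PCM at 4 kHz (recordings at other rates are polyphase
resampled). Because stethoscope amplitude depends on application pressure
and placement, each recording is normalised to unit peak before analysis;
absolute level is never used as a feature.

Recordings are cropped or zero-padded to a fixed **input length** of 5 or
10 s, treated as a hyperparameter. Cropping keeps the *first* seconds —
deterministic and faithful to capture order; a seeded random-crop mode
exists for augmentation but is off by default. Zero padding (rather than
repetition or exclusion of short recordings) is used because silence is
the natural neutral filler and the attention layer learns to down-weight
it — the trained attention traces confirm padded tails receive low weight.

The spectrogram uses a periodic Hann window of 100 ms with 50 % overlap
and FFT length equal to the window (400 samples, no zero padding), so the
bin spacing is exactly 1/0.1 s = 10 Hz and the hop is 50 ms. A 10 s
recording gives 199 frames (`floor((40000-400)/200)+1`). The band is
clipped to 20–400 Hz *inclusive* — exactly 39 bins — which removes DC and
very-low-frequency rumble while retaining frequencies above the stertor
fundamentals that help separate harmonic events from broadband noise.

Feature scaling is log power, `log(power + 1e-10)`, standardised to zero
mean and unit variance per recording. Whether linear or log power is the
better network input is genuinely open for this signal class; log
compression is the standard choice for harmonically structured
bioacoustic events and trains more stably, so it is the default, with the
linear variant behind `to_features(scale = "linear")`.

## Network

The grader is a bidirectional GRU (one or two stacked layers) over the
39-dimensional frame features. The forward direction iterates first to
last frame, the backward direction last to first, and their hidden states
are concatenated per frame. Pooling over time is a single-head
self-attentive layer: a one-hidden-layer tanh scorer assigns each frame a
score, a softmax over frames normalises the scores to weights, and the
pooled representation is the weighted time average of hidden states. One
hidden tanh layer is the smallest scorer consistent with the
self-attentive formulation; a single head matches the need for one
interpretable weight trace per recording. The head is a fully connected
ReLU network with four linear outputs and a sigmoid per position — not a
softmax, because the ordinal loss treats positions as separate binary
events. Dropout, when active, sits between stacked recurrent layers and
on head hidden activations; those are the only placements that do not
break the recurrence.

### Ordinal encoding, loss, decoding

The stertor grade is ordered, so the four outputs are trained against
cumulative targets: grade *g* sets positions `0..g` to 1 (grade 2 is
`[1,1,1,0]`). The loss is the mean over positions of binary cross-entropy
between each sigmoid output and its target bit, computed in the
numerically stabilised logits form; the mean (rather than sum) makes the
scale independent of the number of classes. Decoding picks the lowest
position whose output falls below a threshold τ (default 0.5, exposed in
the API and CLI) minus one, clamping at 0 — position 0's target is 1 for
every class, so an output vector whose first entry is below τ can only
mean grade 0. The raw output vector is decoded literally; no monotonising
correction is applied to non-monotone vectors, keeping decoding faithful
to the stated rule (a monotonised variant would be a reasonable
alternative but changes nothing for monotone outputs).

ROC analysis needs a continuous score; the package uses the **severity**
`outputs[1] + outputs[2] + outputs[3]` (0-based positions 1–3), the
expected grade under the cumulative reading. Position 0 is excluded as
uninformative. This construction is the package's own choice — any
monotone aggregate would do — and is monotone in each output. Note it can
disagree in rank with hard decoding near the threshold (a vector may
decode lower yet carry higher summed probability); the suites therefore
assert consistency under elementwise dominance, where both must agree.

### Training

AdamW at learning rate 0.001 with decoupled weight decay 0.01, shuffled
mini-batches (default 16; 32 in the scaled protocol), a fixed epoch budget
(default 100) and, when a validation split is supplied,
best-validation-loss checkpointing with early-stopping patience 15
(5 in the scaled protocol). Epoch count, batch size, patience and the
search budget are not dictated by the problem; the defaults are chosen to
converge comfortably on cohorts of a few hundred recordings. Class
imbalance is left untouched by default — the cohort's skew towards grades
1–2 is part of the modelled task and explains the weaker per-class
behaviour at grades 0 and 3 — with optional inverse-frequency resampling
behind `training_config(class_weighting = TRUE)`. Everything is
reproducible from a single integer seed: initialisation, shuffling,
dropout masks and the hyperparameter sampler all derive from it.

## Evaluation protocol

Small clinical cohorts make a held-out test set statistically weak, and
plain k-fold CV biases performance upward when hyperparameters are tuned
on the folds. The package therefore implements nested cross-validation:

1. Dogs are assigned to 5 folds by **stratified minimisation**: dogs are
   visited in seeded random order and each goes to the fold minimising
   the summed marginal imbalance (Pocock–Simon style, equal weights: the
   sum over sex, breed, body-condition band and BOAS grade of the range
   of category counts across folds), with fold size as the final
   balancer and residual ties broken at random.
2. Each fold in turn is the test fold. A random search (default 20
   candidates) over architecture hyperparameters is scored by 4-fold CV
   on the remaining folds — the selection metric is the mean validation
   AUC for the binary grade ≥ 2 task, matching the headline evaluation
   target; ties go to the smaller model, then sampling order.
3. The winning architecture trains once on all four training folds and
   predicts the untouched test fold.
4. Ten repeats with fresh stratifications give 50 independent runs.

The unit of fold assignment is the **dog**, not the encounter or
recording: per-recording splits would place the same animal on both sides
of a split and leak identity. Covariates for balancing come from the
dog's first encounter. Post-operative encounters stay in training folds
(they carry usable acoustics) but are excluded from all reported test
metrics, since the intended use is screening new cases.

Per-run ROC curves are combined by **vertical averaging** — TPR evaluated
at a common FPR grid (0 to 1, step 0.01, well below the across-run spread)
and averaged, because threshold averaging would assume the runs' scores
are mutually calibrated. Curve evaluation follows the true threshold
sweep: vertical segments at tied FPRs evaluate to their upper end, and
segments between distinct FPRs run from the upper-left to the lower-right
corner, so the trapezoidal area under a single averaged curve reproduces
that curve's AUC to grid precision. Operating points are reported at the
Youden maximum (sensitivity + specificity) and at a high-sensitivity
point defined as the best specificity subject to a sensitivity floor
(default 0.80) — a floor is the natural screening-style rule where the
underlying selection criterion is not otherwise pinned down.

## Synthetic cohort generator

The clinical dataset is not distributable, so the generator stands in for
it as a first-class, tested component. Each recording is the sum of three
parts, all seeded:

* **Breathing noise**: Gaussian noise band-limited to 50–800 Hz (4th-order
  Butterworth, zero-phase), amplitude-modulated by a semi-periodic breath
  envelope — one Hann bump per breath over a small baseline, breath rate
  drawn from 0.25–0.6 Hz with per-cycle jitter, and per-breath amplitudes
  mixing shallow breaths with intermittent deeper ones (the irregular
  pattern typical of obstructive breathing).
* **Stertor events** (grades 1–3): semi-periodic harmonic bursts. Each
  event draws a fundamental from 30–150 Hz and 3–6 harmonics with
  geometric amplitude decay 0.7, under a Hann onset/offset envelope;
  gamma-distributed gaps set the event rate. The fundamental range and
  harmonic count place the energy mass below ~300 Hz while keeping
  harmonics inside the 20–400 Hz feature band. Grade acts on three knobs
  at once — rate 0.35/0.65/1.0 events/s, duration 0.2–0.5/0.3–0.8/0.5–1.2
  s, peak amplitude 0.08/0.20/0.45 — so mild grades are genuinely sparse
  and close to the noise floor rather than merely attenuated copies of
  severe ones. Grade 0 contributes nothing. The event schedule (start,
  end, fundamental) is returned for oracle tests.
* **Sensor noise**: white, amplitude 0.01.

Mixtures are rescaled only if they would clip. Cohort metadata (breed,
sex, body-condition band, BOAS grade, post-operative flag) is sampled
from the published encounter-level marginal distributions of the real
cohort; covariates are sampled independently because the joint
distribution is not published. Each recording's stertor grade equals the
encounter's BOAS grade, except that the pre-exercise recording may sit
one grade lower with probability 0.25 — post-exercise noise is never
quieter, and the encounter maximum equals the BOAS grade as the grading
scheme implies.

What the generator does **not** emulate: real airway acoustics (no
physical model of palate vibration), recording artefacts (stethoscope
movement, environmental noise, clipped segments), annotator disagreement
in the labels, and any correlation between covariates and acoustics
beyond grade. Passing the end-to-end suites therefore shows the
*pipeline* — features, network, training, protocol, evaluation — recovers
a grade signal it is designed for; it does not certify clinical
performance on real dogs, which published results place distinctly lower
than on this separable-by-construction task.

## Problem sizes and numerical choices

The scaled protocol used by the end-to-end suites and the reproduction
script (`scaled_protocol_config()`) is 100 dogs (200 recordings of 10 s),
one repeat of 5 folds, 5 random-search candidates over a reduced space
(hidden 16/32, one bidirectional layer, dropout ≤ 0.3, 5 s inputs,
attention width 16, one 32-unit head layer), 30-epoch budgets with
patience 5 on inner folds. These sizes were chosen as the smallest at
which the protocol's statistics are meaningful on a single CPU; the full
protocol simply scales the repeat, candidate and epoch counts.

Numerical details worth recording:

* Binary cross-entropy is always computed from logits in the
  `max(l,0) − l·y + log1p(exp(−|l|))` form; saturated sigmoids cannot
  produce infinities.
* The softmax in attention subtracts the row maximum before
  exponentiation.
* `to_features` guards zero-variance spectrograms (e.g. constant power)
  by returning all-zero features rather than dividing by zero.
* Peak normalisation rejects all-zero recordings with a "degenerate
  recording" error; callers decide whether to skip.
* WAV quantisation scales by 32768 and clamps the top code so that
  decode→encode round-trips are bit-exact on the 16-bit grid.
* Analytic gradients of the full network (both dropout settings) are
  held to 1e-6 relative agreement with central finite differences in the
  test suite.
* Ties in the random search are broken by parameter count then sampling
  order; ties in fold minimisation by fold size then seeded uniform
  choice; ties among equal ROC scores are grouped into single curve
  points.

## Known limitations

* The stridor column is carried but constant; a stridor head would need
  a cohort with many more stridor-positive recordings.
* The severity score is one of several defensible continuous aggregates
  of the ordinal outputs; alternatives (e.g. the first sub-threshold
  probability) would shift ROC curves slightly.
* Encounter combination averages continuous outputs; averaging decoded
  integer grades (`average_decoded = TRUE`) is available but coarser,
  and the mean-vs-max choice matters little on separable synthetic data.
* The generator's covariates are independent of its acoustics given the
  grade, so fold stratification on covariates cannot be stress-tested
  for confounding effects here.
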