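# stertor

Detection and grading of **stertor** — the low-frequency, snoring-like
respiratory noise of brachycephalic obstructive airway syndrome (BOAS) — in
laryngeal electronic-stethoscope recordings of short-faced dog breeds, and
combination of per-recording grades into a per-encounter BOAS
classification.

BOAS affects a large fraction of Pugs, Bulldogs and French Bulldogs, and
the clinical respiratory functional grading (RFG) scheme grades it 0
(none) to 3 (severe) largely from auscultated noise. This package is aimed
at veterinary-bioacoustics researchers who want an automated, repeatable
counterpart to that auscultation step: a full pipeline from WAV audio to a
screening decision, plus the evaluation protocol needed to estimate its
performance without bias on small clinical cohorts, and a synthetic cohort
generator so every stage is testable without clinical data.

## The model

Recordings (mono, 4 kHz, 16-bit, up to 30 s) are peak-normalised, cropped
or zero-padded to a fixed 5 or 10 s, and converted to a spectrogram with a
100 ms Hann window and 50 % overlap — 10 Hz bins, clipped to the
20–400 Hz stethoscope analysis band, i.e. exactly 39 bins and 199 frames
for a 10 s recording. Log-power features are standardised per recording.

The grader is a bidirectional GRU over the frame features. A self-attentive
layer scores each frame's concatenated hidden state
`h_t = [h_t^fwd ; h_t^bwd]` with a small tanh network,

    a_t = softmax_t( v' tanh(W h_t + b) ),   pooled = Σ_t a_t h_t,

so silence and noise receive low weight, and the attention trace shows
which frames drove the decision. A ReLU head maps the pooled state to four
outputs trained as an ordinal regression with cumulative ("NNRank")
targets: the target for grade *g* sets positions `0..g` to 1, each output
gets its own sigmoid and binary cross-entropy, and decoding picks the
lowest position whose output falls below a threshold (default 0.5). The
sum of outputs 1–3 is a continuous severity in `[0, 3]` used for ROC
analysis. Training uses AdamW at learning rate 0.001. The network core
(forward pass and analytic backpropagation) is implemented in
RcppArmadillo and verified against finite differences in the test suite.

Per-recording stertor grades map one-to-one onto BOAS grades; an
encounter's recordings (pre-/post-exercise) are combined by the mean
(default) or maximum of their outputs, and grades 0/1 vs 2/3 define the
clinically significant "BOAS negative/positive" boundary.

Performance estimation follows a nested cross-validation: dogs (never
individual recordings, to prevent identity leakage) are assigned to 5
folds by stratified minimisation balancing sex, breed, body-condition band
and BOAS grade; each fold in turn is held out while a random
hyperparameter search with 4-fold inner CV selects the architecture; 10
repeats give 50 independently optimised runs. ROC curves are combined by
vertical averaging, and post-operative encounters are excluded from test
metrics.

## Worked example

```r
library(stertor)

# 1. Simulate a small cohort of 20 dogs (40 recordings)
coh <- generate_cohort(synth_config(n_dogs = 20, seed = 11),
                       out_dir = tempfile("demo"))
head(coh$manifest[, c("recording_id", "phase", "stertor_grade", "boas_grade")], 3)
#>        recording_id phase stertor_grade boas_grade
#> 1  dog0001_enc1_pre   pre             2          2
#> 2 dog0001_enc1_post  post             2          2
#> 3  dog0002_enc1_pre   pre             2          2

# 2. Features for one recording
rec <- read_wav(file.path(coh$audio_dir, coh$manifest$wav_file[1]))
rec
#> <audio_recording 'dog0001_enc1_pre': 40000 samples @ 4000 Hz (10.00 s), peak 0.507>
feats <- extract_features(rec, input_length_s = 5)
dim(feats)
#> [1] 99 39

# 3. Train a small model on the whole cohort
df <- coh$manifest
all_feats <- lapply(df$wav_file, function(f)
  extract_features(read_wav(file.path(coh$audio_dir, f)), input_length_s = 5))
h <- hyperparameter_set(hidden_size = 16, input_length_s = 5,
                        attention_dim = 16, head_hidden_sizes = 32)
fit <- train_model(all_feats, df$stertor_grade, h, seed = 3,
                   config = training_config(epochs = 80, batch_size = 16))

# 4. Predict a severe and a quiet recording
p <- forward(all_feats[[which(df$stertor_grade == 3)[1]]], fit$params)
round(p$outputs, 3); p$decoded_grade; round(p$severity, 2)
#> [1] 0.992 0.986 0.990 0.763
#> [1] 3
#> [1] 2.74
q <- forward(all_feats[[which(df$stertor_grade == 0)[1]]], fit$params)
round(q$outputs, 3); q$decoded_grade; round(q$severity, 2)
#> [1] 0.991 0.738 0.222 0.016
#> [1] 1
#> [1] 0.98

# 5. Training-set ROC for the binary (grade >= 2) task
sev <- sapply(forward(all_feats, fit$params), `[[`, "severity")
curve <- roc_and_auc(sev, as.integer(df$stertor_grade >= 2))
round(curve$auc, 3)
#> [1] 0.974
op <- operating_point(curve, "youden")
sprintf("sens %.0f%% spec %.0f%%", 100 * op$sensitivity, 100 * op$specificity)
#> [1] "sens 91% spec 100%"
```

The four outputs are the per-position probabilities of the cumulative
encoding (`P(grade >= 0), P(grade >= 1), ...` in spirit); the severe
recording keeps all four high and decodes to grade 3, the quiet one decays
quickly and decodes to grade 1 with severity near 1. (This in-sample AUC
is only a smoke check — unbiased estimates come from `nested_cv()`.)

The full protocol is one call:

```r
runs <- nested_cv(coh$encounters, coh$audio_dir,
                  config = scaled_protocol_config(), master_seed = 7)
ev <- evaluate_runs(runs)   # recording- and encounter-level ROC summaries
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/stertor-cli.R` with subcommands `simulate`, `featurize`,
`train`, `nestedcv`, `predict` and `evaluate`.

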