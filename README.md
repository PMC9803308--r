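# ecgwave

Single-lead ECG denoising, per-sample delineation, and T-wave-alternans
(TWA) detection in one reproducible R pipeline.

## What it does, and for whom

Surface ECG analysis starts from three recurring tasks: cleaning the trace
(baseline wander, powerline, muscle noise), finding the waves (P, QRS, T
and the isoelectric baseline between them), and reading clinically
meaningful patterns off the delineation — here, microvolt-level
beat-to-beat alternation of the T-wave, a marker tied to repolarisation
dispersion and sudden-cardiac-arrest risk. `ecgwave` implements that chain
for researchers and method developers who want an end-to-end, offline,
seed-reproducible testbed:

1. **Denoising auto-encoder (DAE).** A fully-connected encoder/decoder
   over one 370-sample beat: `y = ReLU(W x + b)`,
   `z = sigmoid(W' y + b')`, trained with Adam to minimise the mean
   squared reconstruction error `(1/N) Σ ‖xᵢ − zᵢ‖²` against the clean
   beat. Two layouts: 370–185 (model 1) and 370–370 (model 2).
2. **Conv+BiLSTM delineator.** Four 1-D convolution stages (8, 16, 32, 64
   filters, kernel 3, stride 1, ReLU, length-preserving) feed a single
   bidirectional LSTM whose per-position states are mapped by an affine +
   softmax head to the five classes {P, QRS, T, ISO, PAD}; training
   minimises per-sample categorical cross-entropy. PAD is the
   zero-padding that completes beats shorter than the 370-sample frame.
3. **TWA rule.** Split the T-peak series into even/odd beats, form
   TW = odd − even, count its zero-crossings, and declare alternans iff
   `zc < 0.35·length(TW)` **and** heart rate > 80 BPM; the magnitude is
   `max |TW[2..end−1]|` (0 when not detected).
4. **Synthetic generator.** Labeled single-lead beats (compact Gaussian
   bumps on a flat baseline, exact-SNR noise injection, optional injected
   alternans) so every stage is trainable and testable with no downloads.

Evaluation tooling (confusion matrix, one-vs-rest per-class metrics,
ROC/PR curves), minimal WFDB-compatible record I/O, and a command-line
wrapper round out the package. The sequential LSTM kernels are compiled
(Rcpp/Armadillo) with a plain-R reference implementation kept as a test
oracle.

## Worked example

```r
library(ecgwave)

## 1. simulate paired clean/noisy beats at the 35 dB protocol
train  <- generate_dataset(200, seed = 10)
heldout <- generate_dataset(50, seed = 20)

## 2. train the wide auto-encoder (desk-scale schedule) and score it
cfg <- train_config(epochs = 50, batch_size = 8, learning_rate = 1e-2,
                    lr_schedule = "cosine", seed = 7)
dae <- train_dae(train, cfg, arch = "model2")
round(dae_heldout_snr(dae, heldout)$mean, 2)
#> [1] 25.16

## 3. delineate DAE-reconstructed beats
den_train <- lapply(train$noisy,  function(f) dae_denoise(dae, f))
den_test  <- lapply(heldout$noisy, function(f) dae_denoise(dae, f))
delin <- train_delineator(den_train,
  train_config(epochs = 30, batch_size = 8, learning_rate = 1e-2,
               loss = "categorical_crossentropy", lr_schedule = "cosine",
               seed = 3))
acc <- delineator_accuracy(delin, den_test)
round(acc$overall, 3); round(acc$per_class, 3)
#> [1] 0.907
#>     P   QRS     T   ISO   PAD
#> 0.962 0.971 0.978 0.917 0.818

## 4. quantify injected T-wave alternans (fast-rate beats, depth 0.1)
beats <- rep(list(generate_beat(beat_morphology(
  p_center = 18, qrs_center = 55, t_center = 115, t_width = 7,
  beat_length = 165))), 8)
alt <- inject_alternans(beats, 0.1, "even")
quantify_record(t_peaks_from_frames(alt))
#> <twa_result> rec: zc 0 / length 4, HR 90.9 BPM -> Detected (magnitude 0.1)
```

Reading the numbers: the held-out reconstruction SNR (~25 dB here) is the
power ratio between the clean beat and the reconstruction error, averaged
over beats; the delineator accuracy is the fraction of the 370 positions
per held-out beat labeled correctly (per-class values are recalls — the
ISO/PAD pair is hardest because the beat's end is marked only by where the
sub-1% noise floor stops); the TWA result reproduces the injected depth
exactly in the noise-free case and flags detection because the difference
series never changes sign at a heart rate above 80 BPM.

The same pipeline is scriptable from a shell via the thin wrapper in
`inst/cli/` (`simulate`, `train-dae`, `denoise`, `train-delineate`,
`delineate`, `twa`, `eval`, `twa-reference` subcommands).

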