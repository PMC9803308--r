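# Shared fixtures and a per-session memo so expensive trained models are
# built once and reused across test files (test_dir runs files in one
# session, alphabetically).

.memo_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .memo_env)) assign(name, expr, envir = .memo_env)
  get(name, envir = .memo_env)
}

# a fixed, valid resting-rate morphology
fix_morph <- function(beat_len = 300L) {
  beat_morphology(p_amp = 0.15, p_center = 22, p_width = 5,
                  qrs_amp = 0.9, qrs_center = 75, qrs_width = 3,
                  t_amp = 0.35, t_center = 165, t_width = 9,
                  beat_length = beat_len)
}

# a fixed tachycardic morphology (heart rate > 80 BPM)
fast_morph <- function() {
  beat_morphology(p_amp = 0.15, p_center = 18, p_width = 4,
                  qrs_amp = 0.9, qrs_center = 55, qrs_width = 3,
                  t_amp = 0.35, t_center = 115, t_width = 7,
                  beat_length = 165L)
}

# datasets for the scaled-down training properties (study conditions:
# 200 training pairs at 35 dB, 50 held-out pairs)
train_pairs <- function() memo("train_pairs", generate_dataset(200, seed = 10))
test_pairs <- function() memo("test_pairs", generate_dataset(50, seed = 20))

# scaled-down trained models, shared across test files (cosine-annealed
# short-schedule configuration; see the methods vignette)
trained_dae_m2 <- function() memo("dae_m2", train_dae(
  train_pairs(),
  train_config(epochs = 50, batch_size = 8, learning_rate = 1e-2,
               lr_schedule = "cosine", seed = 7),
  arch = "model2"))

# the end-to-end pipeline feeds the delineator with DAE-reconstructed beats
pipeline_train_frames <- function() memo("pipe_train",
  lapply(train_pairs()$noisy, function(f) dae_denoise(trained_dae_m2(), f)))

pipeline_test_frames <- function() memo("pipe_test",
  lapply(test_pairs()$noisy, function(f) dae_denoise(trained_dae_m2(), f)))

# matched-noise auto-encoder for the 15 dB regime tests
trained_dae_15 <- function() memo("dae_15", train_dae(
  generate_dataset(200, noise = noise_spec(15), seed = 10),
  train_config(epochs = 50, batch_size = 8, learning_rate = 1e-2,
               lr_schedule = "cosine", seed = 7),
  arch = "model2"))

trained_delineator <- function() memo("delineator", train_delineator(
  pipeline_train_frames(),
  train_config(epochs = 30, batch_size = 8, learning_rate = 1e-2,
               loss = "categorical_crossentropy", lr_schedule = "cosine",
               seed = 3)))

# tiny delineator spec for oracle/gradient tests
tiny_spec <- function(Tn = 8L, stages = list(c(2, 3, 1), c(3, 3, 1)),
                      hidden = 3L) {
  delineator_spec(conv_stages = stages, recurrent_hidden = hidden,
                  sequence_length = Tn)
}

tiny_weights <- function(spec, seed = 1) {
  ecgwave:::local_seed(seed, ecgwave:::init_delineator(spec))
}
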