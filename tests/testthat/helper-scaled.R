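# Scaled-down experiment world shared by the module tests and the acceptance
# suite. Data statistics follow the stated conditions (250 Hz default world is
# scaled to 128 Hz / 2 s trials on a 3-channel motor montage; trial counts,
# ERD depths and all thresholds are unscaled). Model widths and epoch counts
# are reduced to fit a CPU test budget; see the methods vignette.

scaled_msfe_config <- function(branches = c(32L, 8L)) {
  msfe_config(branch_kernel_lengths = branches,
              n_temporal_filters = 8L, fusion_filters = 8L,
              fusion_kernel_length = 8L, pool1_length = 8L,
              pool2_length = 4L)
}

scaled_model_config <- function(n_classes = 4L, ablation = "full",
                                branches = c(32L, 8L)) {
  msat_config(n_classes, msfe = scaled_msfe_config(branches),
              decoder = temporal_decoder_config(n_filters = 8L),
              ablation = ablation)
}

scaled_fs <- 128
scaled_T <- 256L

# One synthetic subject on the 3-channel montage.
gen_scaled_subject <- function(seed, n_per_class, erd_depth = 0.8,
                               n_classes = 4L, session_id = 1L) {
  eff <- default_class_effects(n_classes, erd_depth)
  sm <- subject_model(paste0("S", seed), rep(1, 3), seed = seed)
  generate_subject(sm, eff, n_per_class, fs = scaled_fs, T = scaled_T,
                   channel_names = default_montage(3L),
                   session_id = session_id)
}

# Batch 32 / 24 epochs / lr 5e-3: the cheapest recipe that reaches
# convergence on every pilot seed (the reference recipe trains to
# convergence; comparing under-trained models would invert the ablation
# orderings). Early stopping is exercised on a dedicated small fixture
# instead, because these models spend their first 10-20 epochs on a
# chance-level plateau that small-patience stopping mistakes for convergence.
scaled_train_config <- function(seed, max_epochs = 24L) {
  train_config(batch_size = 32L, learning_rate = 5e-3,
               max_epochs = max_epochs, early_stop_patience = Inf,
               seed = seed)
}

# Train on one generated subject, test on an independently drawn one
# (same class effects, fresh noise), mirroring a session-to-session split.
scaled_within_run <- function(seed, ablation = "full", branches = c(32L, 8L),
                              erd_depth = 0.8, n_train = 200L,
                              n_test = 100L) {
  tr <- gen_scaled_subject(seed, n_train, erd_depth)
  te <- gen_scaled_subject(seed + 555L, n_test, erd_depth, session_id = 2L)
  train_within_subject(tr, te,
                       scaled_model_config(ablation = ablation,
                                           branches = branches),
                       scaled_train_config(seed))
}

# A tiny configuration for shape/gradient tests (seconds, not minutes).
tiny_model_config <- function(n_classes = 3L) {
  msat_config(n_classes,
              msfe = msfe_config(branch_kernel_lengths = c(8L, 4L),
                                 n_temporal_filters = 3L,
                                 depth_multiplier = 2L, pool1_length = 2L,
                                 pool2_length = 2L, fusion_filters = 4L,
                                 fusion_kernel_length = 3L, dropout_p = 0),
              decoder = temporal_decoder_config(n_blocks = 2L,
                                                layers_per_block = 1L,
                                                kernel_length = 3L,
                                                n_filters = 4L,
                                                dropout_p = 0),
              attention_heads = 2L)
}
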