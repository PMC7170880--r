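# Shared fixtures, built in code and memoized for the duration of the test
# run. The "main world" is the default experiment corpus used by the dataset,
# training, and saliency checks; the "transfer world" is the two-population
# scenario. Everything is a pure function of fixed seeds.

.fixture_cache <- new.env()

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# 360 records x 120 s, <= 2 seizures each, annotated with the default noise
# model; first 100 records are the gold-labeled evaluation pool.
main_world <- function() {
  memo("main_world", function() {
    sc <- corpus_scenario(n_records = 360, duration_s = 120,
                          max_events_per_record = 2,
                          event_duration_range = c(15, 30))
    recs <- simulate_corpus(sc, seed = 101)
    recs <- simulate_weak_annotations(
      recs, noise_model_config(seed = derive_seed(101, "ann")))
    nev <- 100
    ds <- clip_dataset_spec(negative_sampling_seed = derive_seed(101, "neg"))
    ev <- build_eval_sets(recs[seq_len(nev)], ds)
    list(records = recs,
         eval_records = recs[seq_len(nev)],
         train_records = recs[-seq_len(nev)],
         train = build_training_set(recs[-seq_len(nev)], ds),
         dev = ev$dev, test = ev$test)
  })
}

# Five weak-supervised CNN fits on the main world (shared across checks).
main_weak_fits <- function() {
  memo("main_weak_fits", function() {
    w <- main_world()
    yt <- clip_labels(w$test)
    lapply(1:5, function(s) {
      m <- build_model(dense_inception_config("desk"),
                       seed = derive_seed(101, "w", s))
      fit <- train(m, w$train, w$dev,
                   train_config("desk", epochs = 8, seed = derive_seed(101, "wt", s)))
      fit$test_auroc <- roc_auroc(yt, predict_proba(fit$model, w$test))$auroc
      fit
    })
  })
}

# Two-population world for transfer: generalized/delta-dominant source with
# weak labels; smaller delta-dominant, lower-amplitude target with gold
# labels.
transfer_world <- function() {
  memo("transfer_world", function() {
    src_sc <- corpus_scenario(
      n_records = 320, duration_s = 120, max_events_per_record = 2,
      event_duration_range = c(15, 30),
      morphology_probs = c(generalized_spike_wave = 0.6,
                           focal_evolving = 0.1, rhythmic_delta_ictal = 0.3))
    src <- simulate_corpus(src_sc, seed = 303)
    src <- simulate_weak_annotations(
      src, noise_model_config(seed = derive_seed(303, "ann")))
    ds <- clip_dataset_spec(negative_sampling_seed = derive_seed(303, "neg"))
    src_sets <- build_eval_sets(src[1:50], ds)
    src_train <- build_training_set(src[51:320], ds)
    tgt_sc <- corpus_scenario(
      n_records = 70, duration_s = 120, max_events_per_record = 2,
      event_duration_range = c(15, 30),
      morphology_probs = c(generalized_spike_wave = 0.1,
                           focal_evolving = 0.1, rhythmic_delta_ictal = 0.8),
      amplitude_ranges = list(generalized_spike_wave = c(15, 45),
                              focal_evolving = c(30, 80),
                              rhythmic_delta_ictal = c(14, 36)))
    tgt <- simulate_corpus(tgt_sc, seed = 404)
    tgt <- simulate_weak_annotations(
      tgt, noise_model_config(seed = derive_seed(404, "ann")))
    ds2 <- clip_dataset_spec(negative_sampling_seed = derive_seed(404, "neg"))
    tgt_sets <- build_eval_sets(tgt, ds2)
    yd <- clip_labels(tgt_sets$dev)
    idx <- with_seed_test(5, c(sample(which(yd == 1), 8),
                               sample(which(yd == 0), 16)))
    list(src_train = src_train, src_dev = src_sets$dev,
         tgt_train = tgt_sets$dev$clips[idx],
         tgt_dev = tgt_sets$dev$clips[-idx],
         tgt_test = tgt_sets$test)
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# A zero-signal record for injection arithmetic.
zero_record <- function(duration_s = 60, fs = 200) {
  data <- matrix(0, round(duration_s * fs), 19)
  colnames(data) <- eeg_channels()
  r <- weakeeg:::new_eeg_record("zero", fs, duration_s, data = data)
  r
}

# Quick toy clips: class 1 carries a 3 Hz burst on all channels.
toy_clips <- function(n, seed = 1, amp = 60) {
  with_seed_test(seed, {
    t <- (0:2399) / 200
    lapply(seq_len(n), function(i) {
      lab <- as.integer(i %% 2 == 0)
      x <- matrix(rnorm(2400 * 19, sd = 10), 2400, 19)
      if (lab == 1) x <- x + amp * sin(2 * pi * 3 * t + runif(1, 0, 2 * pi))
      colnames(x) <- eeg_channels()
      eeg_clip(sprintf("toy%03d", i), 0, 12, x, lab,
               label_source = if (lab == 1) "gold" else "sampled_negative")
    })
  })
}

# Small config that keeps unit tests fast but exercises every layer type.
tiny_config <- function(...) {
  dense_inception_config("desk", n_blocks = 2, growth = 2, fc_sizes = c(5, 1),
                         front_pool = 100, pool_out = 3, dropout_p = 0, ...)
}
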