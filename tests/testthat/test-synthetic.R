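# Synthetic EEG generator: background spectra, event injection, artifacts,
# and the calibrated weak-annotation noise model.

test_that("background records have the right geometry, determinism, and spectrum", {
  r <- generate_background(60, 200, seed = 7)
  expect_equal(dim(r$data), c(12000L, 19L))
  expect_identical(colnames(r$data), eeg_channels())
  expect_length(r$gold_events, 0)
  # bit-identical under the same seed
  expect_identical(r$data, generate_background(60, 200, seed = 7)$data)
  # posterior-dominant rhythm: O1 alpha-band power exceeds beta-band power
  x <- r$data[, "O1"]
  P <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * 200 / length(x)
  expect_gt(sum(P[f >= 8 & f <= 12]), sum(P[f >= 13 & f <= 30]))
  # physiologic amplitude scale (tens of microvolts)
  expect_true(all(apply(r$data, 2, sd) > 2) && all(apply(r$data, 2, sd) < 100))
  expect_error(generate_background(-5, 200), class = "weakeeg_invalid_argument")
  expect_error(generate_background(10, 0), class = "weakeeg_invalid_argument")
})

test_that("seizure injection is additive, localized, and bookkept", {
  r <- inject_seizure(zero_record(), seizure_event(20, 10, amplitude_uv = 100))
  idx <- 20 * 200 + 1:(10 * 200)
  rms_in <- sqrt(mean(r$data[idx, "Fp1"]^2))
  rms_out <- sqrt(mean(r$data[-idx, "Fp1"]^2))
  expect_gt(rms_in, 10 * max(rms_out, 1))
  # signal outside the event interval untouched, exactly
  expect_identical(max(abs(r$data[-idx, ])), 0)
  expect_length(r$gold_events, 1)

  # focal seizure is strongest on its focus channels
  rf <- inject_seizure(zero_record(), seizure_event(
    10, 20, morphology = "focal_evolving", focus_channels = c("C4", "F4"),
    amplitude_uv = 60))
  idx2 <- 10 * 200 + 1:(20 * 200)
  expect_gt(sqrt(mean(rf$data[idx2, "C4"]^2)), sqrt(mean(rf$data[idx2, "O1"]^2)))

  expect_error(seizure_event(5, 0), class = "weakeeg_invalid_argument")
  expect_error(inject_seizure(zero_record(10), seizure_event(5, 20)),
               class = "weakeeg_invalid_argument")
  expect_error(inject_seizure(r, seizure_event(25, 10)),
               class = "weakeeg_overlap_error")
})

test_that("artifacts have the right spectra and never create gold events", {
  r <- inject_artifact(zero_record(), artifact_event(
    10, 30, kind = "line_noise_60hz", amplitude_uv = 20))
  x <- r$data[, "Cz"]
  P <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * 200 / length(x)
  half <- f <= 100
  expect_equal(f[half][which.max(P[half][-1]) + 1], 60, tolerance = 0.2)
  expect_length(r$gold_events, 0)
  r2 <- inject_artifact(zero_record(), artifact_event(5, 20, "nonevolving_rhythmic"))
  expect_length(r2$gold_events, 0)
  expect_error(inject_artifact(zero_record(10), artifact_event(5, 20)),
               class = "weakeeg_invalid_argument")
})

test_that("weak annotations hit their calibration targets and are deterministic", {
  sc <- corpus_scenario(n_records = 300, duration_s = 300,
                        max_events_per_record = 3, p_seizure_record = 0.85,
                        min_event_gap_s = 70)
  recs <- simulate_corpus(sc, seed = 11)
  cfg <- noise_model_config(seed = 5)
  ann <- simulate_weak_annotations(recs, cfg)
  q <- annotation_quality(ann, cfg$matching_tol_s)
  expect_gt(q$n_events, 400)
  se_p <- sqrt(0.37 * 0.63 / q$n_annotations)
  se_r <- sqrt(0.45 * 0.55 / q$n_events)
  expect_lt(abs(q$precision - 0.37), 3 * se_p)
  expect_lt(abs(q$recall - 0.45), 3 * se_r)
  # deterministic given the seed
  ann2 <- simulate_weak_annotations(recs, cfg)
  expect_identical(lapply(ann, `[[`, "weak_annotations"),
                   lapply(ann2, `[[`, "weak_annotations"))
  expect_error(simulate_weak_annotations(list(), cfg),
               class = "weakeeg_invalid_argument")
})

test_that("the noise-free limit annotates every event exactly at onset", {
  sc <- corpus_scenario(n_records = 20, duration_s = 200)
  recs <- simulate_corpus(sc, seed = 21)
  perfect <- noise_model_config(target_precision = 1, target_recall = 1,
                                onset_jitter_sd_s = 0, p_late_annotation = 0,
                                seed = 1)
  ann <- simulate_weak_annotations(recs, perfect)
  for (r in ann) {
    expect_equal(nrow(r$weak_annotations), length(r$gold_events))
    if (length(r$gold_events) > 0) {
      onsets <- sort(vapply(r$gold_events, `[[`, numeric(1), "onset_s"))
      expect_equal(sort(r$weak_annotations$time_s), onsets)
      expect_true(all(r$weak_annotations$matches_gold))
    }
  }
})

test_that("a bandpower linear probe separates ictal from background windows", {
  sc <- corpus_scenario(n_records = 100, duration_s = 120)
  recs <- simulate_corpus(sc, seed = 31)
  bands <- eeg_bands()
  window_feats <- function(x) {
    P <- Mod(stats::mvfft(x))^2
    f <- (seq_len(nrow(x)) - 1) * 200 / nrow(x)
    f <- pmin(f, 200 - f)
    feats <- c()
    for (b in bands) {
      e <- colSums(P[f >= b[1] & f < b[2], , drop = FALSE])
      feats <- c(feats, e / pmax(colSums(P), 1e-12))
    }
    c(feats, log1p(colSums(P)))
  }
  clear_of_events <- function(start, events) {
    all(vapply(events, function(e)
      start + 12 <= e$onset_s || start >= e$onset_s + e$duration_s,
      logical(1)))
  }
  X <- NULL; y <- NULL
  for (r in recs) {
    if (length(r$gold_events) == 0) next
    r <- realize_record(r)
    for (e in r$gold_events) {
      if (e$duration_s < 12) next
      i0 <- round(e$onset_s * 200) + 1
      X <- rbind(X, window_feats(r$data[i0:(i0 + 2399), ])); y <- c(y, 1)
    }
    # background windows that intersect no gold event
    for (start in seq(0, r$duration_s - 12, by = 24)) {
      if (!clear_of_events(start, r$gold_events)) next
      b0 <- round(start * 200) + 1
      X <- rbind(X, window_feats(r$data[b0:(b0 + 2399), ])); y <- c(y, 0)
      break
    }
  }
  half <- seq_len(floor(nrow(X) / 2))
  fit <- glmnet::glmnet(X[half, ], y[half], family = "binomial",
                        alpha = 0, lambda = 0.05)
  p <- as.numeric(predict(fit, X[-half, ], type = "response"))
  expect_gt(roc_auroc(y[-half], p)$auroc, 0.9)
})

test_that("fixture corpora round-trip with byte-identical manifests", {
  d1 <- tempfile("corpus1"); d2 <- tempfile("corpus2")
  sc <- corpus_scenario(n_records = 6, duration_s = 60)
  mf1 <- write_fixture_corpus(d1, sc, noise_model_config(seed = 2), seed = 9)
  mf2 <- write_fixture_corpus(d2, sc, noise_model_config(seed = 2), seed = 9)
  expect_length(mf1$record_ids, 6)
  expect_identical(readBin(file.path(d1, "manifest.json"), "raw", 1e6),
                   readBin(file.path(d2, "manifest.json"), "raw", 1e6))
  # manifest quality statistics equal those recomputed from the files
  recs <- read_fixture_corpus(d1)
  q <- annotation_quality(recs, 30)
  expect_equal(q$precision, mf1$realized$precision)
  expect_equal(q$recall, mf1$realized$recall)
  unlink(c(d1, d2), recursive = TRUE)
})
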