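# Occlusion sensitivity maps, sliding prediction traces, and the
# localization score.

test_that("occlusion maps have the right shape and insensitivity behavior", {
  m <- build_model(dense_inception_config("desk"), seed = 3)
  clip <- toy_clips(1, seed = 1)[[1]]
  om <- occlusion_map(m, clip)
  expect_equal(dim(om$values), c(19L, 12L))
  # constant-output model: all-zero map
  const_model <- function(clips) rep(0.7, length(clips))
  om0 <- occlusion_map(const_model, clip$x)
  expect_true(all(om0$values == 0))
  # occluding zeros changes nothing
  zc <- matrix(0, 2400, 19)
  omz <- occlusion_map(m, zc)
  expect_true(all(omz$values == 0))
  # normalization contract
  omn <- occlusion_map(m, clip, normalize = TRUE)
  if (any(omn$values != 0)) expect_equal(max(abs(omn$values)), 1)
  expect_error(occlusion_map(m, matrix(0, 100, 19)),
               class = "weakeeg_invalid_input")
})

test_that("a single-channel analytic model confines saliency to its channel", {
  # logistic of the mean of channel 1 only
  ch1_model <- function(clips)
    vapply(clips, function(x) 1 / (1 + exp(-mean(x[, 1]))), numeric(1))
  set.seed(5)
  x <- matrix(rnorm(2400 * 19, mean = 0.5), 2400, 19)
  om <- occlusion_map(ch1_model, x)
  expect_true(any(om$values[1, ] != 0))
  expect_true(all(om$values[-1, ] == 0))
})

test_that("the batched map equals naive cell-by-cell recomputation", {
  m <- build_model(dense_inception_config("desk"), seed = 6)
  clip <- toy_clips(2, seed = 7)[[2]]
  om <- occlusion_map(m, clip)
  p0 <- predict_proba(m, list(clip$x))
  # matrix-product summation order differs between batch shapes (BLAS
  # blocking), so agreement is to near machine precision, not bit-exact
  for (cell in list(c(1, 1), c(7, 4), c(19, 12), c(10, 6))) {
    xo <- clip$x
    xo[(cell[2] - 1) * 200 + 1:200, cell[1]] <- 0
    expect_equal(unname(om$values[cell[1], cell[2]]),
                 (p0 - predict_proba(m, list(xo))) / p0 * 100,
                 tolerance = 1e-9)
  }
})

test_that("sliding predictions cover the record with the stated alignment", {
  rec <- zero_record(120)
  m <- build_model(dense_inception_config("desk"), seed = 8)
  tr <- sliding_predictions(m, rec, stride_s = 1)
  expect_length(tr$probabilities, 109)
  expect_equal(tr$times_s[1], 0)
  expect_equal(tail(tr$times_s, 1), 108)
  expect_true(all(diff(tr$times_s) == 1))
  # constant-output model gives a constant trace
  trc <- sliding_predictions(function(clips) rep(0.4, length(clips)), rec)
  expect_true(all(trc$probabilities == 0.4))
  expect_error(sliding_predictions(m, zero_record(5)),
               class = "weakeeg_invalid_input")
})

test_that("a trained model's trace rises inside an injected seizure", {
  fits <- main_weak_fits()
  model <- fits[[1]]$model
  sc <- corpus_scenario(n_records = 6, duration_s = 120, p_seizure_record = 1,
                        max_events_per_record = 1,
                        event_duration_range = c(25, 35))
  recs <- lapply(simulate_corpus(sc, seed = 77), realize_record)
  diffs <- vapply(recs, function(r) {
    tr <- sliding_predictions(model, r, stride_s = 2)
    ev <- r$gold_events[[1]]
    inside <- tr$times_s >= ev$onset_s - 6 &
      tr$times_s <= ev$onset_s + ev$duration_s - 6
    mean(tr$probabilities[inside]) - mean(tr$probabilities[!inside])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("localization scores behave on perfect, uniform, and disjoint maps", {
  ev <- seizure_event(100, 6, focus_channels = c("Fp1", "Fp2"))
  vals <- matrix(0, 19, 12, dimnames = list(eeg_channels(), NULL))
  # clip starts at 98 s; event covers seconds 3..8 of the clip
  vals[1:2, 3:8] <- 5
  map <- structure(list(values = vals, baseline_prob = 0.9, window_s = 1,
                        normalized = FALSE, degenerate = FALSE,
                        record_id = "r", start_s = 98), class = "occlusion_map")
  expect_equal(localization_score(map, ev), 1.0)
  # uniform map: expectation over random tie-breaks equals the support fraction
  uni <- map; uni$values[] <- 1
  scores <- vapply(1:400, function(s) localization_score(uni, ev, tie_seed = s),
                   numeric(1))
  expect_lt(abs(mean(scores) - 12 / 228), 0.015)
  # event outside the clip
  far <- seizure_event(500, 5)
  expect_error(localization_score(map, far),
               class = "weakeeg_undefined_score")
})
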