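# Clip dataset construction: resampling, positive extraction, negative
# sampling, class balancing, and the record-disjoint evaluation split.

test_that("resampling has exact length arithmetic and an identity fast path", {
  x <- rnorm(2560)
  expect_length(resample_to_200hz(x, 256), 2000)
  expect_identical(resample_to_200hz(x, 200), x)
  expect_error(resample_to_200hz(x, -1), class = "weakeeg_invalid_argument")
})

test_that("a pure tone survives resampling with <1% passband error", {
  n <- 4096
  t <- (0:(n - 1)) / 512
  y <- resample_to_200hz(sin(2 * pi * 10 * t), 512)
  expect_length(y, round(n * 200 / 512))
  ref <- sin(2 * pi * 10 * (0:(length(y) - 1)) / 200)
  interior <- 150:(length(y) - 150)
  expect_lt(max(abs(y[interior] - ref[interior])), 0.01)
  # periodogram peak stays at 10 Hz
  P <- Mod(stats::fft(y))^2
  f <- (seq_along(y) - 1) * 200 / length(y)
  half <- f <= 100
  expect_equal(f[half][which.max(P[half][-1]) + 1], 10, tolerance = 0.3)
})

test_that("positive clips are anchored at annotations with exact shapes", {
  r <- zero_record(200)
  r$weak_annotations <- data.frame(time_s = c(100, 195), text = "seizure",
                                   source = "technician", matches_gold = TRUE)
  clips <- extract_positive_clips(list(r), 12, "weak")
  expect_length(clips, 1)
  expect_equal(clips[[1]]$start_s, 100)
  expect_equal(dim(clips[[1]]$x), c(2400L, 19L))
  expect_equal(attr(clips, "n_skipped"), 1L)
  # gold anchoring and the 60-s shape contract
  r2 <- zero_record(200)
  r2 <- inject_seizure(r2, seizure_event(30, 20))
  g60 <- extract_positive_clips(list(r2), 60, "gold")
  expect_equal(dim(g60[[1]]$x), c(12000L, 19L))
  expect_equal(g60[[1]]$label_source, "gold")
})

test_that("negative sampling uses only annotation-free records, deterministically", {
  sc <- corpus_scenario(n_records = 30, duration_s = 90)
  recs <- simulate_corpus(sc, seed = 41)
  recs <- simulate_weak_annotations(recs, noise_model_config(seed = 42))
  ann_free <- vapply(recs, function(r) nrow(r$weak_annotations) == 0, logical(1))
  neg <- sample_negative_clips(recs, 40, 12, seed = 3)
  expect_length(neg, 40)
  free_ids <- vapply(recs[ann_free], `[[`, character(1), "record_id")
  expect_true(all(vapply(neg, `[[`, character(1), "record_id") %in% free_ids))
  expect_true(all(clip_labels(neg) == 0))
  neg2 <- sample_negative_clips(recs, 40, 12, seed = 3)
  expect_identical(vapply(neg, `[[`, numeric(1), "start_s"),
                   vapply(neg2, `[[`, numeric(1), "start_s"))
  # fully annotated corpus is unsatisfiable
  all_ann <- lapply(recs, function(r) {
    r$weak_annotations <- data.frame(time_s = 1, text = "sz",
                                     source = "technician", matches_gold = FALSE)
    r
  })
  expect_error(sample_negative_clips(all_ann, 5, 12, seed = 1),
               class = "weakeeg_unsatisfiable_sampling")
})

test_that("training sets are balanced and conserve positives", {
  w <- main_world()
  tr <- w$train
  y <- clip_labels(tr)
  expect_equal(mean(y), 0.5, tolerance = 1 / length(y))
  expect_equal(sum(y), tr$info$n_pos)
  # undersampling removes only negatives: every weak positive is retained
  pos_in <- extract_positive_clips(w$train_records, 12, "weak")
  expect_equal(tr$info$n_pos, length(pos_in))
  # parameterized positive fraction
  ds2 <- clip_dataset_spec(train_pos_fraction = 0.2, negative_sampling_seed = 8)
  tr2 <- build_training_set(w$train_records[1:80], ds2)
  expect_equal(mean(clip_labels(tr2)), 0.2, tolerance = 0.01)
  # empty-class error
  blank <- lapply(w$train_records[1:3], function(r) {
    r$weak_annotations <- weakeeg:::empty_annotations(); r
  })
  expect_error(build_training_set(blank, clip_dataset_spec()),
               class = "weakeeg_empty_class")
})

test_that("evaluation sets hit the 80-20 balance and are record-disjoint", {
  w <- main_world()
  pool_y <- c(clip_labels(w$dev), clip_labels(w$test))
  expect_equal(mean(pool_y), 0.2, tolerance = 0.005)
  dev_ids <- unique(vapply(w$dev$clips, `[[`, character(1), "record_id"))
  test_ids <- unique(vapply(w$test$clips, `[[`, character(1), "record_id"))
  expect_length(intersect(dev_ids, test_ids), 0)
  # and the training records never appear in either evaluation set
  train_ids <- unique(vapply(w$train$clips, `[[`, character(1), "record_id"))
  expect_length(intersect(train_ids, union(dev_ids, test_ids)), 0)
  # split-infeasible error with a single gold-positive record
  one <- list(inject_seizure(zero_record(120), seizure_event(30, 20)),
              zero_record(120))
  one[[1]]$record_id <- "a"; one[[2]]$record_id <- "b"
  expect_error(build_eval_sets(one, clip_dataset_spec()),
               class = "weakeeg_split_infeasible")
})

test_that("clip and spec constructors enforce their contracts", {
  expect_error(eeg_clip("r", 0, 12, matrix(0, 100, 19), 1),
               class = "weakeeg_invalid_argument")
  expect_error(clip_dataset_spec(clip_len_s = 30),
               class = "weakeeg_invalid_argument")
  expect_error(clip_dataset_spec(train_pos_fraction = 1.5),
               class = "weakeeg_invalid_argument")
})
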