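# Corpus-level simulation: scenario configuration, lazy record layouts (gold
# events and artifacts without the realized signal, so corpora with thousands
# of events fit in memory), deterministic signal realization, and the on-disk
# container format.

#' Corpus scenario configuration
#'
#' The stated world for synthetic corpora. Defaults describe a mixed
#' monitoring population: 180-s records, 60% of records containing one or two
#' seizures of 15-40 s, half the records carrying rhythmic artifact and/or
#' 60 Hz line noise, and morphology mixes over the three
#' implemented seizure types (generalized spike-wave ~3 Hz, focal chirp 8 to
#' 20 Hz, rhythmic ictal delta 1-3 Hz). Default event amplitudes overlap
#' the background and artifact amplitudes: the synthetic background is far
#' less rich than real EEG, and full clinical spike-wave amplitudes would
#' make clips separable by raw power alone, which no EEG classification
#' problem is in practice. Focal discharges get higher local amplitudes than
#' the broad-field morphologies because they drive only a two-electrode
#' focus.
#'
#' @param n_records Number of records.
#' @param duration_s Record duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param p_seizure_record Probability a record contains any seizure.
#' @param max_events_per_record Maximum seizures per record (1..max uniform).
#' @param event_duration_range Seizure duration range (s).
#' @param min_event_gap_s Minimum separation between seizures in a record
#'   (default 20 s). Set it above twice the annotation-matching tolerance
#'   when measuring recall, so that tolerance windows of neighboring events
#'   cannot double-count a single marker.
#' @param p_artifact Probability a record carries a rhythmic artifact; line
#'   noise is added independently with the same probability.
#' @param morphology_probs Named probabilities over the three morphologies.
#' @param amplitude_ranges Named list of `c(lo, hi)` amplitude ranges (uV).
#' @param rhythm_profile Optional background override, see
#'   [generate_background()].
#' @return An object of class `corpus_scenario`.
#' @export
corpus_scenario <- function(n_records = 40, duration_s = 180, fs = 200,
                            p_seizure_record = 0.6, max_events_per_record = 2,
                            event_duration_range = c(15, 40),
                            min_event_gap_s = 20,
                            p_artifact = 0.5,
                            morphology_probs = c(generalized_spike_wave = 0.5,
                                                 focal_evolving = 0.3,
                                                 rhythmic_delta_ictal = 0.2),
                            amplitude_ranges = list(
                              generalized_spike_wave = c(15, 45),
                              focal_evolving = c(30, 80),
                              rhythmic_delta_ictal = c(20, 60)),
                            rhythm_profile = NULL) {
  stopifnot(n_records >= 1, duration_s > 0, fs > 0,
            all(names(morphology_probs) %in% SEIZURE_MORPHOLOGIES))
  structure(list(n_records = n_records, duration_s = duration_s, fs = fs,
                 p_seizure_record = p_seizure_record,
                 max_events_per_record = max_events_per_record,
                 event_duration_range = event_duration_range,
                 min_event_gap_s = min_event_gap_s,
                 p_artifact = p_artifact,
                 morphology_probs = morphology_probs,
                 amplitude_ranges = amplitude_ranges,
                 rhythm_profile = rhythm_profile),
            class = "corpus_scenario")
}

# Lay out one record: choose events and artifacts but do not render signal.
# Backgrounds are heterogeneous across records (amplitude, rhythm prominence,
# sensor noise, per-electrode gains), as they are across patients.
simulate_record_layout <- function(scenario, record_id, seed) {
  sc <- scenario
  with_seed(seed, {
    prof <- utils::modifyList(list(
      pink_rms_uv = stats::runif(1, 7, 22),
      alpha_amp_uv = stats::runif(1, 5, 35),
      sensor_sd_uv = stats::runif(1, 1, 3)),
      if (is.null(sc$rhythm_profile)) list() else sc$rhythm_profile)
    rec <- new_eeg_record(record_id, sc$fs, sc$duration_s,
                          sim = list(seed = derive_seed(seed, "signal"),
                                     rhythm_profile = prof,
                                     channel_gains = stats::runif(19, 0.7, 1.3)))
    n_ev <- if (stats::runif(1) < sc$p_seizure_record)
      sample.int(sc$max_events_per_record, 1) else 0L
    guard <- 5; min_gap <- sc$min_event_gap_s
    placed <- matrix(numeric(0), 0, 2)
    for (k in seq_len(n_ev)) {
      dur <- stats::runif(1, sc$event_duration_range[1], sc$event_duration_range[2])
      for (try in 1:50) {
        onset <- stats::runif(1, guard, max(guard, sc$duration_s - dur - guard))
        ok <- all(apply(placed, 1, function(iv)
          !intervals_overlap(onset - min_gap, onset + dur + min_gap, iv[1], iv[2])))
        if (nrow(placed) == 0) ok <- TRUE
        if (ok) {
          morph <- sample(names(sc$morphology_probs), 1, prob = sc$morphology_probs)
          ar <- sc$amplitude_ranges[[morph]]
          focus <- switch(morph,
            generalized_spike_wave = NULL,
            focal_evolving = sample(list(c("F4", "C4"), c("F3", "C3"),
                                         c("T3", "T5"), c("T4", "T6")), 1)[[1]],
            rhythmic_delta_ictal = NULL)
          ev <- seizure_event(onset, dur, morphology = morph,
                              focus_channels = focus,
                              amplitude_uv = stats::runif(1, ar[1], ar[2]))
          rec$gold_events <- c(rec$gold_events, list(ev))
          placed <- rbind(placed, c(onset, onset + dur))
          break
        }
      }
    }
    if (stats::runif(1) < sc$p_artifact) {
      dur <- stats::runif(1, 10, 30)
      onset <- stats::runif(1, 0, sc$duration_s - dur)
      rec$artifacts <- c(rec$artifacts, list(artifact_event(
        onset, dur, kind = "nonevolving_rhythmic",
        affected_channels = sample(eeg_channels(), 8),
        amplitude_uv = stats::runif(1, 30, 90),
        freq_hz = stats::runif(1, 4, 7))))
    }
    if (stats::runif(1) < sc$p_artifact) {
      dur <- stats::runif(1, 10, 40)
      onset <- stats::runif(1, 0, sc$duration_s - dur)
      rec$artifacts <- c(rec$artifacts, list(artifact_event(
        onset, dur, kind = "line_noise_60hz",
        amplitude_uv = stats::runif(1, 5, 15))))
    }
    rec
  })
}

#' Realize the signal of a lazily simulated record
#'
#' Renders background plus all laid-out gold events and artifacts from the
#' record's stored simulation seed. A no-op when the signal is present.
#'
#' @param record An `eeg_record`.
#' @return The record with its `data` matrix populated.
#' @export
realize_record <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  if (!is.null(record$data)) return(record)
  if (is.null(record$sim))
    abort_invalid("record has neither signal nor simulation parameters")
  bg <- generate_background(record$duration_s, record$fs,
                            seed = record$sim$seed,
                            rhythm_profile = record$sim$rhythm_profile,
                            record_id = record$record_id)
  data <- bg$data
  for (e in record$gold_events) data <- render_seizure(data, e, record$fs)
  for (a in record$artifacts) data <- render_artifact(data, a, record$fs)
  if (!is.null(record$sim$channel_gains))
    data <- sweep(data, 2, record$sim$channel_gains, "*")
  record$data <- data
  record
}

#' Simulate a corpus of records
#'
#' Generates `scenario$n_records` seeded records. With `signals = FALSE` only
#' the layouts (events, artifacts, simulation seeds) are created, which is
#' enough for annotation simulation and keeps large corpora cheap; signals are
#' realized on demand by [realize_record()] and are identical either way.
#'
#' @param scenario A [corpus_scenario()].
#' @param seed Integer corpus seed.
#' @param signals Realize signal matrices now? Default FALSE.
#' @return List of `eeg_record`s with ids `"rec001"`, `"rec002"`, ...
#' @export
simulate_corpus <- function(scenario = corpus_scenario(), seed = 1,
                            signals = FALSE) {
  stopifnot(inherits(scenario, "corpus_scenario"))
  records <- lapply(seq_len(scenario$n_records), function(i)
    simulate_record_layout(scenario, sprintf("rec%03d", i),
                           derive_seed(seed, "record", i)))
  if (signals) records <- lapply(records, realize_record)
  records
}

#' Write a simulated corpus to disk
#'
#' Container format: one RDS file per record (signal matrix in microvolts,
#' sampling rate, channel names, gold and weak annotation tables) plus a JSON
#' manifest listing record ids, event counts, and the realized noise-model
#' statistics. Rerunning with the same scenario and seed reproduces the
#' manifest byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param scenario A [corpus_scenario()].
#' @param noise_cfg A [noise_model_config()] for the weak annotations.
#' @param seed Corpus seed.
#' @param signals Write realized signal matrices (default TRUE).
#' @return The manifest, invisibly; written as `manifest.json`.
#' @export
write_fixture_corpus <- function(out_dir, scenario = corpus_scenario(),
                                 noise_cfg = noise_model_config(), seed = 1,
                                 signals = TRUE) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  records <- simulate_corpus(scenario, seed, signals = FALSE)
  records <- simulate_weak_annotations(records, noise_cfg)
  qual <- annotation_quality(records, noise_cfg$matching_tol_s)
  for (r in records) {
    if (signals) r <- realize_record(r)
    saveRDS(r, file.path(out_dir, paste0(r$record_id, ".rds")), compress = FALSE)
  }
  manifest <- list(
    format = "weakeeg-corpus-v1",
    seed = seed,
    fs = scenario$fs,
    record_ids = vapply(records, `[[`, character(1), "record_id"),
    n_gold_events = vapply(records, function(r) length(r$gold_events), integer(1)),
    n_weak_annotations = vapply(records, function(r) nrow(r$weak_annotations), integer(1)),
    noise_model = list(target_precision = noise_cfg$target_precision,
                       target_recall = noise_cfg$target_recall,
                       matching_tol_s = noise_cfg$matching_tol_s),
    realized = list(precision = qual$precision, recall = qual$recall,
                    n_events = qual$n_events, n_annotations = qual$n_annotations))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(manifest)
}

#' Read a corpus written by [write_fixture_corpus()]
#'
#' @param dir Corpus directory containing `manifest.json` and record files.
#' @return List of `eeg_record`s in manifest order.
#' @export
read_fixture_corpus <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  lapply(mf$record_ids, function(id) readRDS(file.path(dir, paste0(id, ".rds"))))
}
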