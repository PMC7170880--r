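# Synthetic scalp-EEG simulator: seeded 19-channel records with known seizure
# ground truth, common artifacts, and a calibrated noisy ("weak") annotation
# model. Real hospital EEG with archived technician annotations is PHI
# restricted, so every downstream experiment in this package runs on records
# from this module.

SEIZURE_MORPHOLOGIES <- c("generalized_spike_wave", "focal_evolving",
                          "rhythmic_delta_ictal")
ARTIFACT_KINDS <- c("line_noise_60hz", "nonevolving_rhythmic")

#' Construct a seizure event
#'
#' A gold ground-truth ictal interval with one of three morphologies seen in
#' clinical error analyses: generalized spike-wave (~3 Hz spike-and-slow-wave
#' over a broad, frontally emphasised field), a focal seizure with fast
#' spiking that evolves in frequency (linear chirp), and rhythmic ictal delta
#' (1-3 Hz frontal slow waves).
#'
#' @param onset_s Onset in seconds from record start (0-based).
#' @param duration_s Event duration in seconds; must be > 0.
#' @param morphology One of `"generalized_spike_wave"`, `"focal_evolving"`,
#'   `"rhythmic_delta_ictal"`.
#' @param focus_channels Channels carrying the full-amplitude discharge;
#'   defaults depend on morphology (frontal set for generalized/delta,
#'   right fronto-central for focal).
#' @param freq_hz Dominant frequency in Hz (for `focal_evolving` the chirp
#'   start frequency).
#' @param amplitude_uv Peak amplitude in microvolts on focus channels.
#' @param freq_end_hz Chirp end frequency (focal morphology only).
#' @return An object of class `seizure_event`.
#' @export
seizure_event <- function(onset_s, duration_s,
                          morphology = "generalized_spike_wave",
                          focus_channels = NULL,
                          freq_hz = NULL, amplitude_uv = 100,
                          freq_end_hz = NULL) {
  morphology <- match.arg(morphology, SEIZURE_MORPHOLOGIES)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    abort_invalid("seizure duration_s must be > 0")
  if (!is.numeric(onset_s) || onset_s < 0)
    abort_invalid("seizure onset_s must be >= 0")
  if (is.null(freq_hz))
    freq_hz <- switch(morphology, generalized_spike_wave = 3,
                      focal_evolving = 8, rhythmic_delta_ictal = 2)
  if (is.null(freq_end_hz))
    freq_end_hz <- if (morphology == "focal_evolving") 20 else freq_hz
  if (is.null(focus_channels))
    focus_channels <- switch(morphology,
      generalized_spike_wave = c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz"),
      focal_evolving = c("F4", "C4"),
      rhythmic_delta_ictal = c("Fp1", "Fp2", "F3", "F4", "Fz"))
  if (!all(focus_channels %in% eeg_channels()))
    abort_invalid("focus_channels must be a subset of the 10-20 montage")
  structure(list(onset_s = onset_s, duration_s = duration_s,
                 morphology = morphology, focus_channels = focus_channels,
                 params = list(freq_hz = freq_hz, amplitude_uv = amplitude_uv,
                               freq_end_hz = freq_end_hz)),
            class = "seizure_event")
}

#' Construct an artifact event
#'
#' Non-ictal signal contaminants: 60 Hz AC line noise and non-evolving
#' rhythmic artifact (constant frequency and amplitude), the canonical
#' false-positive triggers for seizure detectors.
#'
#' @param onset_s,duration_s Interval in seconds (half-open).
#' @param kind `"line_noise_60hz"` or `"nonevolving_rhythmic"`.
#' @param affected_channels Channels receiving the artifact (default all 19).
#' @param amplitude_uv Peak amplitude in microvolts.
#' @param freq_hz Frequency of the rhythmic artifact (ignored for line noise,
#'   which is fixed at 60 Hz).
#' @return An object of class `artifact_event`.
#' @export
artifact_event <- function(onset_s, duration_s, kind = "nonevolving_rhythmic",
                           affected_channels = eeg_channels(),
                           amplitude_uv = 40, freq_hz = 5) {
  kind <- match.arg(kind, ARTIFACT_KINDS)
  if (!is.numeric(duration_s) || duration_s <= 0)
    abort_invalid("artifact duration_s must be > 0")
  if (onset_s < 0) abort_invalid("artifact onset_s must be >= 0")
  if (!all(affected_channels %in% eeg_channels()))
    abort_invalid("affected_channels must be a subset of the 10-20 montage")
  structure(list(onset_s = onset_s, duration_s = duration_s, kind = kind,
                 affected_channels = affected_channels,
                 amplitude_uv = amplitude_uv,
                 freq_hz = if (kind == "line_noise_60hz") 60 else freq_hz),
            class = "artifact_event")
}

new_eeg_record <- function(record_id, fs, duration_s, data = NULL,
                           gold_events = list(), artifacts = list(),
                           weak_annotations = empty_annotations(),
                           sim = NULL) {
  structure(list(record_id = record_id, fs = fs, duration_s = duration_s,
                 channels = eeg_channels(), data = data,
                 gold_events = gold_events, artifacts = artifacts,
                 weak_annotations = weak_annotations, sim = sim),
            class = "eeg_record")
}

empty_annotations <- function() {
  data.frame(time_s = numeric(0), text = character(0), source = character(0),
             matches_gold = logical(0), stringsAsFactors = FALSE)
}

#' @method print eeg_record
#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record %s: %.0f s @ %g Hz, %d ch, %d gold events, %d artifacts, %d weak annotations%s>\n",
              x$record_id, x$duration_s, x$fs, length(x$channels),
              length(x$gold_events), length(x$artifacts),
              nrow(x$weak_annotations),
              if (is.null(x$data)) ", signal not realized" else ""))
  invisible(x)
}

# ---- background signal -----------------------------------------------------

default_rhythm_profile <- function() {
  list(pink_rms_uv = 12,    # broadband 1/f background RMS
       alpha_amp_uv = 20,   # posterior dominant rhythm peak amplitude on O1/O2
       alpha_band = c(8.5, 11.5),
       sensor_sd_uv = 2)    # per-channel white sensor noise
}

# 1/f^alpha (alpha = 1) noise via spectral shaping, unit variance.
pink_noise <- function(n, f_lo = 0.5, fs = 200) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f) # two-sided frequency axis
  g <- 1 / sqrt(pmax(f, f_lo))
  g[1] <- 0 # remove DC
  x <- Re(stats::fft(X * g, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate background EEG
#'
#' A minimal background model for awake scalp EEG: per-channel 1/f broadband
#' noise, a shared posterior-dominant alpha rhythm (8-12 Hz, strongest over
#' O1/O2 with anterior falloff and slow amplitude waxing/waning), and white
#' sensor noise. Amplitudes are in a physiologic range of tens of microvolts.
#'
#' @param duration_s Record duration in seconds (> 0).
#' @param fs Sampling rate in Hz (default 200).
#' @param seed Integer seed; the record is a pure function of its arguments.
#' @param rhythm_profile Optional list overriding `pink_rms_uv`,
#'   `alpha_amp_uv`, `alpha_band`, `sensor_sd_uv`.
#' @param record_id Identifier stored on the record.
#' @return An `eeg_record` with a `round(duration_s * fs) x 19` signal matrix
#'   in microvolts and no gold events.
#' @export
generate_background <- function(duration_s, fs = 200, seed = 1,
                                rhythm_profile = NULL, record_id = "rec") {
  check_scalar_pos(duration_s, "duration_s")
  check_scalar_pos(fs, "fs")
  prof <- utils::modifyList(default_rhythm_profile(),
                            if (is.null(rhythm_profile)) list() else rhythm_profile)
  n <- round(duration_s * fs)
  ch <- eeg_channels()
  data <- with_seed(seed, {
    m <- matrix(0, n, length(ch))
    for (j in seq_along(ch)) m[, j] <- prof$pink_rms_uv * pink_noise(n, fs = fs)
    # posterior dominant rhythm, shared oscillator with per-channel weight
    fa <- stats::runif(1, prof$alpha_band[1], prof$alpha_band[2])
    t <- (seq_len(n) - 1) / fs
    env <- 1 + 0.35 * sin(2 * pi * 0.11 * t + stats::runif(1, 0, 2 * pi))
    osc <- sin(2 * pi * fa * t + stats::runif(1, 0, 2 * pi)) * env
    wa <- c(Fp1 = .08, Fp2 = .08, F3 = .12, F4 = .12, C3 = .25, C4 = .25,
            P3 = .55, P4 = .55, O1 = 1, O2 = 1, F7 = .1, F8 = .1,
            T3 = .2, T4 = .2, T5 = .6, T6 = .6, Fz = .12, Cz = .25, Pz = .6)
    m <- m + outer(osc, prof$alpha_amp_uv * wa[ch])
    m + matrix(stats::rnorm(n * length(ch), sd = prof$sensor_sd_uv), n)
  })
  colnames(data) <- ch
  new_eeg_record(record_id, fs, duration_s, data = data,
                 sim = list(seed = seed, rhythm_profile = rhythm_profile))
}

# ---- event waveform rendering ---------------------------------------------

# Raised-cosine on/off ramps so the added waveform is exactly zero outside
# the event interval.
event_envelope <- function(n, fs, ramp_s = 1) {
  ramp <- min(ramp_s, (n / fs) / 4)
  k <- max(1L, round(ramp * fs))
  e <- rep(1, n)
  up <- 0.5 * (1 - cos(pi * seq_len(k) / k))
  e[seq_len(k)] <- up
  e[n + 1 - seq_len(k)] <- rev(up)
  e
}

seizure_waveform <- function(event, fs) {
  n <- round(event$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  p <- event$params
  w <- switch(event$morphology,
    generalized_spike_wave = {
      # harmonic-rich spike-and-slow-wave complex at freq_hz
      f <- p$freq_hz
      s <- sin(2 * pi * f * t) + 0.6 * sin(4 * pi * f * t + 0.8) +
        0.35 * sin(6 * pi * f * t + 1.6)
      s / max(abs(s))
    },
    focal_evolving = {
      # linear chirp freq_hz -> freq_end_hz with a sharpening harmonic
      k <- (p$freq_end_hz - p$freq_hz) / event$duration_s
      ph <- 2 * pi * (p$freq_hz * t + 0.5 * k * t^2)
      s <- sin(ph) + 0.4 * sin(2 * ph)
      s / max(abs(s))
    },
    rhythmic_delta_ictal = {
      f <- max(1, min(3, p$freq_hz))
      s <- sin(2 * pi * f * t) + 0.2 * sin(4 * pi * f * t)
      s / max(abs(s))
    })
  p$amplitude_uv * w * event_envelope(n, fs)
}

artifact_waveform <- function(artifact, fs) {
  n <- round(artifact$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  # constant frequency, constant amplitude: no evolution by construction
  artifact$amplitude_uv * sin(2 * pi * artifact$freq_hz * t) *
    event_envelope(n, fs, ramp_s = 0.5)
}

event_sample_span <- function(onset_s, duration_s, fs, n_total) {
  i0 <- round(onset_s * fs) + 1L
  n <- round(duration_s * fs)
  if (i0 < 1L || i0 + n - 1L > n_total)
    abort_invalid("event interval lies outside the record")
  seq.int(i0, i0 + n - 1L)
}

render_seizure <- function(data, event, fs) {
  idx <- event_sample_span(event$onset_s, event$duration_s, fs, nrow(data))
  w <- seizure_waveform(event, fs)
  weights <- switch(event$morphology,
    generalized_spike_wave = pmax(spatial_weights(event$focus_channels), 0.35),
    focal_evolving = spatial_weights(event$focus_channels),
    rhythmic_delta_ictal = spatial_weights(event$focus_channels))
  data[idx, ] <- data[idx, ] + outer(w, weights)
  data
}

render_artifact <- function(data, artifact, fs) {
  idx <- event_sample_span(artifact$onset_s, artifact$duration_s, fs, nrow(data))
  w <- artifact_waveform(artifact, fs)
  j <- match(artifact$affected_channels, eeg_channels())
  data[idx, j] <- data[idx, j] + outer(w, rep(1, length(j)))
  data
}

intervals_overlap <- function(a0, a1, b0, b1) a0 < b1 && b0 < a1

#' Inject a seizure into a record
#'
#' Adds the event's waveform on its focus channels with a smooth spatial
#' falloff to the rest of the montage, appends the event to the record's gold
#' ground truth, and leaves the signal outside the (half-open) event interval
#' bit-identical. Gold events may not overlap.
#'
#' @param record An `eeg_record` with realized signal.
#' @param event A [seizure_event()].
#' @return The modified record.
#' @export
inject_seizure <- function(record, event) {
  stopifnot(inherits(record, "eeg_record"), inherits(event, "seizure_event"))
  if (event$onset_s + event$duration_s > record$duration_s + 1e-9)
    abort_invalid("seizure interval extends past the end of the record")
  for (ev in record$gold_events)
    if (intervals_overlap(event$onset_s, event$onset_s + event$duration_s,
                          ev$onset_s, ev$onset_s + ev$duration_s))
      abort_invalid("overlapping gold seizure events are not allowed",
                    class = "weakeeg_overlap_error")
  if (!is.null(record$data))
    record$data <- render_seizure(record$data, event, record$fs)
  record$gold_events <- c(record$gold_events, list(event))
  record
}

#' Inject an artifact into a record
#'
#' `line_noise_60hz` adds a 60 Hz sinusoid on the affected channels;
#' `nonevolving_rhythmic` adds a fixed-frequency, fixed-amplitude rhythmic
#' waveform. No gold event is created.
#'
#' @param record An `eeg_record`.
#' @param artifact An [artifact_event()].
#' @return The modified record.
#' @export
inject_artifact <- function(record, artifact) {
  stopifnot(inherits(record, "eeg_record"), inherits(artifact, "artifact_event"))
  if (artifact$onset_s + artifact$duration_s > record$duration_s + 1e-9)
    abort_invalid("artifact interval extends past the end of the record")
  if (!is.null(record$data))
    record$data <- render_artifact(record$data, artifact, record$fs)
  record$artifacts <- c(record$artifacts, list(artifact))
  record
}

# ---- weak annotation noise model ------------------------------------------

#' Noisy annotation model configuration
#'
#' Calibration of the simulated "weak" annotations to the measured quality of
#' archived clinical annotations: overall precision 0.37 and recall 0.45, with
#' a strong but not absolute tendency for markers to land near seizure onset.
#'
#' @param target_precision Fraction of annotations that mark a real seizure.
#' @param target_recall Fraction of seizures that receive an annotation.
#' @param onset_jitter_sd_s SD (s) of Gaussian jitter around onset for markers
#'   that land near onset.
#' @param p_late_annotation Probability a marker lands uniformly inside the
#'   event rather than near its onset.
#' @param matching_tol_s An annotation matches a gold event when it falls in
#'   `[onset - tol, offset + tol]`; 30 s reflects page-level EEG reading.
#' @param seed Integer seed for the annotation process.
#' @return An object of class `noise_model_config`.
#' @export
noise_model_config <- function(target_precision = 0.37, target_recall = 0.45,
                               onset_jitter_sd_s = 3, p_late_annotation = 0.25,
                               matching_tol_s = 30, seed = 1) {
  if (target_precision <= 0 || target_precision > 1)
    abort_invalid("target_precision must be in (0, 1]")
  if (target_recall <= 0 || target_recall > 1)
    abort_invalid("target_recall must be in (0, 1]")
  structure(list(target_precision = target_precision,
                 target_recall = target_recall,
                 onset_jitter_sd_s = onset_jitter_sd_s,
                 p_late_annotation = p_late_annotation,
                 matching_tol_s = matching_tol_s, seed = seed),
            class = "noise_model_config")
}

annotation_texts <- c("seizure", "sz", "possible seizure", "seizure?")
annotation_sources <- c("technician", "fellow", "student")

# Complement of the union of tolerance-padded gold windows within [0, dur],
# as a 2-column matrix of [start, end) intervals.
free_intervals <- function(record, tol) {
  if (length(record$gold_events) == 0)
    return(matrix(c(0, record$duration_s), 1))
  w <- t(vapply(record$gold_events, function(e)
    c(max(0, e$onset_s - tol),
      min(record$duration_s, e$onset_s + e$duration_s + tol)), numeric(2)))
  w <- w[order(w[, 1]), , drop = FALSE]
  out <- NULL; cur <- 0
  for (i in seq_len(nrow(w))) {
    if (w[i, 1] > cur) out <- rbind(out, c(cur, w[i, 1]))
    cur <- max(cur, w[i, 2])
  }
  if (cur < record$duration_s) out <- rbind(out, c(cur, record$duration_s))
  if (is.null(out)) matrix(numeric(0), 0, 2) else out
}

intersect_intervals <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) out <- rbind(out, c(lo, hi))
  }
  if (is.null(out)) matrix(numeric(0), 0, 2) else out
}

sample_in_intervals <- function(iv) {
  len <- iv[, 2] - iv[, 1]
  k <- sample.int(nrow(iv), 1, prob = len)
  stats::runif(1, iv[k, 1], iv[k, 2])
}

matches_any_event <- function(time_s, events, tol) {
  for (e in events)
    if (time_s >= e$onset_s - tol && time_s <= e$onset_s + e$duration_s + tol)
      return(TRUE)
  FALSE
}

#' Simulate weak annotations over a corpus
#'
#' Each gold event is annotated independently with probability
#' `target_recall`; the marker lands at onset plus Gaussian jitter, or (with
#' probability `p_late_annotation`) uniformly inside the event. False
#' annotations are then added on seizure-free stretches -- preferentially
#' inside artifact intervals when any exist -- in the number required for the
#' expected corpus-level precision to equal `target_precision`. Deterministic
#' given `cfg$seed`.
#'
#' @param records List of `eeg_record`s carrying gold events.
#' @param cfg A [noise_model_config()].
#' @return The records, with `weak_annotations` populated (a data frame with
#'   columns `time_s`, `text`, `source`, `matches_gold`).
#' @export
simulate_weak_annotations <- function(records, cfg = noise_model_config()) {
  if (!is.list(records) || length(records) == 0)
    abort_invalid("`records` must be a non-empty list of eeg_record objects")
  stopifnot(inherits(cfg, "noise_model_config"))
  tol <- cfg$matching_tol_s
  with_seed(cfg$seed, {
    ann <- vector("list", length(records))
    for (i in seq_along(records)) {
      r <- records[[i]]
      times <- numeric(0)
      for (e in r$gold_events) {
        if (stats::runif(1) >= cfg$target_recall) next
        t0 <- if (stats::runif(1) < cfg$p_late_annotation)
          stats::runif(1, e$onset_s, e$onset_s + e$duration_s)
        else e$onset_s + stats::rnorm(1, sd = cfg$onset_jitter_sd_s)
        times <- c(times, min(max(t0, 0), r$duration_s))
      }
      ann[[i]] <- times
    }
    # honest matched count, then calibrate the false-annotation budget so
    # expected precision = target
    n_matched <- sum(vapply(seq_along(records), function(i)
      sum(vapply(ann[[i]], matches_any_event, logical(1),
                 events = records[[i]]$gold_events, tol = tol)), numeric(1)))
    total_events <- sum(vapply(records, function(r) length(r$gold_events), numeric(1)))
    n_false <- if (n_matched > 0) {
      round(n_matched * (1 - cfg$target_precision) / cfg$target_precision)
    } else if (total_events == 0) {
      # no seizures anywhere: a background false-marker rate of 1 per 500 s
      max(1L, round(sum(vapply(records, `[[`, numeric(1), "duration_s")) / 500))
    } else 0L
    # candidate placement intervals per record
    free <- lapply(records, free_intervals, tol = tol)
    art <- lapply(seq_along(records), function(i) {
      r <- records[[i]]
      if (length(r$artifacts) == 0) return(matrix(numeric(0), 0, 2))
      aiv <- t(vapply(r$artifacts, function(a)
        c(a$onset_s, a$onset_s + a$duration_s), numeric(2)))
      intersect_intervals(aiv, free[[i]])
    })
    free_len <- vapply(free, function(m) sum(m[, 2] - m[, 1]), numeric(1))
    art_len <- vapply(art, function(m)
      if (nrow(m)) sum(m[, 2] - m[, 1]) else 0, numeric(1))
    false_by_rec <- integer(length(records))
    for (k in seq_len(n_false)) {
      in_art <- sum(art_len) > 0 && stats::runif(1) < 0.5
      lens <- if (in_art) art_len else free_len
      if (sum(lens) == 0) next
      i <- sample.int(length(records), 1, prob = lens)
      iv <- if (in_art) art[[i]] else free[[i]]
      ann[[i]] <- c(ann[[i]], sample_in_intervals(iv))
      false_by_rec[i] <- false_by_rec[i] + 1L
    }
    for (i in seq_along(records)) {
      times <- ann[[i]]
      if (length(times) == 0) { records[[i]]$weak_annotations <- empty_annotations(); next }
      df <- data.frame(
        time_s = times,
        text = sample(annotation_texts, length(times), replace = TRUE),
        source = sample(annotation_sources, length(times), replace = TRUE,
                        prob = c(0.7, 0.2, 0.1)),
        matches_gold = vapply(times, matches_any_event, logical(1),
                              events = records[[i]]$gold_events, tol = tol),
        stringsAsFactors = FALSE)
      records[[i]]$weak_annotations <- df[order(df$time_s), , drop = FALSE]
      rownames(records[[i]]$weak_annotations) <- NULL
    }
    records
  })
}

#' Measure realized annotation quality
#'
#' Recomputes corpus-level precision (fraction of annotations within the
#' matching tolerance of some gold event) and recall (fraction of gold events
#' with at least one matching annotation) from the records themselves.
#'
#' @param records Annotated records.
#' @param matching_tol_s Matching tolerance in seconds (default 30).
#' @return List with `precision`, `recall`, and the underlying counts.
#' @export
annotation_quality <- function(records, matching_tol_s = 30) {
  n_ann <- 0L; n_match <- 0L; n_ev <- 0L; n_ev_hit <- 0L
  for (r in records) {
    times <- r$weak_annotations$time_s
    n_ann <- n_ann + length(times)
    n_match <- n_match + sum(vapply(times, matches_any_event, logical(1),
                                    events = r$gold_events, tol = matching_tol_s))
    for (e in r$gold_events) {
      n_ev <- n_ev + 1L
      hit <- any(times >= e$onset_s - matching_tol_s &
                 times <= e$onset_s + e$duration_s + matching_tol_s)
      n_ev_hit <- n_ev_hit + as.integer(hit)
    }
  }
  list(precision = if (n_ann > 0) n_match / n_ann else NA_real_,
       recall = if (n_ev > 0) n_ev_hit / n_ev else NA_real_,
       n_annotations = n_ann, n_matched = n_match,
       n_events = n_ev, n_events_matched = n_ev_hit)
}
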