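# Clip dataset construction: fixed-length labeled windows cut from annotated
# records, class-balanced weak training sets, and gold-labeled dev/test sets
# at the clinical 80-20 negative-positive balance.

#' Construct a labeled EEG clip
#'
#' A fixed-duration window: `clip_len_s * fs` samples over the 19-channel
#' montage (2400 x 19 for 12-s clips, 12000 x 19 for 60-s clips at 200 Hz).
#'
#' @param record_id Source record identifier.
#' @param start_s Window start in seconds from record start; the clip covers
#'   the half-open interval `[start_s, start_s + clip_len_s)`.
#' @param clip_len_s Clip length in seconds.
#' @param x Samples-by-channels signal matrix.
#' @param label 0 (no seizure onset) or 1 (seizure onset).
#' @param label_source `"weak"`, `"gold"`, or `"sampled_negative"`.
#' @param fs Sampling rate (default 200).
#' @return An object of class `eeg_clip`.
#' @export
eeg_clip <- function(record_id, start_s, clip_len_s, x, label,
                     label_source = c("weak", "gold", "sampled_negative"),
                     fs = 200) {
  label_source <- match.arg(label_source)
  n <- round(clip_len_s * fs)
  if (nrow(x) != n || ncol(x) != 19L)
    abort_invalid(sprintf("clip matrix must be %d x 19, got %d x %d",
                          n, nrow(x), ncol(x)))
  if (!label %in% c(0, 1)) abort_invalid("label must be 0 or 1")
  structure(list(record_id = record_id, start_s = start_s,
                 clip_len_s = clip_len_s, x = x, label = as.integer(label),
                 label_source = label_source, fs = fs),
            class = "eeg_clip")
}

#' Clip dataset specification
#'
#' @param clip_len_s Clip length: 12 (fast detection) or 60 (slow detection).
#' @param train_pos_fraction Positive fraction of the balanced training set
#'   (default 0.5; negatives are undersampled to reach it).
#' @param test_neg_pos Negative-positive balance of the gold evaluation pool
#'   (default `c(0.8, 0.2)`, reflecting the relative rarity of seizures).
#' @param negative_sampling_seed Seed for all negative sampling and shuffling.
#' @param dev_test_split_fraction Fraction of the eval pool assigned to the
#'   development set (records are never shared between dev and test).
#' @return An object of class `clip_dataset_spec`.
#' @export
clip_dataset_spec <- function(clip_len_s = 12, train_pos_fraction = 0.5,
                              test_neg_pos = c(0.8, 0.2),
                              negative_sampling_seed = 1,
                              dev_test_split_fraction = 0.5) {
  if (!clip_len_s %in% c(12, 60))
    abort_invalid("clip_len_s must be 12 or 60")
  if (train_pos_fraction <= 0 || train_pos_fraction >= 1)
    abort_invalid("train_pos_fraction must be in (0, 1)")
  if (length(test_neg_pos) != 2 || abs(sum(test_neg_pos) - 1) > 1e-9)
    abort_invalid("test_neg_pos must be two fractions summing to 1")
  if (dev_test_split_fraction <= 0 || dev_test_split_fraction >= 1)
    abort_invalid("dev_test_split_fraction must be in (0, 1)")
  structure(list(clip_len_s = clip_len_s,
                 train_pos_fraction = train_pos_fraction,
                 test_neg_pos = test_neg_pos,
                 negative_sampling_seed = negative_sampling_seed,
                 dev_test_split_fraction = dev_test_split_fraction),
            class = "clip_dataset_spec")
}

new_clip_dataset <- function(clips, info = list()) {
  structure(list(clips = clips, info = info), class = "clip_dataset")
}

#' @method print clip_dataset
#' @export
print.clip_dataset <- function(x, ...) {
  lab <- clip_labels(x)
  cat(sprintf("<clip_dataset: %d clips, %d positive (%.1f%%)>\n",
              length(lab), sum(lab), 100 * mean(lab)))
  invisible(x)
}

as_clip_list <- function(x) {
  if (inherits(x, "clip_dataset")) x$clips
  else if (is.list(x)) x
  else abort_invalid("expected a clip_dataset or list of clips")
}

#' Labels of a clip collection
#' @param clips A `clip_dataset` or list of clips.
#' @return Integer vector of 0/1 labels.
#' @export
clip_labels <- function(clips) {
  vapply(as_clip_list(clips), `[[`, integer(1), "label")
}

#' Extract positive clips at annotation times
#'
#' One clip per annotation (weak) or per gold event onset (gold), anchored at
#' the annotation time so the clip covers `[t, t + clip_len_s)`; markers too
#' close to the record end to fit a full clip are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param records List of `eeg_record`s (lazy records are realized on the fly).
#' @param clip_len_s Clip length in seconds.
#' @param label_source `"weak"` (annotation times) or `"gold"` (event onsets).
#' @return List of positive `eeg_clip`s with attribute `n_skipped`.
#' @export
extract_positive_clips <- function(records, clip_len_s = 12,
                                   label_source = c("weak", "gold")) {
  label_source <- match.arg(label_source)
  clips <- list(); skipped <- 0L
  for (r in records) {
    times <- if (label_source == "weak") r$weak_annotations$time_s
             else vapply(r$gold_events, `[[`, numeric(1), "onset_s")
    if (length(times) == 0) next
    n_clip <- round(clip_len_s * r$fs)
    n_total <- round(r$duration_s * r$fs)
    i0 <- floor(times * r$fs) + 1L
    ok <- i0 >= 1L & (i0 + n_clip - 1L) <= n_total
    skipped <- skipped + sum(!ok)
    if (!any(ok)) next
    r <- realize_record(r)
    for (k in which(ok)) {
      idx <- seq.int(i0[k], i0[k] + n_clip - 1L)
      clips[[length(clips) + 1L]] <- eeg_clip(
        r$record_id, times[k], clip_len_s, r$data[idx, , drop = FALSE],
        label = 1L, label_source = label_source, fs = r$fs)
    }
  }
  attr(clips, "n_skipped") <- skipped
  clips
}

# Shared negative sampler over an explicit record pool.
sample_negatives_from <- function(pool, n, clip_len_s, seed) {
  if (length(pool) == 0)
    abort_invalid("no eligible records to sample negatives from",
                  class = "weakeeg_unsatisfiable_sampling")
  elig_dur <- vapply(pool, function(r) r$duration_s - clip_len_s, numeric(1))
  pool <- pool[elig_dur > 0]; elig_dur <- elig_dur[elig_dur > 0]
  if (length(pool) == 0)
    abort_invalid("eligible records are shorter than one clip",
                  class = "weakeeg_unsatisfiable_sampling")
  with_seed(seed, {
    ridx <- sample.int(length(pool), n, replace = TRUE, prob = elig_dur)
    starts <- stats::runif(n, 0, elig_dur[ridx])
    clips <- vector("list", n)
    for (i in unique(ridx)) {
      r <- realize_record(pool[[i]])
      n_clip <- round(clip_len_s * r$fs)
      for (k in which(ridx == i)) {
        i0 <- floor(starts[k] * r$fs) + 1L
        i0 <- min(i0, nrow(r$data) - n_clip + 1L)
        clips[[k]] <- eeg_clip(r$record_id, (i0 - 1L) / r$fs, clip_len_s,
                               r$data[seq.int(i0, i0 + n_clip - 1L), , drop = FALSE],
                               label = 0L, label_source = "sampled_negative",
                               fs = r$fs)
      }
    }
    clips
  })
}

#' Sample negative clips from annotation-free records
#'
#' Negatives for training are random windows drawn only from records that
#' carry no weak annotations at all (records are chosen with probability
#' proportional to their eligible duration). Deterministic given `seed`.
#'
#' @param records Corpus records.
#' @param n Number of clips.
#' @param clip_len_s Clip length in seconds.
#' @param seed Sampling seed.
#' @return List of `n` negative `eeg_clip`s.
#' @export
sample_negative_clips <- function(records, n, clip_len_s = 12, seed = 1) {
  pool <- Filter(function(r) nrow(r$weak_annotations) == 0, records)
  if (length(pool) == 0)
    abort_invalid("every record carries weak annotations; negative sampling unsatisfiable",
                  class = "weakeeg_unsatisfiable_sampling")
  sample_negatives_from(pool, n, clip_len_s, seed)
}

#' Build the balanced weak training set
#'
#' All weak-positive clips are retained and negatives are undersampled from
#' annotation-free records so the positive fraction equals
#' `spec$train_pos_fraction` (ties resolve toward one extra negative). The
#' returned clips are shuffled with a recorded seed.
#'
#' @param records Corpus records carrying weak annotations.
#' @param spec A [clip_dataset_spec()].
#' @return A `clip_dataset`; `$info` records counts and seeds.
#' @export
build_training_set <- function(records, spec = clip_dataset_spec()) {
  pos <- extract_positive_clips(records, spec$clip_len_s, "weak")
  n_pos <- length(pos)
  if (n_pos == 0)
    abort_invalid("no weak-positive clips available",
                  class = "weakeeg_empty_class")
  f <- spec$train_pos_fraction
  n_neg <- floor(n_pos * (1 - f) / f + 0.5)
  neg <- sample_negative_clips(records, n_neg, spec$clip_len_s,
                               seed = spec$negative_sampling_seed)
  clips <- c(pos, neg)
  shuffle_seed <- derive_seed(spec$negative_sampling_seed, "shuffle")
  ord <- with_seed(shuffle_seed, sample.int(length(clips)))
  new_clip_dataset(clips[ord],
                   info = list(n_pos = n_pos, n_neg = n_neg,
                               n_skipped = attr(pos, "n_skipped"),
                               shuffle_seed = shuffle_seed))
}

# Greedy record-disjoint halving balanced on clip counts.
split_records_by_count <- function(ids, counts, frac) {
  o <- order(counts, decreasing = TRUE)
  take_a <- logical(length(ids)); a <- 0; b <- 0
  for (i in o) {
    if (a / max(1e-9, frac) <= b / max(1e-9, 1 - frac)) {
      take_a[i] <- TRUE; a <- a + counts[i]
    } else b <- b + counts[i]
  }
  take_a
}

#' Build gold-labeled development and test sets
#'
#' Gold-positive clips (anchored at event onsets) plus negatives sampled from
#' seizure-free records at the `test_neg_pos` balance, split into two halves
#' with no record shared between the development and test sets.
#'
#' @param records Corpus records carrying gold events.
#' @param spec A [clip_dataset_spec()].
#' @return List with `dev` and `test` `clip_dataset`s.
#' @export
build_eval_sets <- function(records, spec = clip_dataset_spec()) {
  pos <- extract_positive_clips(records, spec$clip_len_s, "gold")
  pos_ids <- unique(vapply(pos, `[[`, character(1), "record_id"))
  if (length(pos_ids) < 2)
    abort_invalid("need gold-positive clips from at least 2 records to split",
                  class = "weakeeg_split_infeasible")
  n_pos <- length(pos)
  ratio <- spec$test_neg_pos[1] / spec$test_neg_pos[2]
  n_neg <- round(n_pos * ratio)
  neg_pool <- Filter(function(r) length(r$gold_events) == 0, records)
  neg <- sample_negatives_from(neg_pool, n_neg, spec$clip_len_s,
                               seed = derive_seed(spec$negative_sampling_seed, "evalneg"))
  split_half <- function(clips) {
    ids <- vapply(clips, `[[`, character(1), "record_id")
    uid <- unique(ids)
    cnt <- vapply(uid, function(u) sum(ids == u), numeric(1))
    in_dev_rec <- uid[split_records_by_count(uid, cnt, spec$dev_test_split_fraction)]
    list(dev = clips[ids %in% in_dev_rec], test = clips[!(ids %in% in_dev_rec)])
  }
  sp <- split_half(pos); sn <- split_half(neg)
  list(dev = new_clip_dataset(c(sp$dev, sn$dev),
                              info = list(n_pos = length(sp$dev), n_neg = length(sn$dev))),
       test = new_clip_dataset(c(sp$test, sn$test),
                               info = list(n_pos = length(sp$test), n_neg = length(sn$test))))
}
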