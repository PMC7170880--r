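# Occlusion-sensitivity analysis: channel-by-second saliency maps obtained
# by zeroing one-second segments and measuring the percent change in the
# model's prediction, plus sliding full-record prediction traces.

#' Occlusion sensitivity map for a clip
#'
#' For every (channel, second) cell, the corresponding one-second segment of
#' that channel is replaced with zeros and the model re-evaluated; the map
#' holds the signed percent change `(p - p_occluded) / p * 100` relative to
#' the unoccluded prediction (positive cells support the seizure call,
#' negative cells suppress it). With `normalize = TRUE` the map is divided
#' by its maximum absolute value (per-image normalization for display).
#'
#' @param model A `dense_inception` model, or any function mapping a list of
#'   clip matrices to probabilities (useful for analytic reference models).
#' @param clip An `eeg_clip` (or matrix) matching the model input shape.
#' @param window_s Occlusion window in seconds (default 1; must divide the
#'   clip length).
#' @param normalize Normalize to max |value| = 1?
#' @param batch_size Forward batch size for the occluded variants.
#' @param fs Sampling rate when `model` is a plain function (default 200).
#' @return Object of class `occlusion_map`: list with `values`
#'   (channels x seconds), `baseline_prob`, `normalized`, `degenerate`
#'   (TRUE when the unoccluded prediction was exactly 0 and raw differences
#'   are returned instead of percent change).
#' @export
occlusion_map <- function(model, clip, window_s = 1, normalize = FALSE,
                          batch_size = 64L, fs = 200) {
  x <- if (inherits(clip, "eeg_clip")) clip$x else clip
  if (inherits(model, "dense_inception")) {
    cfg <- model$config
    fs <- cfg$fs
    if (nrow(x) != round(cfg$clip_len_s * cfg$fs) || ncol(x) != cfg$n_channels)
      abort_invalid("clip does not match the model input shape",
                    class = "weakeeg_invalid_input")
  }
  scorer <- if (is.function(model)) model
            else function(clips) predict_proba(model, clips, batch_size = batch_size)
  clip_len_s <- nrow(x) / fs
  if (round(clip_len_s) %% window_s != 0)
    abort_invalid("window_s must divide the clip length")
  n_win <- round(clip_len_s / window_s)
  n_ch <- ncol(x)
  wlen <- round(window_s * fs)
  p0 <- scorer(list(x))
  occluded <- vector("list", n_ch * n_win)
  k <- 0L
  for (ch in seq_len(n_ch)) for (w in seq_len(n_win)) {
    k <- k + 1L
    xo <- x
    xo[(w - 1L) * wlen + seq_len(wlen), ch] <- 0
    occluded[[k]] <- xo
  }
  po <- scorer(occluded)
  degenerate <- p0 == 0
  vals <- if (degenerate) (p0 - po) else (p0 - po) / p0 * 100
  values <- matrix(vals, nrow = n_ch, ncol = n_win, byrow = TRUE,
                   dimnames = list(colnames(x), NULL))
  if (normalize && any(values != 0)) values <- values / max(abs(values))
  structure(list(values = values, baseline_prob = p0,
                 window_s = window_s, normalized = normalize,
                 degenerate = degenerate,
                 record_id = if (inherits(clip, "eeg_clip")) clip$record_id else NA,
                 start_s = if (inherits(clip, "eeg_clip")) clip$start_s else NA),
            class = "occlusion_map")
}

#' Sliding-window prediction trace over a record
#'
#' Evaluates the model on windows starting at 0, `stride_s`, `2*stride_s`,
#' ... while a full clip fits; each probability is timestamped at its window
#' start.
#'
#' @param model A `dense_inception` model or scoring function.
#' @param record An `eeg_record` (realized on the fly if lazy).
#' @param stride_s Stride in seconds (default 1).
#' @param batch_size Forward batch size.
#' @param clip_len_s Window length when `model` is a plain function.
#' @return Object of class `prediction_trace`: `times_s`, `probabilities`,
#'   `stride_s`, `clip_len_s`.
#' @export
sliding_predictions <- function(model, record, stride_s = 1, batch_size = 64L,
                                clip_len_s = 12) {
  stopifnot(inherits(record, "eeg_record"))
  if (inherits(model, "dense_inception")) clip_len_s <- model$config$clip_len_s
  scorer <- if (is.function(model)) model
            else function(clips) predict_proba(model, clips, batch_size = batch_size)
  cfg <- list(clip_len_s = clip_len_s)
  if (record$duration_s < cfg$clip_len_s)
    abort_invalid("record shorter than one clip",
                  class = "weakeeg_invalid_input")
  record <- realize_record(record)
  starts <- seq(0, record$duration_s - cfg$clip_len_s, by = stride_s)
  n_clip <- round(cfg$clip_len_s * record$fs)
  wins <- lapply(starts, function(s) {
    i0 <- floor(s * record$fs) + 1L
    record$data[seq.int(i0, i0 + n_clip - 1L), , drop = FALSE]
  })
  probs <- scorer(wins)
  structure(list(times_s = starts, probabilities = probs,
                 stride_s = stride_s, clip_len_s = cfg$clip_len_s,
                 record_id = record$record_id),
            class = "prediction_trace")
}

#' Localization score of an occlusion map against a gold event
#'
#' Quantifies whether the map's strongest cells lie on the event: with k =
#' the number of (focus-channel, second) cells the event covers within the
#' clip, the score is the fraction of the k top-valued map cells falling
#' inside that support. 1 = perfect localization; a ties-randomized uniform
#' map scores the support fraction in expectation.
#'
#' @param map An [occlusion_map()].
#' @param gold_event The `seizure_event`, with `onset_s` relative to the
#'   record (the map's `start_s` is used to convert to clip time).
#' @param focus_channels Channels counted as event support (defaults to the
#'   event's focus set).
#' @param clip_start_s Clip start override when the map lacks provenance.
#' @param tie_seed Seed for random tie-breaking among equal cells.
#' @return Overlap fraction in `[0, 1]`.
#' @export
localization_score <- function(map, gold_event, focus_channels = NULL,
                               clip_start_s = NULL, tie_seed = 1) {
  stopifnot(inherits(map, "occlusion_map"))
  start_s <- if (!is.null(clip_start_s)) clip_start_s else map$start_s
  if (is.na(start_s)) abort_invalid("clip start time unknown; pass clip_start_s")
  if (is.null(focus_channels)) focus_channels <- gold_event$focus_channels
  n_sec <- ncol(map$values)
  ch <- rownames(map$values)
  # event support in clip-relative (channel, second) cells
  ev0 <- gold_event$onset_s - start_s
  ev1 <- ev0 + gold_event$duration_s
  secs <- which(seq_len(n_sec) - 1 < ev1 & seq_len(n_sec) > ev0)
  if (length(secs) == 0)
    abort_invalid("event does not intersect the clip",
                  class = "weakeeg_undefined_score")
  support <- matrix(FALSE, nrow(map$values), n_sec)
  support[match(focus_channels, ch), secs] <- TRUE
  k <- sum(support)
  # top-k cells by value, ties broken by a seeded random permutation
  v <- as.vector(map$values)
  ord <- with_seed(tie_seed, order(v, stats::runif(length(v)), decreasing = TRUE))
  mean(as.vector(support)[ord[seq_len(k)]])
}
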