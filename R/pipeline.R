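# End-to-end reproducible runs: a single declarative configuration drives
# simulate -> build-clips -> train (weak) + train (gold-small) -> evaluate ->
# occlude, with one global seed fanned out to per-stage seeds and a manifest
# recording seeds, counts, metrics, and file hashes.

#' Default pipeline configuration
#'
#' @param scenario A [corpus_scenario()].
#' @param noise A [noise_model_config()].
#' @param dataset A [clip_dataset_spec()].
#' @param model_config A [dense_inception_config()].
#' @param train_cfg A [train_config()].
#' @param eval_frac Fraction of records held out for the gold-labeled
#'   dev/test sets (record-disjoint from training).
#' @param threshold Decision threshold for confusion metrics.
#' @param seed Global seed; every stage derives its own stream from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = corpus_scenario(),
                            noise = noise_model_config(),
                            dataset = clip_dataset_spec(),
                            model_config = dense_inception_config("desk"),
                            train_cfg = train_config("desk"),
                            eval_frac = 0.35, threshold = 0.5, seed = 1) {
  structure(list(scenario = scenario, noise = noise, dataset = dataset,
                 model_config = model_config, train_cfg = train_cfg,
                 eval_frac = eval_frac, threshold = threshold, seed = seed),
            class = "pipeline_config")
}

#' Validate and normalize a pipeline configuration
#'
#' Fills every missing component with its default and reports each violation
#' with a path into the configuration. Errors are returned, not raised.
#'
#' @param config A (possibly partial) list of pipeline settings.
#' @return List with `config` (normalized `pipeline_config`) and `errors`
#'   (character vector; empty when valid).
#' @export
validate_config <- function(config = list()) {
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)
  defaults <- pipeline_config()
  cfg <- utils::modifyList(unclass(defaults), config, keep.null = TRUE)
  class(cfg) <- "pipeline_config"
  ds <- cfg$dataset
  if (!ds$clip_len_s %in% c(12, 60))
    note("dataset$clip_len_s: only 12-s and 60-s clips are supported")
  if (ds$train_pos_fraction <= 0 || ds$train_pos_fraction >= 1)
    note("dataset$train_pos_fraction: must be in (0, 1)")
  nz <- cfg$noise
  if (nz$target_precision <= 0 || nz$target_precision > 1)
    note("noise$target_precision: must be in (0, 1]")
  if (nz$target_recall <= 0 || nz$target_recall > 1)
    note("noise$target_recall: must be in (0, 1]")
  if (cfg$eval_frac <= 0 || cfg$eval_frac >= 1)
    note("eval_frac: must be in (0, 1)")
  if (cfg$train_cfg$lr0 <= 0) note("train_cfg$lr0: must be > 0")
  if (cfg$scenario$n_records < 3)
    note("scenario$n_records: need at least 3 records")
  if (cfg$model_config$clip_len_s != ds$clip_len_s)
    note("model_config$clip_len_s: must match dataset$clip_len_s")
  list(config = cfg, errors = errors)
}

stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    stop(structure(class = c("weakeeg_stage_error", "error", "condition"),
                   list(message = sprintf("pipeline stage '%s' failed: %s",
                                          name, conditionMessage(e)),
                        stage = name, parent = e, call = NULL)))
  })
}

#' Run the full pipeline
#'
#' Simulates a corpus, splits records into a weakly annotated training pool
#' and a gold-labeled evaluation pool (record-disjoint), builds the balanced
#' weak training set and the 80-20 dev/test sets, trains the CNN on weak
#' labels and the same architecture on the small gold dev set, evaluates
#' both on the held-out test set, and computes an occlusion map for the
#' highest-scoring true-positive test clip. All artifacts and a JSON
#' manifest are written under `out_dir`.
#'
#' @param config A [pipeline_config()] (or partial list; it is validated).
#' @param out_dir Output directory.
#' @return List with `metrics` (weak and gold-small test reports), `manifest`,
#'   and the trained `models`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("weakeeg_run")) {
  vc <- validate_config(if (inherits(config, "pipeline_config")) unclass(config) else config)
  if (length(vc$errors) > 0)
    abort_invalid(paste("invalid pipeline config:",
                        paste(vc$errors, collapse = "; ")))
  cfg <- vc$config
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- cfg$seed

  records <- stage("simulate", {
    recs <- simulate_corpus(cfg$scenario, derive_seed(seed, "simulate"))
    simulate_weak_annotations(recs, utils::modifyList(
      cfg$noise, list(seed = derive_seed(seed, "annotate"))))
  })
  n_eval <- max(2L, round(cfg$eval_frac * length(records)))
  eval_records <- records[seq_len(n_eval)]
  train_records <- records[-seq_len(n_eval)]

  sets <- stage("build-clips", {
    ds <- cfg$dataset
    ds$negative_sampling_seed <- derive_seed(seed, "negatives")
    train_set <- build_training_set(train_records, ds)
    ev <- build_eval_sets(eval_records, ds)
    list(train = train_set, dev = ev$dev, test = ev$test)
  })

  fit_weak <- stage("train-weak", {
    tc <- cfg$train_cfg; tc$seed <- derive_seed(seed, "train-weak")
    model <- build_model(cfg$model_config, seed = derive_seed(seed, "init-weak"))
    train(model, sets$train, sets$dev, tc)
  })
  fit_gold <- stage("train-gold-small", {
    tc <- cfg$train_cfg; tc$seed <- derive_seed(seed, "train-gold")
    model <- build_model(cfg$model_config, seed = derive_seed(seed, "init-gold"))
    train(model, sets$dev, sets$dev, tc)
  })

  metrics <- stage("evaluate", {
    y <- clip_labels(sets$test)
    list(weak = metrics_report(y, predict_proba(fit_weak$model, sets$test),
                               cfg$threshold),
         gold_small = metrics_report(y, predict_proba(fit_gold$model, sets$test),
                                     cfg$threshold))
  })

  occ <- stage("occlude", {
    y <- clip_labels(sets$test)
    p <- predict_proba(fit_weak$model, sets$test)
    tp <- which(y == 1 & p >= cfg$threshold)
    if (length(tp) == 0) NULL
    else occlusion_map(fit_weak$model, sets$test$clips[[tp[which.max(p[tp])]]],
                       normalize = TRUE)
  })

  # serialize artifacts
  idx <- data.frame(
    split = c(rep("train", length(sets$train$clips)),
              rep("dev", length(sets$dev$clips)),
              rep("test", length(sets$test$clips))),
    record_id = vapply(c(sets$train$clips, sets$dev$clips, sets$test$clips),
                       `[[`, character(1), "record_id"),
    start_s = vapply(c(sets$train$clips, sets$dev$clips, sets$test$clips),
                     `[[`, numeric(1), "start_s"),
    label = c(clip_labels(sets$train), clip_labels(sets$dev), clip_labels(sets$test)),
    label_source = vapply(c(sets$train$clips, sets$dev$clips, sets$test$clips),
                          `[[`, character(1), "label_source"))
  utils::write.csv(idx, file.path(out_dir, "clip_index.csv"), row.names = FALSE)
  utils::write.csv(fit_weak$history, file.path(out_dir, "history_weak.csv"),
                   row.names = FALSE)
  saveRDS(fit_weak$model, file.path(out_dir, "model_weak.rds"), compress = FALSE)
  if (!is.null(occ)) saveRDS(occ, file.path(out_dir, "occlusion_tp.rds"),
                             compress = FALSE)
  manifest <- list(
    seed = seed,
    stage_seeds = list(simulate = derive_seed(seed, "simulate"),
                       annotate = derive_seed(seed, "annotate"),
                       negatives = derive_seed(seed, "negatives"),
                       train_weak = derive_seed(seed, "train-weak")),
    n_records = length(records), n_eval_records = n_eval,
    train_clips = length(sets$train$clips),
    train_pos = sets$train$info$n_pos,
    dev_clips = length(sets$dev$clips), test_clips = length(sets$test$clips),
    annotation_quality = annotation_quality(records, cfg$noise$matching_tol_s)[
      c("precision", "recall", "n_events", "n_annotations")],
    test_metrics = list(
      weak = metrics$weak[c("auroc", "f1", "precision", "recall", "fpr")],
      gold_small = metrics$gold_small[c("auroc", "f1", "precision", "recall", "fpr")]),
    hashes = as.list(tools::md5sum(file.path(out_dir,
      c("clip_index.csv", "history_weak.csv")))))
  names(manifest$hashes) <- c("clip_index.csv", "history_weak.csv")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(list(metrics = metrics, manifest = manifest,
                 models = list(weak = fit_weak$model, gold_small = fit_gold$model),
                 sets = sets, occlusion = occ, out_dir = out_dir))
}
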