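# weakeeg

Weakly supervised seizure onset detection from scalp EEG, as a reproducible
desk-scale pipeline.

Hospital EEG monitoring produces archived freeform seizure markers from
technicians, fellows, and students — *weak annotations* with audited
precision around 0.37 and recall around 0.45, biased toward seizure onset.
`weakeeg` implements the complete stack for studying whether such noisy,
plentiful labels can train a clip-level seizure-onset detector, using a
seeded synthetic EEG world in place of the PHI-restricted clinical corpora:

* **Simulator** — 19-channel 10–20 montage records at 200 Hz: 1/f background
  with a posterior alpha rhythm, three ictal morphologies (generalized
  spike-wave, evolving focal fast-spiking, rhythmic ictal delta), 60 Hz line
  noise and non-evolving rhythmic artifact, and a calibrated weak-annotation
  noise model (`simulate_corpus()`, `simulate_weak_annotations()`).
* **Clip datasets** — 12-s (2400×19) and 60-s (12000×19) clips; balanced
  weak training sets, gold-labeled dev/test sets at 80–20
  negative–positive balance, record-disjoint splits; Kaiser-windowed
  polyphase resampling to 200 Hz (`build_training_set()`,
  `build_eval_sets()`, `resample_to_200hz()`).
* **Baselines** — the classical feature battery (time-domain moments, DFT
  band fractions, Daubechies-4 wavelet energies, lagged cross-correlation,
  electrode-graph measures) with a 100-tree depth-4 random forest and ridge
  logistic regression (`clip_features()`, `fit_baseline()`).
* **Dense-inception CNN** — multi-kernel inception blocks with dense
  connectivity, implemented with its own backward pass and Adam in base R;
  the full-scale preset reproduces the published 12,677,803-parameter
  architecture exactly, and a ~8k-parameter desk preset trains in seconds
  per epoch on one CPU (`dense_inception_config()`, `build_model()`,
  `train()`).
* **Experiments** — weak-vs-gold supervision, training-set-size scaling with
  seed confidence intervals, and transfer by fine-tuning the last two fully
  connected layers with frozen convolutions (`scaling_experiment()`,
  `transfer_finetune()`).
* **Evaluation and saliency** — precision/recall/F1/FPR, ROC/AUROC with
  operating-point selection, seed aggregation, and occlusion sensitivity
  maps over (channel × second) cells plus sliding full-record prediction
  traces (`metrics_report()`, `occlusion_map()`, `sliding_predictions()`).

## Worked example

```r
library(weakeeg)

# a corpus with known seizure ground truth and noisy annotations
scenario <- corpus_scenario(n_records = 120, duration_s = 120)
records  <- simulate_corpus(scenario, seed = 101)
records  <- simulate_weak_annotations(records, noise_model_config(seed = 7))
annotation_quality(records)[c("precision", "recall")]
#> $precision
#> [1] 0.3684211
#> $recall
#> [1] 0.4086022
```

Measured against gold events with the 30-s matching tolerance, the
simulated markers land on the audited clinical quality: about 37% of
markers are real seizures, and about 45% of seizures get marked.

```r
# record-disjoint train / dev / test, weak labels for training only
spec  <- clip_dataset_spec(negative_sampling_seed = 11)
train <- build_training_set(records[41:120], spec)
evals <- build_eval_sets(records[1:40], spec)
train
#> <clip_dataset: 116 clips, 58 positive (50.0%)>

model <- build_model(dense_inception_config("desk"), seed = 1)
fit   <- train(model, train, evals$dev, train_config("desk", seed = 2))
report <- metrics_report(clip_labels(evals$test),
                         predict_proba(fit$model, evals$test))
round(c(auroc = report$auroc, f1 = report$f1, fpr = report$fpr), 3)
#> auroc    f1   fpr
#> 0.711 0.385 0.458
```

Trained on 116 clips of which 63% of the positives were mislabeled, the
desk CNN still ranks gold-labeled test clips well above chance (AUROC
0.71). F1 and FPR use the default 0.5 threshold; on this small run the
model's scores sit high, so 0.5 admits many false positives, and
`operating_point()` is the tool for choosing a threshold against an
explicit TPR or FPR target. An occlusion map for a detected seizure shows
which channel-seconds drove the call:

```r
tp <- which(clip_labels(evals$test) == 1)[1]
om <- occlusion_map(fit$model, evals$test$clips[[tp]], normalize = TRUE)
dim(om$values)   # 19 channels x 12 seconds, percent change per occluded cell
#> [1] 19 12
```

## Acceptance script

`scripts/acceptance.R` regenerates, from scratch, the calibration corpus
(720 records, ≥1000 gold seizure events, artifacts included), runs the
default weak-annotation noise model, and measures corpus-level precision
and recall against gold with the documented 30-s tolerance:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The JSON output holds one entry per target with the measured value and the
problem size used.
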