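# Optimization protocol for the dense-inception model: Adam with a
# halve-every-10-epochs learning-rate schedule, best-dev-AUROC checkpoint
# selection, the sample-size scaling experiment, and transfer fine-tuning of
# the two fully connected layers.

#' Training configuration
#'
#' The full-scale protocol trains with Adam from random initialization at an
#' initial learning rate of 1e-6, halved every 10 epochs, dropout 0.2 on the
#' last layer, batches of 10 clips, for 25 epochs. That learning rate
#' presumes the 12.7M-parameter model and tens of thousands of clips; the
#' `"desk"` preset keeps the same schedule shape with `lr0 = 1e-3` and 6
#' epochs so CPU-scale runs converge. The checkpoint with the best
#' development-set AUROC is returned.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param lr0 Initial learning rate.
#' @param lr_halving_period Epochs between learning-rate halvings (10).
#' @param epochs Training epochs.
#' @param batch_size Clips per batch (10).
#' @param seed Seed for init order, shuffling, and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(preset = c("desk", "paper"), lr0 = NULL,
                         lr_halving_period = 10L, epochs = NULL,
                         batch_size = 10L, seed = 1) {
  preset <- match.arg(preset)
  if (is.null(lr0)) lr0 <- if (preset == "paper") 1e-6 else 1e-3
  if (is.null(epochs)) epochs <- if (preset == "paper") 25L else 6L
  if (lr0 <= 0) abort_invalid("lr0 must be > 0")
  if (epochs < 0) abort_invalid("epochs must be >= 0")
  structure(list(preset = preset, lr0 = lr0,
                 lr_halving_period = as.integer(lr_halving_period),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = seed),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' `lr(e) = lr0 * 2^(-floor(e / period))` with `e` counted from 0: 1e-6 at
#' epochs 0-9, 5e-7 at 10-19, 2.5e-7 at 20-29 for the full-scale protocol.
#'
#' @param epoch 0-based epoch index.
#' @param cfg A [train_config()].
#' @return Learning rate.
#' @export
lr_schedule <- function(epoch, cfg) {
  cfg$lr0 * 2^(-(epoch %/% cfg$lr_halving_period))
}

bce_loss <- function(logit, y) {
  mean(ifelse(logit > 0, logit + log1p(exp(-logit)), log1p(exp(logit))) - y * logit)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(model$params)) {
    if (!model$trainable[[nm]]) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    model$params[[nm]] <- model$params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(model = model, state = state)
}

#' Train a dense-inception model
#'
#' Mini-batch Adam on binary cross-entropy over the logistic output, with the
#' halving learning-rate schedule, per-epoch shuffling, dropout, and
#' development-set AUROC tracking. The returned model is the checkpoint with
#' the best dev AUROC (ties: earliest epoch); the full history is attached.
#' Every stochastic element draws from one generator seeded by `cfg$seed`,
#' so identical inputs give identical results.
#'
#' @param model A built `dense_inception` (its trainable flags are honored,
#'   so a frozen model fine-tunes only its FC layers).
#' @param train_clips Training `clip_dataset` or clip list (labeled).
#' @param dev_clips Development set for checkpoint selection (gold-labeled).
#' @param cfg A [train_config()].
#' @return List with `model` (best checkpoint), `history` (data frame:
#'   epoch, lr, train_loss, dev_auroc), `best_epoch`.
#' @export
train <- function(model, train_clips, dev_clips, cfg = train_config()) {
  stopifnot(inherits(model, "dense_inception"), inherits(cfg, "train_config"))
  tr <- as_clip_list(train_clips)
  if (length(tr) == 0) abort_invalid("training set is empty")
  dv <- as_clip_list(dev_clips)
  y_tr <- clip_labels(tr)
  y_dv <- clip_labels(dv)
  n_exp <- round(model$config$clip_len_s * model$config$fs)
  xt <- lapply(tr, function(cl) t(if (inherits(cl, "eeg_clip")) cl$x else cl))
  if (any(vapply(xt, ncol, integer(1)) != n_exp))
    abort_invalid("clip shape does not match the model input shape",
                  class = "weakeeg_invalid_input")
  best <- list(auroc = -Inf, params = model$params, epoch = -1L)
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     train_loss = numeric(0), dev_auroc = numeric(0))
  if (cfg$epochs == 0L)
    return(list(model = model, history = hist, best_epoch = 0L))
  with_seed(derive_seed(cfg$seed, "train"), {
    state <- adam_init(model$params)
    for (e in seq_len(cfg$epochs) - 1L) {
      lr <- lr_schedule(e, cfg)
      ord <- sample.int(length(xt))
      losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + cfg$batch_size - 1L, length(ord))
        idx <- ord[i:j]
        xb <- do.call(cbind, xt[idx])
        fw <- nn_forward(model, xb, length(idx), train = TRUE, keep_cache = TRUE)
        losses <- c(losses, bce_loss(fw$logit, y_tr[idx]))
        grads <- nn_backward(model, fw, y_tr[idx])
        st <- adam_step(model, grads, state, lr)
        model <- st$model; state <- st$state
        i <- j + 1L
      }
      dev_auroc <- if (length(dv) > 0 && length(unique(y_dv)) == 2)
        roc_auroc(y_dv, predict_proba(model, dv))$auroc else NA_real_
      hist <- rbind(hist, data.frame(epoch = e, lr = lr,
                                     train_loss = mean(losses),
                                     dev_auroc = dev_auroc))
      if (!is.na(dev_auroc) && dev_auroc > best$auroc) {
        best$auroc <- dev_auroc; best$params <- model$params; best$epoch <- e
      }
    }
  })
  if (is.finite(best$auroc)) model$params <- best$params
  list(model = model, history = hist,
       best_epoch = if (is.finite(best$auroc)) best$epoch else cfg$epochs - 1L)
}

#' Scaling-with-weak-labels experiment
#'
#' For each training-set size, subsamples the weak-labeled balanced training
#' set (seeded per replicate), trains `n_seeds` models from independent
#' initializations, and evaluates each on the fixed gold-labeled test set.
#' Mirrors the observation that AUROC improves and run-to-run variance
#' shrinks as weakly labeled data are added.
#'
#' @param train_set Weak-labeled balanced `clip_dataset`.
#' @param dev_set,test_set Gold-labeled development and test sets.
#' @param sizes Increasing training-set sizes (each <= training-set size).
#' @param model_config A [dense_inception_config()].
#' @param cfg A [train_config()].
#' @param n_seeds Replicates per size (default 5).
#' @return List with `table` (size, mean/median AUROC, 95% CI bounds, CI
#'   width) and `per_seed` (size x seed matrix of AUROC values).
#' @export
scaling_experiment <- function(train_set, dev_set, test_set, sizes,
                               model_config = dense_inception_config("desk"),
                               cfg = train_config(), n_seeds = 5L) {
  clips <- as_clip_list(train_set)
  if (is.unsorted(sizes)) abort_invalid("sizes must be increasing")
  if (max(sizes) > length(clips))
    abort_invalid("largest size exceeds the available training set")
  y <- clip_labels(clips)
  per_seed <- matrix(NA_real_, length(sizes), n_seeds,
                     dimnames = list(paste0("n", sizes), NULL))
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    for (sd in seq_len(n_seeds)) {
      sub_seed <- derive_seed(cfg$seed, "subsample", si * 1000L + sd)
      # class-stratified subsample keeps the 50-50 balance at every size
      idx <- with_seed(sub_seed, {
        pos <- which(y == 1); neg <- which(y == 0)
        npos <- min(length(pos), round(n / 2))
        c(sample(pos, npos), sample(neg, n - npos))
      })
      run_cfg <- cfg
      run_cfg$seed <- derive_seed(cfg$seed, "scalerun", si * 1000L + sd)
      model <- build_model(model_config, seed = derive_seed(run_cfg$seed, "init"))
      fit <- train(model, clips[idx], dev_set, run_cfg)
      per_seed[si, sd] <- roc_auroc(clip_labels(test_set),
                                    predict_proba(fit$model, test_set))$auroc
    }
  }
  tab <- do.call(rbind, lapply(seq_along(sizes), function(si) {
    ag <- aggregate_over_seeds(per_seed[si, ])
    data.frame(n_train = sizes[si], mean_auroc = ag$mean,
               median_auroc = ag$median, ci_lo = ag$ci[1], ci_hi = ag$ci[2],
               ci_width = diff(ag$ci))
  }))
  list(table = tab, per_seed = per_seed)
}

#' Transfer fine-tuning of the two FC layers
#'
#' Freezes every convolutional parameter of a source-trained model and
#' trains only the last two fully connected layers on the (typically much
#' smaller) target training set.
#'
#' @param pretrained_model Source-trained `dense_inception`.
#' @param target_train,target_dev Target-population clip sets.
#' @param cfg A [train_config()].
#' @return As [train()]; `history` carries a `phase = "finetune"` column, and
#'   convolutional parameters are bit-identical to the input model.
#' @export
transfer_finetune <- function(pretrained_model, target_train, target_dev,
                              cfg = train_config()) {
  tr <- as_clip_list(target_train)
  n_exp <- round(pretrained_model$config$clip_len_s * pretrained_model$config$fs)
  if (length(tr) > 0 && nrow(tr[[1]]$x) != n_exp)
    abort_invalid("target clip shape does not match the pretrained model",
                  class = "weakeeg_invalid_input")
  model <- freeze_all_but_last_two_fc(pretrained_model)
  fit <- train(model, target_train, target_dev, cfg)
  if (nrow(fit$history) > 0) fit$history$phase <- "finetune"
  fit
}
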