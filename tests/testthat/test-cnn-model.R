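# Dense-inception CNN: parameter-count oracle, forward contracts, freezing,
# and gradient correctness.

test_that("parameter counts match independent shape arithmetic", {
  # hand computation for a small config: kernels 3/5/9 (K=17), growth 2,
  # 2 blocks (c_in 19 then 25), pool 3 bins, hidden 5:
  # conv = 17*19*2+6 + 17*25*2+6 = 1508; flat = (19+12)*3 = 93;
  # fc = 93*5 + 5 + 5 + 1 = 476; total = 1984.
  cfg <- tiny_config()
  expect_equal(count_params(cfg), 1984)
  m <- build_model(cfg, seed = 1)
  expect_equal(n_params(m), 1984)
  # the invariant holds across configurations
  for (g in c(3, 7)) for (nb in c(1, 4)) {
    c2 <- dense_inception_config("desk", n_blocks = nb, growth = g)
    expect_equal(n_params(build_model(c2, seed = 2)), count_params(c2))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(dense_inception_config("desk", kernel_sizes = c(3, 5)),
               class = "weakeeg_invalid_config")
  expect_error(dense_inception_config("desk", fc_sizes = c(16, 8, 1)),
               class = "weakeeg_invalid_config")
  expect_error(dense_inception_config("desk", fc_sizes = c(16, 2)),
               class = "weakeeg_invalid_config")
  expect_error(dense_inception_config("desk", dropout_p = 1),
               class = "weakeeg_invalid_config")
  expect_error(dense_inception_config("desk", front_pool = 7),
               class = "weakeeg_invalid_config")
})

test_that("forward passes respect the probability and batching contracts", {
  m <- build_model(dense_inception_config("desk"), seed = 3)
  zero <- matrix(0, 2400, 19)
  p <- predict_proba(m, zero)
  expect_true(p > 0 && p < 1)
  clips <- toy_clips(7, seed = 2)
  probs <- predict_proba(m, clips)
  expect_length(probs, 7)
  expect_true(all(probs > 0 & probs < 1))
  # permuting batch order permutes outputs identically
  perm <- c(3, 1, 7, 2, 6, 5, 4)
  expect_identical(predict_proba(m, clips[perm]), probs[perm])
  # evaluation mode is deterministic
  expect_identical(predict_proba(m, clips), probs)
  # identical seed, identical model
  m2 <- build_model(dense_inception_config("desk"), seed = 3)
  expect_identical(m$params, m2$params)
  expect_error(predict_proba(m, matrix(0, 100, 19)),
               class = "weakeeg_invalid_input")
})

test_that("freezing isolates exactly the two fully connected layers", {
  cfg <- dense_inception_config("desk")
  m <- build_model(cfg, seed = 4)
  mf <- freeze_all_but_last_two_fc(m)
  sh <- weakeeg:::config_shapes(cfg)
  h <- cfg$fc_sizes[1]
  fc_count <- sh$flat * h + h + h + 1
  expect_equal(n_trainable_params(mf), fc_count)
  expect_true(all(!mf$trainable[grep("^block", names(mf$trainable))]))
  # one optimizer pass leaves every convolutional parameter untouched
  clips <- toy_clips(10, seed = 5)
  fit <- train(mf, clips, clips, train_config("desk", epochs = 1, seed = 6))
  for (nm in grep("^block", names(m$params), value = TRUE))
    expect_identical(fit$model$params[[nm]], m$params[[nm]])
  expect_false(identical(fit$model$params[["fc1.W"]], m$params[["fc1.W"]]))
  expect_equal(n_trainable_params(unfreeze_all(mf)), n_params(m))
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_config()
  mod <- build_model(cfg, seed = 1)
  set.seed(42)
  B <- 3
  clips <- lapply(1:B, function(i) matrix(rnorm(2400 * 19), 2400, 19))
  y <- c(1, 0, 1)
  xb <- do.call(cbind, lapply(clips, t))
  fw <- weakeeg:::nn_forward(mod, xb, B, keep_cache = TRUE)
  gr <- weakeeg:::nn_backward(mod, fw, y)
  loss_of <- function(m) {
    z <- weakeeg:::nn_forward(m, xb, B)$logit
    mean(ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z))) - y * z)
  }
  eps <- 1e-6
  for (nm in names(mod$params)) {
    for (rep in 1:3) {
      i <- sample(length(mod$params[[nm]]), 1)
      mp <- mod; mp$params[[nm]][i] <- mod$params[[nm]][i] + eps
      mm <- mod; mm$params[[nm]][i] <- mod$params[[nm]][i] - eps
      num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("every parameter receives gradient on a generic batch", {
  cfg <- dense_inception_config("desk")
  m <- build_model(cfg, seed = 7)
  set.seed(11)
  clips <- lapply(1:6, function(i) matrix(rnorm(2400 * 19, sd = 20), 2400, 19))
  xb <- do.call(cbind, lapply(clips, t))
  fw <- weakeeg:::nn_forward(m, xb, 6, keep_cache = TRUE)
  gr <- weakeeg:::nn_backward(m, fw, c(1, 0, 1, 0, 1, 0))
  for (nm in names(m$params))
    expect_gt(max(abs(gr[[nm]])), 0)
})
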