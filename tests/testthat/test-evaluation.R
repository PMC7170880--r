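# Confusion metrics, ROC/AUROC with brute-force oracles, operating points,
# and seed aggregation.

# Independent oracles: direct counting over all positive-negative pairs and
# exhaustive threshold scans.
auroc_by_pairs <- function(labels, probs) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

test_that("confusion metrics implement the four definitions exactly", {
  r <- confusion_metrics(c(1, 0), c(0.9, 0.1))
  expect_equal(r[c("precision", "recall", "f1", "fpr")],
               list(precision = 1, recall = 1, f1 = 1, fpr = 0))
  # hand-evaluated counts TP=3 FP=1 FN=2 TN=4
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  probs <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.3, 0.2, 0.1, 0.05)
  m <- confusion_metrics(labels, probs, 0.5)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(3, 1, 2, 4))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m$fpr, 0.2)
  # F1 symmetric closed form
  expect_equal(2 * 0.5 * 0.5 / (0.5 + 0.5), 0.5)
  # zero-denominator conventions
  z <- confusion_metrics(c(0, 0), c(0.1, 0.2), 0.5)
  expect_equal(c(z$precision, z$recall, z$f1, z$fpr), c(0, 0, 0, 0))
  expect_error(confusion_metrics(c(1, 0), 0.5), class = "weakeeg_invalid_input")
})

test_that("AUROC equals pair counting and the curve is well-formed", {
  expect_equal(roc_auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))$auroc, 0.75)
  expect_equal(roc_auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auroc, 1.0)
  expect_equal(roc_auroc(c(1, 0, 1, 0), rep(0.4, 4))$auroc, 0.5)
  expect_error(roc_auroc(c(1, 1), c(0.2, 0.3)),
               class = "weakeeg_undefined_metric")
  # property: oracle equivalence on random instances of up to 20 clips,
  # including heavy ties
  set.seed(99)
  for (i in 1:40) {
    n <- sample(4:20, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    probs <- round(runif(n), sample(c(1, 2), 1))
    ra <- roc_auroc(labels, probs)
    expect_equal(ra$auroc, auroc_by_pairs(labels, probs))
    # curve endpoints and monotonicity
    expect_equal(ra$roc$fpr[1], 0); expect_equal(ra$roc$tpr[1], 0)
    expect_equal(tail(ra$roc$fpr, 1), 1); expect_equal(tail(ra$roc$tpr, 1), 1)
    expect_true(all(diff(ra$roc$fpr) >= 0) && all(diff(ra$roc$tpr) >= 0))
  }
})

test_that("operating points match an exhaustive threshold scan", {
  # dominant point of a perfect classifier
  perfect <- roc_auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$roc
  op <- operating_point(perfect, target_tpr = 0.9)
  expect_equal(c(op$tpr, op$fpr), c(1, 0))
  # boundary: only FPR=0 point has TPR=0
  flat <- data.frame(threshold = c(Inf, 0.5, -Inf), fpr = c(0, 1, 1),
                     tpr = c(0, 1, 1))
  op0 <- operating_point(flat, target_fpr = 0)
  expect_equal(c(op0$tpr, op0$fpr), c(0, 0))
  expect_error(operating_point(flat[2, ], target_fpr = -1),
               class = "weakeeg_no_feasible_threshold")
  # brute-force oracle on random small curves
  set.seed(123)
  for (i in 1:20) {
    labels <- c(0, 1, sample(0:1, 10, replace = TRUE))
    probs <- round(runif(12), 2)
    rc <- roc_auroc(labels, probs)$roc
    tgt <- runif(1)
    feasible <- rc[rc$tpr >= tgt, ]
    if (nrow(feasible) > 0) {
      op <- operating_point(rc, target_tpr = tgt)
      expect_equal(op$fpr, min(feasible$fpr))
      expect_gte(op$tpr, tgt)
    }
    feas2 <- rc[rc$fpr <= tgt, ]
    if (nrow(feas2) > 0) {
      op2 <- operating_point(rc, target_fpr = tgt)
      expect_equal(op2$tpr, max(feas2$tpr))
      expect_lte(op2$fpr, tgt)
    }
  }
})

test_that("seed aggregation reports mean, t-interval, and median", {
  a <- aggregate_over_seeds(rep(0.8, 5))
  expect_equal(a$mean, 0.8)
  expect_equal(diff(a$ci), 0)
  expect_equal(aggregate_over_seeds(c(0.7, 0.8, 0.9))$median, 0.8)
  # frozen closed-form check: mean 0.8, sd 0.1581139, t(.975, 4) = 2.776445
  b <- aggregate_over_seeds(c(0.6, 0.7, 0.8, 0.9, 1.0))
  expect_equal(b$ci, c(0.6036757, 0.9963243), tolerance = 1e-6)
  expect_error(aggregate_over_seeds(0.5),
               class = "weakeeg_insufficient_replicates")
})

test_that("the median ROC is the pointwise median over a common FPR grid", {
  r1 <- data.frame(threshold = c(Inf, 1, -Inf), fpr = c(0, 0, 1), tpr = c(0, 1, 1))
  r2 <- data.frame(threshold = c(Inf, 1, -Inf), fpr = c(0, 1, 1), tpr = c(0, 0, 1))
  r3 <- data.frame(threshold = c(Inf, 1, -Inf), fpr = c(0, 0.5, 1), tpr = c(0, 0.5, 1))
  med <- median_roc(list(r1, r2, r3))
  expect_equal(nrow(med), 101)
  # at fpr 0.75 the three curves give tpr 1, 0, 0.5 -> median 0.5
  expect_equal(med$tpr[med$fpr == 0.75], 0.5)
})
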