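test_that("Hamming loss counts disagreeing positions", {
  Y <- matrix(c(1, 0, 1, 0, 1, 0), 2, 3)
  expect_equal(hamming_loss(Y, Y), 0)
  expect_equal(hamming_loss(Y, 1 - Y), 1)
  P <- Y; P[1, 1] <- 0
  expect_equal(hamming_loss(Y, P), 1 / 6)
  expect_error(hamming_loss(Y, Y[, 1:2]), "shape")
  expect_error(hamming_loss(Y, Y * 2), "binary")
})

test_that("Jaccard similarity handles identity, disjointness and empty unions", {
  Y <- rbind(c(1, 1, 0), c(0, 1, 1))
  expect_equal(jaccard_similarity(Y, Y), 1)
  expect_equal(jaccard_similarity(rbind(c(1, 0, 0)), rbind(c(0, 1, 1))), 0)
  expect_equal(jaccard_similarity(rbind(c(1, 1, 0)), rbind(c(1, 0, 1))),
               1 / 3)
  # one exact empty-union row (scores 1), one disjoint row (scores 0)
  expect_equal(jaccard_similarity(rbind(c(0, 0), c(1, 0)),
                                  rbind(c(0, 0), c(0, 1))), 0.5)
})

test_that("accuracy modes agree with direct counting", {
  Y <- rbind(c(1, 0), c(1, 1), c(0, 1))
  expect_equal(ml_accuracy(Y, Y, "bitwise"), 1)
  expect_equal(ml_accuracy(Y, Y, "subset"), 1)
  P <- rbind(c(1, 0), c(1, 0), c(1, 0)) # all-correct, one-bit, all-wrong
  expect_equal(ml_accuracy(Y, P, "subset"), 1 / 3)
  expect_error(ml_accuracy(Y, P, "bogus"))

  set.seed(73)
  for (i in 1:50) {
    A <- matrix(rbinom(24, 1, 0.5), 4, 6)
    B <- matrix(rbinom(24, 1, 0.5), 4, 6)
    expect_equal(ml_accuracy(A, B), 1 - hamming_loss(A, B))
  }
})

test_that("precision, recall and F1 match the printed contingency", {
  # one label, 20 instances: TP = 8, FP = 2, FN = 4, TN = 6
  Y <- matrix(c(rep(1, 8), rep(0, 2), rep(1, 4), rep(0, 6)), ncol = 1)
  P <- matrix(c(rep(1, 8), rep(1, 2), rep(0, 4), rep(0, 6)), ncol = 1)
  out <- precision_recall_f1(Y, P, "micro")
  expect_equal(out$precision, 0.8)
  expect_equal(out$recall, 2 / 3)
  expect_equal(out$f1, 8 / 11) # 2PR/(P+R)

  expect_equal(as.numeric(precision_recall_f1(Y, Y, "micro")), c(1, 1, 1))
  P0 <- matrix(0, nrow(Y), 1)
  zero <- precision_recall_f1(Y, P0, "micro")
  expect_equal(zero$recall, 0)
  expect_equal(zero$f1, 0)
})

test_that("per-label confusion partitions every instance", {
  set.seed(79)
  Y <- matrix(rbinom(60, 1, 0.4), 10, 6)
  P <- matrix(rbinom(60, 1, 0.4), 10, 6)
  conf <- per_label_confusion(Y, P)
  expect_equal(conf$tp + conf$fp + conf$fn + conf$tn, rep(10, 6))
  # brute-force instance loop
  for (j in 1:6) {
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (i in 1:10) {
      if (Y[i, j] == 1 && P[i, j] == 1) tp <- tp + 1
      if (Y[i, j] == 0 && P[i, j] == 1) fp <- fp + 1
      if (Y[i, j] == 1 && P[i, j] == 0) fn <- fn + 1
      if (Y[i, j] == 0 && P[i, j] == 0) tn <- tn + 1
    }
    expect_equal(as.numeric(conf[j, c("tp", "fp", "fn", "tn")]),
                 c(tp, fp, fn, tn))
  }
  perfect <- per_label_confusion(Y, Y)
  expect_true(all(perfect$fp == 0 & perfect$fn == 0))
})

test_that("metrics are invariant to simultaneous label permutations", {
  set.seed(83)
  Y <- matrix(rbinom(60, 1, 0.4), 10, 6)
  P <- matrix(rbinom(60, 1, 0.4), 10, 6)
  perm <- sample(6)
  r1 <- evaluate_multilabel(Y, P)
  r2 <- evaluate_multilabel(Y[, perm], P[, perm])
  # aggregate metrics are invariant; the per-label confusion attribute is
  # permuted alongside, so compare the bare metric rows
  expect_equal(as.data.frame(tibble::as_tibble(r1)),
               as.data.frame(tibble::as_tibble(r2)), ignore_attr = TRUE)
})

test_that("micro-F1 from pooled confusion sums matches the metric output", {
  set.seed(89)
  Y <- matrix(rbinom(120, 1, 0.35), 20, 6)
  P <- matrix(rbinom(120, 1, 0.35), 20, 6)
  conf <- per_label_confusion(Y, P)
  tp <- sum(conf$tp); fp <- sum(conf$fp); fn <- sum(conf$fn)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  f1 <- 2 * p * r / (p + r)
  out <- precision_recall_f1(Y, P, "micro")
  expect_equal(out$f1, f1, tolerance = 1e-12)
  expect_equal(out$precision, p, tolerance = 1e-12)
})

test_that("the combined report carries all metrics and serialises", {
  set.seed(97)
  Y <- matrix(rbinom(60, 1, 0.4), 10, 6)
  P <- matrix(rbinom(60, 1, 0.4), 10, 6)
  rep <- evaluate_multilabel(Y, P)
  vals <- as.numeric(tibble::as_tibble(rep))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(rep$accuracy, 1 - rep$hamming_loss)

  path <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$metrics$hamming_loss, rep$hamming_loss)

  roc <- roc_points(Y, matrix(runif(60), 10, 6),
                    thresholds = c(0, 0.5, 1))
  expect_equal(nrow(roc), 18)
  expect_true(all(roc$tpr[roc$threshold == 0] == 1, na.rm = TRUE))
})
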