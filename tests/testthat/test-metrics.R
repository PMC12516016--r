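test_that("stratified split follows the floor/round/remainder convention", {
  # n = 10 per class -> 7 / 1 / 2
  labels <- rep(c(0, 1), each = 10)
  s <- stratified_split(labels, split_spec(seed = 4L))
  expect_equal(lengths(s), c(train = 14L, validation = 2L, test = 4L))
  for (cl in 0:1) {
    expect_equal(sum(labels[s$train] == cl), 7L)
    expect_equal(sum(labels[s$validation] == cl), 1L)
    expect_equal(sum(labels[s$test] == cl), 2L)
  }
  # disjoint and exhaustive
  expect_equal(sort(unname(unlist(s))), seq_along(labels))
  # same seed reproduces exactly; different seed reshuffles
  expect_identical(s, stratified_split(labels, split_spec(seed = 4L)))
  expect_false(identical(s, stratified_split(labels, split_spec(seed = 5L))))
})

test_that("degenerate fractions and tiny classes are handled", {
  labels <- rep(c(0, 1), each = 10)
  s <- stratified_split(labels, split_spec(c(1, 0, 0)))
  expect_equal(length(s$train), 20L)
  expect_equal(length(s$validation) + length(s$test), 0L)
  expect_error(stratified_split(rep(c(0, 1), c(2, 10))), "cannot populate")
  expect_error(stratified_split(rep(1, 10)), "two classes")
  expect_error(split_spec(c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("kfold indices are stratified, disjoint and balanced", {
  labels <- rep(c(0, 1), c(48, 52))
  folds <- kfold_indices(labels, k = 5L, seed = 2L)
  expect_length(folds, 5L)
  expect_equal(sort(unlist(folds)), seq_along(labels))
  expect_equal(vapply(folds, length, integer(1)), rep(20L, 5))
  for (cl in 0:1) {
    per <- vapply(folds, function(f) sum(labels[f] == cl), integer(1))
    expect_lte(diff(range(per)), 1L)
  }
  # uneven class counts (7, 9), k = 3
  labels2 <- rep(c(0, 1), c(7, 9))
  folds2 <- kfold_indices(labels2, 3L, seed = 0L)
  for (cl in 0:1) {
    per <- vapply(folds2, function(f) sum(labels2[f] == cl), integer(1))
    expect_lte(diff(range(per)), 1L)
  }
  expect_error(kfold_indices(rep(c(0, 1), c(3, 50)), k = 5L), "at least k")
  expect_error(kfold_indices(labels, k = 1L))
})

test_that("confusion metrics match hand-computed values", {
  # TP=40 FP=10 FN=5 TN=45: p_o = 0.85, p_e = 0.5, kappa = 0.7
  y <- rep(c(1, 1, 0, 0), c(40, 5, 10, 45))
  p <- rep(c(1, 0, 1, 0), c(40, 5, 10, 45))
  m <- compute_metrics(y, p, curves = FALSE)
  expect_equal(unname(m$confusion), c(40L, 10L, 5L, 45L))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 40 / 45)
  expect_equal(m$kappa, 0.7)
  expect_equal(m$f1, 2 * 0.8 * (40 / 45) / (0.8 + 40 / 45))

  perfect <- compute_metrics(c(1, 0, 1), c(0.9, 0.1, 0.8))
  for (f in c("accuracy", "precision", "recall", "f1", "kappa", "auroc",
              "auprc")) {
    expect_equal(perfect[[f]], 1)
  }
})

test_that("metric identities hold against the returned confusion matrix", {
  set.seed(12)
  y <- rbinom(200, 1, 0.45)
  p <- pmin(pmax(y * 0.3 + runif(200) * 0.7, 0), 1)
  m <- compute_metrics(y, p)
  cm <- as.numeric(m$confusion)  # TP FP FN TN
  n <- sum(cm)
  expect_equal(m$accuracy, (cm[1] + cm[4]) / n, tolerance = 1e-12)
  expect_equal(m$precision, cm[1] / (cm[1] + cm[2]), tolerance = 1e-12)
  expect_equal(m$recall, cm[1] / (cm[1] + cm[3]), tolerance = 1e-12)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
               tolerance = 1e-12)
  p_e <- ((cm[1] + cm[2]) * (cm[1] + cm[3]) +
            (cm[3] + cm[4]) * (cm[2] + cm[4])) / n^2
  expect_equal(m$kappa, (m$accuracy - p_e) / (1 - p_e), tolerance = 1e-12)
})

test_that("zero-denominator metrics warn and report 0", {
  expect_warning(m <- compute_metrics(c(1, 1, 0), c(0.1, 0.2, 0.3),
                                      curves = FALSE), "degenerate")
  expect_equal(m$precision, 0)
  expect_true(m$degenerate)
})

test_that("AUROC equals brute-force pair counting, including ties", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(8:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- round(runif(n), 1)          # coarse grid forces ties
    cv <- roc_pr_curves(y, p)
    expect_equal(cv$auroc, oracle_auroc(y, p), tolerance = 1e-12)
    expect_gte(cv$auprc, 0); expect_lte(cv$auprc, 1)
  }
  sep <- roc_pr_curves(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(sep$auroc, 1)
  expect_equal(sep$auprc, 1)
  expect_error(roc_pr_curves(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("random scores give chance-level AUROC at large n", {
  set.seed(77)
  y <- rbinom(4000, 1, 0.5)
  p <- runif(4000)
  expect_lt(abs(roc_pr_curves(y, p)$auroc - 0.5), 0.03)
})

test_that("raising the threshold never increases recall", {
  set.seed(55)
  y <- rbinom(100, 1, 0.5)
  p <- runif(100)
  rec <- vapply(seq(0, 1, by = 0.1), function(th)
    suppressWarnings(compute_metrics(y, p, th, curves = FALSE)$recall),
    numeric(1))
  expect_true(all(diff(rec) <= 1e-12))
})

test_that("fold aggregation uses mean and population sd", {
  mk <- function(acc, kap) {
    structure(list(accuracy = acc, precision = 0.9, recall = 0.8,
                   f1 = 0.85, kappa = kap, auroc = 0.9, auprc = 0.9),
              class = "classification_metrics")
  }
  acc <- c(89.37, 90.26, 90.10, 90.18, 90.66) / 100
  kap <- c(0.781, 0.797, 0.796, 0.798, 0.800)
  folds <- Map(mk, acc, kap)
  fs <- aggregate_folds(folds)
  expect_equal(unname(fs$mu["accuracy"]), mean(acc))
  expect_equal(unname(fs$sigma["accuracy"]),
               sqrt(mean((acc - mean(acc))^2)))
  expect_gte(max(acc), fs$mu["accuracy"])
  expect_lte(min(acc), fs$mu["accuracy"])
  # identical folds -> sigma 0
  same <- aggregate_folds(Map(mk, rep(0.9, 3), rep(0.8, 3)))
  expect_equal(unname(same$sigma["accuracy"]), 0)
  expect_error(aggregate_folds(folds[1]), "two folds")
})
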