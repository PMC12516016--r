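test_that("bce_loss matches its closed form and is symmetric", {
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(1, 1 - 1e-7), 1e-6)
  expect_equal(bce_loss(1, 1), bce_loss(0, 0))   # clipped endpoints
  set.seed(1)
  y <- rbinom(20, 1, 0.5)
  h <- runif(20)
  expect_equal(bce_loss(y, h), bce_loss(1 - y, 1 - h), tolerance = 1e-12)
  expect_gte(bce_loss(y, h), 0)
  expect_error(bce_loss(c(1, 0), 0.5), "length")
  expect_error(bce_loss(c(2, 0), c(0.5, 0.5)), "binary")
})

test_that("configuration constructors validate their contracts", {
  expect_error(branch_config("nosuchnet"), "unregistered")
  expect_error(branch_config(frozen = FALSE), "frozen")
  expect_error(train_config(subbands = character(0)))
  expect_error(train_config(patience = 50L, max_epochs = 50L), "patience")
  tc <- train_config(subbands = c("HH", "LL"))
  expect_equal(tc$subbands, c("LL", "HH"))   # canonical order
})

test_that("branch forward pass honours shape and range contracts", {
  br <- build_branch(input_shape = c(64L, 64L, 3L), seed = 3L)
  expect_equal(br$feature_shape, c(4L, 4L, 64L))
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  s1 <- branch_score(br, img)
  expect_gt(s1, 0); expect_lt(s1, 1)
  # deterministic: rebuilding with the same seed reproduces bit-identically
  br2 <- build_branch(input_shape = c(64L, 64L, 3L), seed = 3L)
  expect_identical(branch_score(br2, img), s1)
  expect_error(branch_score(br, array(0, c(32, 32, 3))), "shape")
})

test_that("descriptor backbones expose shape contracts but not forward passes", {
  expect_error(build_branch(branch_config("efficientnetv2b2")), "descriptor")
  expect_equal(backbone_feature_shape("resnet50", c(128, 128, 3))[3], 2048L)
})

test_that("assembled model emits an ordered probability vector", {
  model <- build_model(input_shape = c(32L, 32L, 3L), seed = 1L)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  pred <- predict_model(model, list(img))
  expect_equal(colnames(pred$P), c("LL", "LH", "HL", "HH"))
  expect_true(all(pred$P > 0 & pred$P < 1))
  expect_true(pred$probabilities > 0 && pred$probabilities < 1)
  # identical input twice in inference mode -> identical output
  pred2 <- predict_model(model, list(img, img))
  expect_identical(pred2$probabilities[1], pred2$probabilities[2])
  # single-band model is valid
  hh <- build_model(subbands = "HH", input_shape = c(32L, 32L, 3L))
  phh <- predict_model(hh, list(img))
  expect_equal(colnames(phh$P), "HH")
  expect_error(build_model(subbands = character(0)), "nonempty")
})

test_that("threshold semantics: ties positive, zero threshold all positive", {
  model <- build_model(input_shape = c(32L, 32L, 3L), seed = 2L)
  imgs <- lapply(1:3, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  pred <- predict_model(model, imgs, threshold = 0)
  expect_equal(pred$labels, rep(1L, 3))
  p <- pred$probabilities[1]
  expect_equal(predict_model(model, imgs[1], threshold = p)$labels, 1L)
})

test_that("training learns a separable problem and freezes the backbone", {
  fit <- small_trained_fit()
  h <- fit$history
  expect_true(all(c("epoch", "train_loss", "train_acc", "val_loss",
                    "val_acc") %in% names(h)))
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  # frozen contract, both by identity and by checksum
  ds <- small_dataset()
  model0 <- build_model(input_shape = c(64L, 64L, 3L), seed = 11L)
  expect_identical(backbone_checksum(model0), backbone_checksum(fit$model))
  expect_identical(model0$branches$LL$backbone, fit$model$branches$LL$backbone)
})

test_that("training is reproducible for an identical config and seed", {
  ds <- small_dataset()
  split <- stratified_split(ds$labels, split_spec(seed = 11L))
  pick <- function(idx) list(images = ds$images[idx],
                             labels = ds$labels[idx])
  tc <- train_config(max_epochs = 3L, patience = 2L, seed = 21L)
  f1 <- train_model(build_model(input_shape = c(64L, 64L, 3L), seed = 21L),
                    pick(split$train), pick(split$validation), tc)
  f2 <- train_model(build_model(input_shape = c(64L, 64L, 3L), seed = 21L),
                    pick(split$train), pick(split$validation), tc)
  expect_identical(f1$history, f2$history)
})

test_that("early stopping halts after patience epochs without improvement", {
  ds <- small_dataset()
  split <- stratified_split(ds$labels, split_spec(seed = 11L))
  pick <- function(idx) list(images = ds$images[idx],
                             labels = ds$labels[idx])
  # learning rate 0: no parameter ever changes, so validation accuracy is
  # flat; best epoch is 1 and training must stop at epoch 1 + patience
  fit <- train_model(build_model(input_shape = c(64L, 64L, 3L), seed = 1L),
                     pick(split$train), pick(split$validation),
                     train_config(learning_rate = 0, max_epochs = 20L,
                                  patience = 4L, seed = 1L))
  expect_equal(nrow(fit$history), 1L + 4L)
  expect_equal(length(unique(fit$history$val_acc)), 1L)
})

test_that("train_model rejects empty sets and non-binary labels", {
  ds <- small_dataset()
  model <- build_model(input_shape = c(64L, 64L, 3L))
  good <- list(images = ds$images[1:4], labels = c(1, 1, 0, 0))
  expect_error(train_model(model, list(images = list(), labels = numeric(0)),
                           good), "nonempty")
  bad <- list(images = ds$images[1:2], labels = c(1, 2))
  expect_error(train_model(model, bad, good), "binary")
})
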