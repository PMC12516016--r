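# Shared fixtures, built lazily and cached for the session.  The small
# trained model uses 64x64 synthetic images so that several test files can
# exercise training, prediction and Grad-CAM without repeating the cost.

.fixture_env <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    spec <- synthetic_spec(image_size = 64L, n_fracture = 40L,
                           n_nonfracture = 40L, bone_width = c(10, 16),
                           crack_width = c(2, 3), seed = 11L)
    .fixture_env$ds <- generate_dataset(spec)
  }
  .fixture_env$ds
}

small_trained_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    ds <- small_dataset()
    split <- stratified_split(ds$labels, split_spec(seed = 11L))
    pick <- function(idx) list(images = ds$images[idx],
                               labels = ds$labels[idx])
    model <- build_model(input_shape = c(64L, 64L, 3L), seed = 11L)
    fit <- train_model(model, pick(split$train), pick(split$validation),
                       train_config(max_epochs = 8L, patience = 3L,
                                    seed = 11L))
    fit$split <- split
    .fixture_env$fit <- fit
  }
  .fixture_env$fit
}
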