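# Trained-model fixture, built once per test run and shared across test
# files (training the tiny backbone takes a couple of minutes).

.model_cache <- new.env(parent = emptyenv())

# 800 subjects -> 600 training / 200 validation pairs, plus a 200-pair
# standalone test set, at the default study-like conditions.
fixture_dataset <- function() {
  if (is.null(.model_cache$dataset)) {
    .model_cache$dataset <- generate_dataset(n_train_val = 800,
                                             n_test = 200,
                                             prevalence = 0.42,
                                             seed = 11)
  }
  .model_cache$dataset
}

fixture_model_config <- function() model_config(epochs = 30, seed = 7)

fixture_model <- function() {
  if (is.null(.model_cache$model)) {
    .model_cache$model <- train(fixture_dataset(), fixture_model_config())
  }
  .model_cache$model
}

# Fused tensors and labels for a dataset split.
fixture_fused <- function(split) {
  lapply(split, function(r) fuse_channels(r$pair))
}

fixture_truth <- function(split) {
  ifelse(vapply(split, `[[`, logical(1), "label"),
         "suspicious", "non_suspicious")
}
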