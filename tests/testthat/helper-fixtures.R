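# Shared fixtures, built once per test run.
#
# A small labeled Hall window set and a CNN trained on it are reused by the
# classifier, pipeline and evaluation tests; training is seconds at this
# scale. Everything is generated in code under fixed seeds.

fixture_cfg <- synth_config()

fixture_windows <- local({
  sets <- lapply(c(-90, 0, 90), function(a) {
    stitch_windows(generate_angle_stream(a, 100, fixture_cfg, seed = 1000 + a),
                   fixture_cfg)
  })
  do.call(bind_windows, sets)
})

fixture_split <- split_dataset(fixture_windows, ratio = 0.8, seed = 99)

fixture_model <- train_angle_cnn(fixture_split$train,
                                 angle_cnn_config(rng_seed = 7))

# Nearest-prototype oracle classifier: class of the nearest training-set
# class mean in Euclidean distance. Independent of the CNN code path.
prototype_classifier <- function(train) {
  classes <- sort(unique(train$label))
  protos <- t(vapply(classes, function(cl) {
    colMeans(train$values[train$label == cl, , drop = FALSE])
  }, numeric(ncol(train$values))))
  function(values) {
    if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
    d2 <- t(apply(values, 1L, function(v) rowSums((protos - rep(v, each = nrow(protos)))^2)))
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
    classes[apply(d2, 1L, which.min)]
  }
}
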