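test_that("the network has the capacity to overfit a small clean set", {
  ds <- tiny_dataset(n = 80, seed = 3)
  cfg <- fcnn_config(
    hidden = c(256, 128), lr = 3e-3, lr_decay = 0.998, batch_size = 16,
    epochs = 2000, patience = 2000, restore_best = FALSE, seed = 5
  )
  model <- train_fcnn(ds, cfg)
  tr <- which(ds$split == "train")
  train_mae <- fiborient:::mlp_mae(
    model$net, fiborient:::dataset_features(ds, tr), ds$labels[tr, ]
  )
  expect_lt(train_mae, 0.01)
  # predictions on training curves recover the parameters closely
  pred <- predict_orientation(model, ds$curves[tr, ], ds$masks[tr, ])
  truth <- ds$params[tr, ]
  for (nm in c("gamma1", "gamma2")) {
    expect_lt(mean(abs(angle_diff180(pred[[nm]], truth[[nm]]))), 1)
  }
})

test_that("training reduces validation error on a corrupted dataset", {
  labels <- sample_labels(2000, seed = 17)
  ds <- build_dataset(labels,
    grid = chi_grid(120),
    corruption = corruption_config(block_len_range = c(3, 20)),
    split_fracs = c(train = 0.8, val = 0.2, test = 0), seed = 17
  )
  model <- train_fcnn(ds, fcnn_config(
    hidden = c(128, 64), epochs = 15, patience = 15, seed = 2
  ))
  expect_lt(model$best_val_mae, model$init_val_mae)
  # the recorded running minimum of the loss history is non-increasing
  expect_true(all(diff(cummin(model$history$val_mae)) <= 0))
})

test_that("training aborts with a diagnostic when the loss diverges", {
  ds <- tiny_dataset(n = 40, seed = 1)
  expect_error(
    train_fcnn(ds, fcnn_config(hidden = c(32), lr = 1e200, epochs = 5, seed = 1)),
    "epoch"
  )
})

test_that("1-nearest-neighbor reproduces its own training labels", {
  ds <- tiny_dataset(n = 50, seed = 9)
  model <- train_baseline(ds, "knn", hyperparams = list(k = 1))
  tr <- which(ds$split == "train")
  pred <- fiborient:::predict_raw(
    model, fiborient:::dataset_features(ds, tr)
  )
  expect_equal(pred, unname(ds$labels[tr, ]), tolerance = 1e-12)
})

test_that("seeded baselines are deterministic", {
  skip_if_not_installed("randomForest")
  ds <- tiny_dataset(n = 40, seed = 11, grid = chi_grid(45))
  m1 <- train_baseline(ds, "rf", hyperparams = list(ntree = 10, seed = 4))
  m2 <- train_baseline(ds, "rf", hyperparams = list(ntree = 10, seed = 4))
  te <- fiborient:::dataset_features(ds, 1:5)
  expect_identical(
    fiborient:::predict_raw(m1, te), fiborient:::predict_raw(m2, te)
  )
})

test_that("svr baseline fits and predicts finite labels", {
  skip_if_not_installed("e1071")
  ds <- tiny_dataset(n = 40, seed = 12, grid = chi_grid(45))
  m <- train_baseline(ds, "svr", hyperparams = list(cost = 1))
  pred <- fiborient:::predict_raw(m, fiborient:::dataset_features(ds, 1:5))
  expect_true(all(is.finite(pred)))
  expect_equal(dim(pred), c(5L, 17L))
})

test_that("prediction interface preserves batch order and checks lengths", {
  ds <- tiny_dataset(n = 40, seed = 13)
  model <- train_baseline(ds, "knn", hyperparams = list(k = 3))
  batch <- predict_orientation(model, ds$curves[1:6, ], ds$masks[1:6, ])
  single <- dplyr::bind_rows(lapply(1:6, function(i) {
    predict_orientation(
      model, ds$curves[i, , drop = FALSE], ds$masks[i, , drop = FALSE]
    )
  }))
  expect_equal(batch, single, tolerance = 1e-12)
  # empty input gives an empty result
  expect_equal(nrow(predict_orientation(model, list())), 0)
  # grid-length mismatch is rejected
  expect_error(
    predict_orientation(model, matrix(0, 1, 77)),
    "does not match"
  )
})

test_that("knn validation tuning picks a k from the documented grid", {
  ds <- tiny_dataset(
    n = 60, seed = 15,
    split_fracs = c(train = 0.7, val = 0.3, test = 0)
  )
  model <- train_baseline(ds, "knn", tune = TRUE)
  expect_true(model$fit$k %in% c(1L, 3L, 5L, 10L, 20L))
})
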