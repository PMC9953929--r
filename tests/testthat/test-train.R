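# training contracts at miniature scale: early stopping, cascade freezing,
# grid search bookkeeping. Learning quality is exercised separately.

fast_cfg <- function(...) {
  args <- utils::modifyList(
    list(profile = "patch", learning_rate = 1e-3, batch_size = 8L,
         max_epochs = 3L, early_stop_patience = 3L, dropout = 0.2, seed = 1L),
    list(...)
  )
  do.call(train_config, args)
}

tiny_cohort <- function(n = 12, seed = 1) {
  cfg <- cohort_config(
    n_subjects = n, class_fraction_ad = 0.5, volume_shape = c(16, 18, 16),
    atrophy_sites = list(list(center = c(7, 8, 7), radius = 4, delta = 0.5)),
    noise_sd = 0.05, background_smoothness_mm = 4, seed = seed
  )
  generate_cohort(cfg)
}

test_that("training configuration defaults follow the study protocol", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$batch_size, 24L)
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$max_epochs, 300L)
  expect_equal(cfg$early_stop_patience, 20L)
  expect_equal(train_config("patch")$max_epochs, 200L)
  expect_error(train_config(max_epochs = 5, early_stop_patience = 10))
})

test_that("early stopping fires exactly patience epochs after the best", {
  ds <- toy_feature_dataset(n = 16, f = 4, sep = 0, seed = 3)  # no signal
  spec <- patchcascade:::new_arch_spec(
    "head", NULL, 4L,
    list(patchcascade:::layer_dense("FC", 2, activation = "softmax",
                                    regularization = "none"))
  )
  cfg <- fast_cfg(learning_rate = 0.5, max_epochs = 60L,
                  early_stop_patience = 5L)
  fit <- train_model(build_model(spec, seed = 4), ds, ds, cfg)
  if (fit$stopped_epoch < cfg$max_epochs) {
    expect_equal(fit$stopped_epoch, fit$best_epoch + cfg$early_stop_patience)
  }
  # an improving run uses every epoch
  ds2 <- toy_feature_dataset(n = 16, f = 4, sep = 4, seed = 5)
  cfg2 <- fast_cfg(learning_rate = 1e-3, max_epochs = 8L,
                   early_stop_patience = 8L)
  fit2 <- train_model(build_model(spec, seed = 6), ds2, ds2, cfg2)
  expect_equal(nrow(fit2$history), fit2$stopped_epoch)

  expect_error(train_model(build_model(spec, seed = 1),
                           list(x = ds$x[, 1, drop = FALSE], y = "AD",
                                ids = "a"), ds, cfg),
               "both classes")
})

test_that("the cascade trains one subnet per patch and freezes them", {
  cohort <- tiny_cohort()
  vols <- cohort_volumes(cohort)
  rec <- stratified_split(cohort, split_config(c(0.6, 0.2, 0.2), seed = 2))
  tr <- rec[rec$split == "train", ]
  va <- rec[rec$split == "val", ]
  specs <- roi_patch_specs(list(c(7, 8, 7), c(8, 9, 8)), c(16, 16, 16),
                           c(16, 18, 16))
  fit <- train_cascade(specs, tr, va, volumes = vols, cfg = fast_cfg(),
                       arch = list(channels = c(2L, 2L, 2L, 2L),
                                   subnet_dense = c(8L, 4L, 2L),
                                   fusion_dense = c(8L, 4L, 2L)),
                       seed = 3)
  expect_length(fit$subnet_fits, 2L)
  expect_s3_class(fit$fusion_fit, "train_fit")

  # conv layers of the subnets are untouched by fusion training and by
  # prediction: the cascade stores the pretrained weights verbatim
  conv_params <- function(model) {
    Filter(Negate(is.null), lapply(seq_along(model$spec$layers), function(i) {
      if (model$spec$layers[[i]]$kind == "conv3d") model$params[[i]]
    }))
  }
  before <- lapply(fit$subnet_fits, function(f) conv_params(f$model))
  te <- rec[rec$split == "test", ]
  probs <- predict_cascade(fit, te, vols)
  after <- lapply(fit$subnet_fits, function(f) conv_params(f$model))
  expect_identical(before, after)
  expect_equal(nrow(probs), nrow(te))
  expect_equal(rowSums(probs), rep(1, nrow(te)), tolerance = 1e-9)

  # fusion input length is the sum of the subnets' deep-feature lengths
  expect_equal(fit$fusion_fit$model$spec$in_channels,
               sum(vapply(fit$subnet_fits, function(f) {
                 conv_feature_length(f$model$spec)
               }, integer(1))))
})

test_that("grid search evaluates combinations and breaks ties as stated", {
  ds <- toy_feature_dataset(n = 20, f = 4, sep = 3, seed = 7)
  spec <- patchcascade:::new_arch_spec(
    "head", NULL, 4L,
    list(patchcascade:::layer_dense("FC", 2, activation = "softmax",
                                    regularization = "none"))
  )
  single <- grid_search(list(learning_rate = 0.01), ds, spec,
                        base_cfg = fast_cfg(), k = 5, seed = 1)
  expect_equal(single$best$learning_rate, 0.01)
  expect_equal(nrow(single$results), 1L)

  dup <- grid_search(list(learning_rate = c(0.01, 0.01)), ds, spec,
                     base_cfg = fast_cfg(), k = 5, seed = 1)
  expect_equal(nrow(dup$results), 1L)  # duplicates collapse
  expect_equal(dup$best$learning_rate, single$best$learning_rate)

  # a non-learning configuration loses to a learning one
  two <- grid_search(list(learning_rate = c(1e-9, 0.05)), ds, spec,
                     base_cfg = fast_cfg(max_epochs = 10L,
                                         early_stop_patience = 10L),
                     k = 5, seed = 2)
  expect_equal(two$best$learning_rate, 0.05)
  expect_error(grid_search(list(), ds, spec), "empty")
})
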