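#' Training configuration
#'
#' Defaults follow the study protocol: Adam with learning rate 1e-4, batch
#' size 24, dropout 0.5, weighted binary cross-entropy with balanced class
#' weights, up to 300 epochs for subject-level models or 200 for patch-level
#' subnetworks (which converge faster), and early stopping when the
#' monitored validation metric fails to improve for 20 consecutive epochs.
#'
#' @param profile `"baseline"` (300 epochs) or `"patch"` (200 epochs).
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param dropout dropout rate (applied where the architecture places it).
#' @param max_epochs maximum training epochs; default set by `profile`.
#' @param early_stop_patience consecutive non-improving epochs tolerated.
#' @param monitor `"val_loss"` (default) or `"val_acc"`.
#' @param seed integer seed governing batching order and dropout masks.
#' @param verbose print per-epoch losses.
#' @return A `train_config` list.
#' @export
train_config <- function(profile = c("baseline", "patch"),
                         learning_rate = 1e-4, batch_size = 24L,
                         dropout = 0.5, max_epochs = NULL,
                         early_stop_patience = 20L,
                         monitor = c("val_loss", "val_acc"),
                         seed = 1L, verbose = FALSE) {
  profile <- match.arg(profile)
  monitor <- match.arg(monitor)
  if (is.null(max_epochs)) {
    max_epochs <- if (profile == "baseline") 300L else 200L
  }
  max_epochs <- as.integer(max_epochs)
  early_stop_patience <- as.integer(early_stop_patience)
  stopifnot(learning_rate > 0, early_stop_patience >= 1L,
            max_epochs >= early_stop_patience, dropout >= 0, dropout < 1)
  structure(
    list(profile = profile, optimizer = "adam",
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         dropout = dropout, max_epochs = max_epochs,
         early_stop_patience = early_stop_patience, monitor = monitor,
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "train_config"
  )
}

# a labelled batch: x = (x,y,z,channel,sample) array or (feature,sample)
# matrix; y = character labels in {AD, CN}; ids = subject ids
nn_dataset <- function(x, y, ids = NULL) {
  y <- as.character(y)
  stopifnot(all(y %in% c("AD", "CN")))
  n <- if (is.matrix(x)) ncol(x) else dim(x)[length(dim(x))]
  stopifnot(n == length(y))
  list(x = x, y = y, ids = ids)
}

dataset_n <- function(ds) length(ds$y)

dataset_subset <- function(ds, idx) {
  x <- if (is.matrix(ds$x)) ds$x[, idx, drop = FALSE]
       else {
         d <- dim(ds$x)
         array(ds$x[, , , , idx, drop = FALSE], c(d[1:4], length(idx)))
       }
  list(x = x, y = ds$y[idx], ids = ds$ids[idx])
}

label_index <- function(y) ifelse(y == "AD", 1L, 2L)

# fetch one subject's volume (in-memory cohort attr or NIfTI on disk)
get_subject_volume <- function(records, volumes, id) {
  if (!is.null(volumes) && !is.null(volumes[[id]])) {
    return(as_vol3d(volumes[[id]]))
  }
  path <- records$volume_path[match(id, records$subject_id)]
  if (is.na(path) || !nzchar(path) || !file.exists(path)) {
    stop(sprintf("no volume available for subject '%s'", id), call. = FALSE)
  }
  read_volume(path)
}

# stack one patch (or the whole volume when spec is NULL) across subjects
patch_dataset <- function(records, volumes = NULL, spec = NULL) {
  vols <- lapply(records$subject_id, function(id) {
    v <- get_subject_volume(records, volumes, id)
    if (!is.null(spec)) v <- extract_patches(v, spec)[[1]]
    v$data
  })
  d <- dim(vols[[1]])
  x <- array(unlist(vols, use.names = FALSE), c(d, 1L, length(vols)))
  nn_dataset(x, records$label, records$subject_id)
}

#' Train a model with early stopping
#'
#' Minibatch Adam on weighted cross-entropy (class weights inversely
#' proportional to training-class frequency, see [class_weights()]), with L2
#' weight decay as declared by the architecture. Training stops at
#' `max_epochs` or as soon as the monitored validation metric has failed to
#' improve for `early_stop_patience` consecutive epochs; the returned model
#' carries the best-validation weights. Deterministic given the
#' configuration seed and the model's initialization seed.
#'
#' @param model a `cnn3d_model` from [build_model()].
#' @param train,val datasets as produced by the internal helpers: lists with
#'   `x` (batch array/matrix), `y` (labels `"AD"`/`"CN"`), `ids`.
#' @param cfg a [train_config()].
#' @return A `train_fit`: list with `model` (best checkpoint), `history`
#'   tibble (epoch, train_loss, val_loss, val_acc), `best_epoch`,
#'   `stopped_epoch`.
#' @export
train_model <- function(model, train, val, cfg = train_config()) {
  stopifnot(inherits(model, "cnn3d_model"), inherits(cfg, "train_config"))
  if (dataset_n(train) == 0L || dataset_n(val) == 0L) {
    stop("train and validation sets must be nonempty", call. = FALSE)
  }
  if (length(unique(train$y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  cw <- class_weights(train$y)
  w_train <- unname(cw[train$y])
  w_val <- unname(cw[val$y])
  y_train <- label_index(train$y)
  y_val <- label_index(val$y)
  n <- dataset_n(train)
  state <- adam_init(model)
  best_metric <- Inf
  best_params <- model$params
  best_epoch <- 0L
  since_improve <- 0L
  hist <- vector("list", cfg$max_epochs)
  stopped <- cfg$max_epochs
  with_local_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (b in seq_len(ceiling(n / cfg$batch_size))) {
        idx <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n)]
        xb <- dataset_subset(train, idx)
        fwd <- nn_forward(model, xb$x, training = TRUE, collect = "caches")
        loss <- nn_loss(model, fwd$probs, y_train[idx], w_train[idx])
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss at epoch %d", epoch),
               call. = FALSE)
        }
        grads <- nn_backward(model, fwd, y_train[idx], w_train[idx])
        upd <- adam_step(model, state, grads, cfg$learning_rate)
        model <- upd$model
        state <- upd$state
        batch_losses <- c(batch_losses, loss)
      }
      val_probs <- nn_forward(model, val$x, training = FALSE)
      val_loss <- nn_loss(model, val_probs, y_val, w_val)
      val_acc <- mean((val_probs[1, ] >= 0.5) == (y_val == 1L))
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(batch_losses),
        val_loss = val_loss, val_acc = val_acc
      )
      if (cfg$verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                        epoch, mean(batch_losses), val_loss, val_acc))
      }
      metric <- if (cfg$monitor == "val_loss") val_loss else -val_acc
      if (metric < best_metric) {
        best_metric <- metric
        best_params <- model$params
        best_epoch <- epoch
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
        if (since_improve >= cfg$early_stop_patience) {
          stopped <- epoch
          break
        }
      }
    }
  })
  model$params <- best_params
  structure(
    list(model = model, history = dplyr::bind_rows(hist),
         best_epoch = best_epoch, stopped_epoch = stopped),
    class = "train_fit"
  )
}

#' @export
print.train_fit <- function(x, ...) {
  cat(sprintf(
    "<train_fit> %s | stopped at epoch %d (best %d), val_loss %.4f\n",
    x$model$spec$name, x$stopped_epoch, x$best_epoch,
    x$history$val_loss[x$best_epoch]
  ))
  invisible(x)
}

#' Train the cascaded patch-level / subject-level framework
#'
#' Stage one trains one patch-level subnetwork per patch position, each from
#' its own random initialization. Stage two freezes every convolutional
#' layer of every subnetwork, extracts the flattened Conv4 deep features for
#' all subjects, concatenates them, and trains the subject-level fusion
#' subnetwork on the frozen features (the subnetworks' FC heads are used
#' only for patch-level pretraining and discarded).
#'
#' @param patch_specs a `grid_plan` or tibble of patch specs.
#' @param train_records,val_records cohort tibbles (subject_id, label,
#'   volume_path) for the two splits.
#' @param volumes optional named list of in-memory volumes keyed by
#'   subject_id; subjects not present are read from `volume_path`.
#' @param cfg a [train_config()] (applied to both stages; patch-level
#'   epochs follow its `max_epochs`).
#' @param arch list of architecture options: `channels`, `subnet_dense`,
#'   `fusion_dense`, `l2`, `dropout`.
#'
#' Patch intensities are standardized (zero mean, unit variance) using each
#' patch position's *training-set* statistics; the same affine transform is
#' applied at validation and test time and stored with the fit.
#' @param seed integer; per-subnetwork seeds are derived from it and the
#'   patch index.
#' @return A `cascade_fit`: subnetwork fits, the fusion fit, and the specs
#'   needed to score new subjects via [predict_cascade()].
#' @export
train_cascade <- function(patch_specs, train_records, val_records,
                          volumes = NULL, cfg = train_config("patch"),
                          arch = list(), seed = 1L) {
  if (inherits(patch_specs, "grid_plan")) patch_specs <- patch_specs$specs
  arch <- utils::modifyList(
    list(channels = c(8L, 16L, 32L, 64L), subnet_dense = c(1024L, 128L, 2L),
         fusion_dense = c(2048L, 512L, 2L), l2 = 1e-4, dropout = 0.5),
    arch
  )
  n_patches <- nrow(patch_specs)
  subnet_fits <- vector("list", n_patches)
  norms <- vector("list", n_patches)
  for (i in seq_len(n_patches)) {
    spec_i <- patch_specs[i, ]
    shape_i <- as.integer(unlist(spec_i[c("size_x", "size_y", "size_z")]))
    subnet <- patch_subnet_spec(shape_i, channels = arch$channels,
                                dense_units = arch$subnet_dense,
                                l2 = arch$l2, dropout = arch$dropout)
    tr <- patch_dataset(train_records, volumes, spec_i)
    va <- patch_dataset(val_records, volumes, spec_i)
    norm_i <- list(mu = mean(tr$x), sd = max(stats::sd(tr$x), 1e-8))
    tr$x <- (tr$x - norm_i$mu) / norm_i$sd
    va$x <- (va$x - norm_i$mu) / norm_i$sd
    norms[[i]] <- norm_i
    seed_i <- derive_seed(seed, i)
    model_i <- build_model(subnet, seed = seed_i)
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(seed, i, 7L)
    subnet_fits[[i]] <- tryCatch(
      train_model(model_i, tr, va, cfg_i),
      error = function(e) {
        stop(sprintf("patch %d: %s", i, conditionMessage(e)), call. = FALSE)
      }
    )
  }
  subnets <- lapply(subnet_fits, `[[`, "model")
  feat_train <- cascade_features(subnets, patch_specs, train_records, volumes,
                                 norms)
  feat_val <- cascade_features(subnets, patch_specs, val_records, volumes,
                               norms)
  fspec <- fusion_spec(lapply(subnets, `[[`, "spec"),
                       dense_units = arch$fusion_dense,
                       l2 = arch$l2, dropout = arch$dropout)
  fusion_model <- build_model(fspec, seed = derive_seed(seed, 0L, 13L))
  cfg_f <- cfg
  cfg_f$seed <- derive_seed(seed, 0L, 17L)
  fusion_fit <- train_model(
    fusion_model,
    nn_dataset(feat_train, train_records$label, train_records$subject_id),
    nn_dataset(feat_val, val_records$label, val_records$subject_id),
    cfg_f
  )
  structure(
    list(subnet_fits = subnet_fits, fusion_fit = fusion_fit,
         patch_specs = patch_specs, norms = norms, arch = arch),
    class = "cascade_fit"
  )
}

# concatenated frozen conv features for a set of subjects: (sum F_i) x N
cascade_features <- function(subnets, patch_specs, records, volumes,
                             norms = NULL) {
  feats <- lapply(seq_along(subnets), function(i) {
    ds <- patch_dataset(records, volumes, patch_specs[i, ])
    if (!is.null(norms) && !is.null(norms[[i]])) {
      ds$x <- (ds$x - norms[[i]]$mu) / norms[[i]]$sd
    }
    conv_features(subnets[[i]], ds$x)
  })
  do.call(rbind, feats)
}

#' Score subjects with a trained cascade
#'
#' @param fit a `cascade_fit`.
#' @param records cohort tibble of subjects to score.
#' @param volumes optional named list of in-memory volumes.
#' @return Matrix of `n x 2` class probabilities (columns AD, CN).
#' @export
predict_cascade <- function(fit, records, volumes = NULL) {
  stopifnot(inherits(fit, "cascade_fit"))
  subnets <- lapply(fit$subnet_fits, `[[`, "model")
  feats <- cascade_features(subnets, fit$patch_specs, records, volumes,
                            fit$norms)
  predict_proba(fit$fusion_fit$model, feats)
}

#' Hyperparameter grid search by stratified k-fold cross-validation
#'
#' Evaluates every combination of the supplied hyperparameter ranges by
#' k-fold (default fivefold) cross-validated mean accuracy on the training
#' set and returns the argmax; ties break toward the smallest learning rate,
#' then the smallest batch size.
#'
#' @param grid named list of hyperparameter value vectors; names must be
#'   [train_config()] fields (e.g. `learning_rate`, `batch_size`, `dropout`,
#'   `max_epochs`).
#' @param dataset a labelled dataset (list with `x`, `y`).
#' @param spec the `arch_spec` to train at each grid point.
#' @param base_cfg the [train_config()] supplying unsearched fields.
#' @param k number of folds.
#' @param seed integer seed for fold assignment and initializations.
#' @return List with `best` (a `train_config`) and `results` (tibble of mean
#'   CV accuracy per combination).
#' @export
grid_search <- function(grid, dataset, spec, base_cfg = train_config(),
                        k = 5L, seed = 1L) {
  if (length(grid) == 0L || any(lengths(grid) == 0L)) {
    stop("hyperparameter grid is empty", call. = FALSE)
  }
  combos <- unique(expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                               stringsAsFactors = FALSE))
  folds <- stratified_folds(dataset$y, k, seed)
  scores <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    cfg <- base_cfg
    for (nm in names(combos)) cfg[[nm]] <- combos[[nm]][ci]
    cfg$max_epochs <- max(cfg$max_epochs, cfg$early_stop_patience)
    accs <- vapply(seq_len(k), function(f) {
      tr <- dataset_subset(dataset, which(folds != f))
      te <- dataset_subset(dataset, which(folds == f))
      cfg_f <- cfg
      cfg_f$seed <- derive_seed(seed, ci, f)
      model <- build_model(spec, seed = derive_seed(seed, ci, f, 3L))
      fit <- train_model(model, tr, te, cfg_f)
      probs <- nn_forward(fit$model, te$x, training = FALSE)
      mean((probs[1, ] >= 0.5) == (te$y == "AD"))
    }, numeric(1))
    scores[ci] <- mean(accs)
  }
  results <- tibble::as_tibble(combos)
  results$mean_cv_acc <- scores
  n_res <- nrow(results)
  lr_key <- if ("learning_rate" %in% names(results)) results$learning_rate
            else rep(0, n_res)
  bs_key <- if ("batch_size" %in% names(results)) results$batch_size
            else rep(0, n_res)
  ord <- order(-results$mean_cv_acc, lr_key, bs_key)
  best_row <- results[ord[1], ]
  best <- base_cfg
  for (nm in names(combos)) best[[nm]] <- best_row[[nm]]
  list(best = best, results = results)
}

# fold labels 1..k, stratified by class
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_local_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}
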