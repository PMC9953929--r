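#' Define an experimental condition
#'
#' A condition is one way of presenting a subject's volume to the
#' classifier: a covering patch grid (`"grid"`), anatomically placed
#' region-of-interest patches (`"roi"`), or the whole-volume subject-level
#' baseline (`"baseline"`).
#'
#' @param name condition label used in tables and plots.
#' @param type `"grid"`, `"roi"` or `"baseline"`.
#' @param patch_shape integer triple (grid / roi).
#' @param counts integer triple of per-axis patch counts (grid).
#' @param centers list of 0-based voxel triples (roi).
#' @return A `condition` list.
#' @export
condition <- function(name, type = c("grid", "roi", "baseline"),
                      patch_shape = NULL, counts = NULL, centers = NULL) {
  type <- match.arg(type)
  if (type == "grid" && (is.null(patch_shape) || is.null(counts))) {
    stop("grid conditions need `patch_shape` and `counts`", call. = FALSE)
  }
  if (type == "roi" && (is.null(patch_shape) || is.null(centers))) {
    stop("roi conditions need `patch_shape` and `centers`", call. = FALSE)
  }
  structure(list(name = name, type = type, patch_shape = patch_shape,
                 counts = counts, centers = centers),
            class = "condition")
}

condition_specs <- function(cond, volume_shape) {
  switch(cond$type,
    grid = plan_grid(volume_shape, cond$patch_shape, cond$counts)$specs,
    roi = roi_patch_specs(cond$centers, cond$patch_shape, volume_shape),
    baseline = NULL
  )
}

#' Run the repeated split / undersample / train / evaluate protocol
#'
#' For each repetition the cohort is freshly split (stratified 70/10/20 by
#' default), the training set optionally halved (stratified), the test set
#' balanced by matched undersampling, and *every* condition is trained and
#' evaluated on those identical splits — a paired design, which is what
#' makes the repeated-measures ANOVA across conditions valid. Network
#' initialization, batching and dropout are re-randomized each repetition;
#' every random draw derives from `seed` and the repetition index.
#'
#' Grid and ROI conditions train the cascaded framework
#' ([train_cascade()]); the baseline condition trains the subject-level
#' network directly. When two or more conditions complete at least two
#' repetitions, the accuracy table is fed to [rm_anova()] and
#' [tukey_posthoc()].
#'
#' @param cohort cohort tibble from [generate_cohort()] (in-memory volumes
#'   are used when present, otherwise `volume_path` is read).
#' @param conditions list of [condition()] objects.
#' @param n_repetitions number of repetitions (study protocol: 20).
#' @param half_training discard a random stratified half of each training
#'   set (validation and test untouched).
#' @param split a [split_config()] (its seed is re-derived per repetition).
#' @param cfg a [train_config()].
#' @param arch architecture options passed to [train_cascade()]; also
#'   controls the baseline condition's channels/head.
#' @param seed master seed.
#' @param output_dir if non-`NULL`, per-repetition metrics CSVs are written
#'   there and existing ones are reused (the run is resumable per
#'   repetition); the final `metrics.csv` and `anova.json` are written too.
#' @return A `patch_experiment`: `metrics` (long tibble, one row per
#'   repetition x condition), `acc_table` (wide), `anova`
#'   (an `rm_anova_fit` or `NULL`), `tukey`, and the configuration.
#' @export
run_experiment <- function(cohort, conditions, n_repetitions = 20L,
                           half_training = FALSE, split = split_config(),
                           cfg = train_config("patch"), arch = list(),
                           seed = 1L, output_dir = NULL) {
  if (length(conditions) < 1L) stop("need >= 1 condition", call. = FALSE)
  if (inherits(conditions, "condition")) conditions <- list(conditions)
  volumes <- cohort_volumes(cohort)
  v1 <- get_subject_volume(cohort, volumes, cohort$subject_id[1])
  volume_shape <- dim(v1)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  }
  all_rows <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    rep_file <- if (!is.null(output_dir)) {
      file.path(output_dir, sprintf("metrics_rep%03d.csv", r))
    }
    if (!is.null(rep_file) && file.exists(rep_file)) {
      all_rows[[r]] <- tibble::as_tibble(
        utils::read.csv(rep_file, stringsAsFactors = FALSE)
      )
      next
    }
    seed_r <- derive_seed(seed, r)
    rec <- stratified_split(
      cohort, split_config(split$fractions, seed = seed_r,
                           stratified = split$stratified)
    )
    if (half_training) rec <- halve_training(rec, derive_seed(seed, r, 5L))
    train_rec <- rec[rec$split == "train", ]
    val_rec <- rec[rec$split == "val", ]
    test_rec <- rec[rec$split == "test", ]
    balanced <- undersample_match(test_rec, volumes)
    rows <- vector("list", length(conditions))
    for (ci in seq_along(conditions)) {
      cond <- conditions[[ci]]
      m <- tryCatch(
        run_condition(cond, volume_shape, train_rec, val_rec, balanced,
                      volumes, cfg, arch, derive_seed(seed, r, 100L + ci)),
        error = function(e) {
          warning(sprintf("repetition %d, condition '%s' failed: %s",
                          r, cond$name, conditionMessage(e)), call. = FALSE)
          compute_metrics(character(0), numeric(0))[0, ]
        }
      )
      if (nrow(m)) {
        rows[[ci]] <- dplyr::bind_cols(
          tibble::tibble(repetition = r, condition = cond$name), m
        )
      }
    }
    all_rows[[r]] <- dplyr::bind_rows(rows)
    if (!is.null(rep_file)) {
      utils::write.csv(all_rows[[r]], rep_file, row.names = FALSE)
    }
  }
  metrics <- dplyr::bind_rows(all_rows)
  complete <- metrics |>
    dplyr::count(.data$repetition) |>
    dplyr::filter(.data$n == length(conditions))
  acc_table <- metrics |>
    dplyr::filter(.data$repetition %in% complete$repetition) |>
    dplyr::select("repetition", "condition", "acc") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "acc")
  anova <- NULL
  tukey <- NULL
  if (length(conditions) >= 2L && nrow(acc_table) >= 2L) {
    anova <- rm_anova(metrics[metrics$repetition %in% complete$repetition, ])
    tukey <- tukey_posthoc(anova)
  }
  if (!is.null(output_dir)) {
    utils::write.csv(metrics, file.path(output_dir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(anova)) {
      write_anova_report(anova, file.path(output_dir, "anova.json"), tukey)
    }
  }
  structure(
    list(metrics = metrics, acc_table = acc_table, anova = anova,
         tukey = tukey,
         config = list(conditions = conditions,
                       n_repetitions = n_repetitions,
                       half_training = half_training, seed = seed)),
    class = "patch_experiment"
  )
}

# stratified random halving of the training split (largest remainder)
halve_training <- function(records, seed) {
  train_idx <- which(records$split == "train")
  drop <- integer(0)
  with_local_seed(seed, {
    for (cl in unique(records$label[train_idx])) {
      idx <- train_idx[records$label[train_idx] == cl]
      n_keep <- largest_remainder(length(idx), c(0.5, 0.5))[1]
      keep <- sample(idx, n_keep)
      drop <- c(drop, setdiff(idx, keep))
    }
  })
  if (length(drop)) records <- records[-drop, ]
  records
}

run_condition <- function(cond, volume_shape, train_rec, val_rec, test_rec,
                          volumes, cfg, arch, seed) {
  arch_full <- utils::modifyList(
    list(channels = c(8L, 16L, 32L, 64L), subnet_dense = c(1024L, 128L, 2L),
         fusion_dense = c(2048L, 512L, 2L), l2 = 1e-4, dropout = 0.5),
    arch
  )
  if (cond$type == "baseline") {
    spec <- baseline_spec(input_shape = volume_shape,
                          channels = arch_full$channels,
                          dense_units = arch_full$subnet_dense,
                          l2 = arch_full$l2, dropout = arch_full$dropout)
    tr <- patch_dataset(train_rec, volumes)
    va <- patch_dataset(val_rec, volumes)
    norm <- list(mu = mean(tr$x), sd = max(stats::sd(tr$x), 1e-8))
    tr$x <- (tr$x - norm$mu) / norm$sd
    va$x <- (va$x - norm$mu) / norm$sd
    model <- build_model(spec, seed = derive_seed(seed, 1L))
    cfg_b <- cfg
    cfg_b$seed <- derive_seed(seed, 2L)
    fit <- train_model(model, tr, va, cfg_b)
    te <- patch_dataset(test_rec, volumes)
    te$x <- (te$x - norm$mu) / norm$sd
    probs <- predict_proba(fit$model, te$x)
  } else {
    specs <- condition_specs(cond, volume_shape)
    fit <- train_cascade(specs, train_rec, val_rec, volumes = volumes,
                         cfg = cfg, arch = arch_full, seed = seed)
    probs <- predict_cascade(fit, test_rec, volumes)
  }
  compute_metrics(test_rec$label, probs[, "AD"])
}

#' @export
print.patch_experiment <- function(x, ...) {
  cat(sprintf("<patch_experiment> %d conditions x %d repetitions\n",
              length(x$config$conditions), x$config$n_repetitions))
  s <- x$metrics |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(dplyr::across(c("acc", "sen", "spe", "f1", "auc"),
                                   ~ mean(.x, na.rm = TRUE)))
  print(s)
  if (!is.null(x$anova)) {
    cat(sprintf("RM-ANOVA: F(%g, %g) = %.3f, reported p = %.4g\n",
                x$anova$df1, x$anova$df2, x$anova$F, x$anova$p_reported))
  }
  invisible(x)
}

#' Reduced-scale study preset
#'
#' A self-consistent miniature of the full protocol sized for interactive
#' use and continuous testing on a single CPU: 28 x 34 x 28 voxel volumes,
#' a single radius-4 atrophy site, 16^3 patches, narrow networks
#' (2/4/8/16 conv channels, compact FC heads) and short training with early
#' stopping. Two ready-made ROI conditions are included: one whose patch
#' covers the atrophy site and one placed in a site-free corner.
#'
#' @param n_subjects cohort size.
#' @param delta atrophy effect size.
#' @param seed cohort seed.
#' @return List with `cohort_config`, `conditions` (list: `covering`,
#'   `excluding`), `site` (the atrophy site), `train_config`, `arch`.
#' @export
desk_scale_preset <- function(n_subjects = 60L, delta = 0.4, seed = 1L) {
  shape <- c(28L, 34L, 28L)
  site <- list(center = c(7, 11, 7), radius = 4, delta = delta)
  list(
    cohort_config = cohort_config(
      n_subjects = n_subjects, class_fraction_ad = 0.5,
      volume_shape = shape, voxel_size_mm = 1.5,
      atrophy_sites = list(site), heterogeneity_fraction = 0,
      noise_sd = 0.05, background_smoothness_mm = 4,
      jitter_voxels = 0.5, seed = seed
    ),
    conditions = list(
      covering = condition("site_covering", "roi",
                           patch_shape = c(16L, 16L, 16L),
                           centers = list(c(7L, 11L, 7L))),
      excluding = condition("site_excluding", "roi",
                            patch_shape = c(16L, 16L, 16L),
                            centers = list(c(20L, 26L, 20L)))
    ),
    site = site,
    train_config = train_config("patch", learning_rate = 3e-3,
                                batch_size = 16L, max_epochs = 35L,
                                early_stop_patience = 15L, dropout = 0.2),
    arch = list(channels = c(2L, 4L, 8L, 16L), subnet_dense = c(32L, 16L, 2L),
                fusion_dense = c(32L, 16L, 2L), l2 = 1e-4, dropout = 0.2)
  )
}
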