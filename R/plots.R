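#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-condition accuracies of an experiment
#'
#' Boxplots of the repetition-level accuracy per condition, with the
#' individual repetitions overlaid.
#'
#' @param object a `patch_experiment`.
#' @param metric which metric column to plot (default `"acc"`).
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.patch_experiment <- function(object, metric = "acc", ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$condition, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = metric,
                  title = "Repetition-level performance by condition") +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' Training and validation loss per epoch, with the best-validation epoch
#' marked.
#'
#' @param object a `train_fit`.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.train_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(title = sprintf("Training history (%s)",
                                  object$model$spec$name),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a patch grid plan
#'
#' Projects the patch boxes onto one coordinate plane; overlap shows as
#' darker shading.
#'
#' @param object a `grid_plan`.
#' @param axes which two axes to project onto (default x and y).
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.grid_plan <- function(object, axes = c("x", "y"), ...) {
  s <- object$specs
  a1 <- axes[1]; a2 <- axes[2]
  df <- tibble::tibble(
    xmin = s[[paste0("start_", a1)]],
    xmax = s[[paste0("start_", a1)]] + s[[paste0("size_", a1)]],
    ymin = s[[paste0("start_", a2)]],
    ymax = s[[paste0("start_", a2)]] + s[[paste0("size_", a2)]]
  )
  ai <- match(axes, axis_names)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      alpha = 0.25, colour = "grey30", fill = "steelblue"
    ) +
    ggplot2::coord_fixed(
      xlim = c(0, object$volume_shape[ai[1]]),
      ylim = c(0, object$volume_shape[ai[2]])
    ) +
    ggplot2::labs(x = paste0(a1, " (voxels)"), y = paste0(a2, " (voxels)"),
                  title = sprintf("%d patches of %s", nrow(s),
                                  paste(object$patch_shape, collapse = "x"))) +
    ggplot2::theme_minimal()
}

#' Plot one slice of a volume
#'
#' @param v a [vol3d].
#' @param axis slicing axis (`"x"`, `"y"` or `"z"`).
#' @param index 1-based slice index (default: middle slice).
#' @return A ggplot raster of the slice.
#' @export
plot_volume_slice <- function(v, axis = "z", index = NULL) {
  stopifnot(inherits(v, "vol3d"))
  a <- match(axis, axis_names)
  if (is.na(a)) stop("`axis` must be 'x', 'y' or 'z'", call. = FALSE)
  d <- dim(v)
  if (is.null(index)) index <- (d[a] + 1L) %/% 2L
  sl <- switch(a, v$data[index, , ], v$data[, index, ], v$data[, , index])
  others <- axis_names[-a]
  df <- expand.grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = others[1], y = others[2], fill = "intensity",
                  title = sprintf("%s = %d slice", axis, index)) +
    ggplot2::theme_minimal()
}
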