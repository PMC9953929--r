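# Declarative architecture specifications for the VGG-like 3D CNN variants:
# the subject-level baseline, the per-patch subnetworks, and the fusion
# subnetwork that classifies concatenated deep features. The specs are pure
# data; count_parameters() and forward_shapes() derive the bookkeeping in
# closed form, and build_model() (nn.R) instantiates runnable weights.

layer_conv3d <- function(name, channels_out, kernel = c(3L, 3L, 3L),
                         stride = c(1L, 1L, 1L), padding = "same",
                         activation = "relu", regularization = "l2",
                         l2 = 1e-4) {
  list(kind = "conv3d", name = name, channels_out = as.integer(channels_out),
       kernel = as.integer(kernel), stride = as.integer(stride),
       padding = padding, activation = activation,
       regularization = regularization, l2 = l2)
}

layer_maxpool3d <- function(name, kernel, stride = kernel,
                            pool_rounding = "ceil") {
  list(kind = "maxpool3d", name = name, kernel = as.integer(kernel),
       stride = as.integer(stride), pool_rounding = pool_rounding)
}

layer_flatten <- function(name = "Flatten") list(kind = "flatten", name = name)

layer_dense <- function(name, units, activation = "relu",
                        regularization = "l2", l2 = 1e-4) {
  list(kind = "dense", name = name, units = as.integer(units),
       activation = activation, regularization = regularization, l2 = l2)
}

layer_dropout <- function(name, rate = 0.5) {
  stopifnot(rate >= 0, rate < 1)
  list(kind = "dropout", name = name, rate = rate)
}

layer_concat <- function(name = "Concat", input_lengths) {
  list(kind = "concat_inputs", name = name,
       input_lengths = as.integer(input_lengths))
}

new_arch_spec <- function(name, input_shape, in_channels, layers) {
  spec <- structure(
    list(name = name,
         input_shape = if (is.null(input_shape)) NULL
                       else check_len3(input_shape, "input_shape"),
         in_channels = as.integer(in_channels), layers = layers),
    class = "arch_spec"
  )
  validate_arch_spec(spec)
  spec
}

validate_arch_spec <- function(spec) {
  last <- spec$layers[[length(spec$layers)]]
  if (!identical(last$kind, "dense") || last$units != 2L ||
      !identical(last$activation, "softmax")) {
    stop("final layer must be a 2-unit softmax dense layer", call. = FALSE)
  }
  forward_shapes(spec)  # errors if propagation collapses an axis
  invisible(spec)
}

# the shared conv trunk + FC head; pool1 distinguishes baseline from subnets
vgg3d_layers <- function(channels, pool1, dense_units, l2, dropout) {
  pools <- list(pool1, c(2L, 2L, 2L), c(2L, 2L, 2L), c(2L, 2L, 2L))
  layers <- list()
  for (i in seq_along(channels)) {
    layers <- c(layers, list(
      layer_conv3d(paste0("Conv", i), channels[i], l2 = l2),
      layer_maxpool3d(paste0("Pool", i), pools[[i]])
    ))
  }
  layers <- c(layers, list(layer_flatten()))
  nfc <- length(dense_units)
  for (i in seq_along(dense_units)) {
    act <- if (i == nfc) "softmax" else "relu"
    reg <- if (i == nfc) "none" else "l2"
    layers <- c(layers, list(
      layer_dense(paste0("FC", i), dense_units[i], activation = act,
                  regularization = reg, l2 = l2)
    ))
    if (i < nfc) {
      layers <- c(layers, list(layer_dropout(paste0("Drop", i), dropout)))
    }
  }
  layers
}

#' Subject-level baseline architecture
#'
#' The whole-volume 3D CNN: four 3^3 same-padded unit-stride convolutions
#' with 8, 16, 32 and 64 channels, each followed by ReLU, L2 weight decay and
#' a max-pooling layer (the first 3^3 stride 3, the rest 2^3 stride 2, all
#' ceil-rounded), then fully connected layers of 1024, 128 and 2 units with
#' dropout after the first two and a softmax over the two diagnostic classes.
#' On a 91 x 115 x 91 single-channel input the conv stages produce
#' 31 x 39 x 31, 16 x 20 x 16, 8 x 10 x 8 and 4 x 5 x 4 feature maps and
#' 5,448,274 trainable parameters in total.
#'
#' @param input_shape spatial input shape (default `c(91, 115, 91)`).
#' @param channels conv channels per stage.
#' @param dense_units fully connected head sizes; last must be 2.
#' @param l2 L2 regularization strength for conv/dense weights.
#' @param dropout dropout rate after the first two FC layers.
#' @return An `arch_spec`.
#' @seealso [patch_subnet_spec()], [fusion_spec()], [count_parameters()],
#'   [forward_shapes()], [build_model()]
#' @export
#' @examples
#' count_parameters(baseline_spec())
baseline_spec <- function(input_shape = c(91L, 115L, 91L),
                          channels = c(8L, 16L, 32L, 64L),
                          dense_units = c(1024L, 128L, 2L),
                          l2 = 1e-4, dropout = 0.5) {
  new_arch_spec(
    name = "baseline", input_shape = input_shape, in_channels = 1L,
    layers = vgg3d_layers(as.integer(channels), pool1 = c(3L, 3L, 3L),
                          dense_units = as.integer(dense_units),
                          l2 = l2, dropout = dropout)
  )
}

#' Patch-level subnetwork architecture
#'
#' Identical to [baseline_spec()] except that the first max-pooling layer is
#' 2^3 stride 2 (patches are already small) and the input is one image
#' patch. The FC head is used for patch-level pretraining only; the fusion
#' stage consumes the flattened Conv4 feature maps and discards the head.
#'
#' @param patch_shape spatial patch shape; every axis must be at least 16 so
#'   the four ceil-rounded halvings retain structure.
#' @inheritParams baseline_spec
#' @return An `arch_spec`.
#' @export
patch_subnet_spec <- function(patch_shape, channels = c(8L, 16L, 32L, 64L),
                              dense_units = c(1024L, 128L, 2L),
                              l2 = 1e-4, dropout = 0.5) {
  patch_shape <- check_len3(patch_shape, "patch_shape")
  if (any(patch_shape < 16L)) {
    stop("every axis of `patch_shape` must be >= 16", call. = FALSE)
  }
  new_arch_spec(
    name = sprintf("patch_%s", paste(patch_shape, collapse = "x")),
    input_shape = patch_shape, in_channels = 1L,
    layers = vgg3d_layers(as.integer(channels), pool1 = c(2L, 2L, 2L),
                          dense_units = as.integer(dense_units),
                          l2 = l2, dropout = dropout)
  )
}

#' Subject-level fusion architecture
#'
#' Classifies a subject from the concatenated flattened Conv4 feature maps of
#' one or more (frozen) patch-level subnetworks: three FC layers (default
#' 2048, 512, 2) with ReLU + L2 on the first two, dropout 0.5 after each of
#' them, and a final softmax.
#'
#' @param patch_subnet_specs list of `arch_spec`s from [patch_subnet_spec()].
#' @param dense_units FC sizes; last must be 2.
#' @inheritParams baseline_spec
#' @return An `arch_spec` whose input is the concatenated feature vector.
#' @export
fusion_spec <- function(patch_subnet_specs, dense_units = c(2048L, 512L, 2L),
                        l2 = 1e-4, dropout = 0.5) {
  if (inherits(patch_subnet_specs, "arch_spec")) {
    patch_subnet_specs <- list(patch_subnet_specs)
  }
  if (length(patch_subnet_specs) < 1L) {
    stop("at least one patch subnetwork spec is required", call. = FALSE)
  }
  lengths <- vapply(patch_subnet_specs, conv_feature_length, integer(1))
  dense_units <- as.integer(dense_units)
  layers <- list(layer_concat(input_lengths = lengths))
  nfc <- length(dense_units)
  for (i in seq_along(dense_units)) {
    act <- if (i == nfc) "softmax" else "relu"
    reg <- if (i == nfc) "none" else "l2"
    layers <- c(layers, list(
      layer_dense(paste0("FC", i), dense_units[i], activation = act,
                  regularization = reg, l2 = l2)
    ))
    if (i < nfc) {
      layers <- c(layers, list(layer_dropout(paste0("Drop", i), dropout)))
    }
  }
  new_arch_spec(name = sprintf("fusion_%d", length(lengths)),
                input_shape = NULL, in_channels = sum(lengths),
                layers = layers)
}

#' Flattened deep-feature length of a patch subnetwork
#'
#' Length of the flattened final conv feature map (post-pool), i.e. the
#' per-patch contribution to the fusion input.
#'
#' @param spec an `arch_spec` with a conv trunk.
#' @return Integer feature length.
#' @export
conv_feature_length <- function(spec) {
  sh <- forward_shapes(spec)
  flat <- sh[sh$kind == "flatten", ]
  if (nrow(flat) == 0L) stop("spec has no flatten layer", call. = FALSE)
  as.integer(flat$n_features[1])
}

#' Per-layer output shapes by closed-form propagation
#'
#' Same-padded unit-stride convolutions preserve the spatial shape; pooling
#' maps each axis extent to `ceiling(extent / stride)` (`floor` when a layer
#' requests it, in which case an axis collapsing to zero is an error naming
#' the layer); flatten multiplies the extents by the channel count.
#'
#' @param spec an `arch_spec`.
#' @param input_shape override the spec's input shape (spatial triple).
#' @return Tibble with one row per layer: `layer`, `kind`, per-axis extents
#'   (`NA` once flattened), `channels`, and `n_features` (the flattened
#'   length at or after the flatten layer).
#' @export
#' @examples
#' forward_shapes(baseline_spec())
forward_shapes <- function(spec, input_shape = NULL) {
  stopifnot(inherits(spec, "arch_spec"))
  spatial <- if (!is.null(input_shape)) check_len3(input_shape, "input_shape")
             else spec$input_shape
  channels <- spec$in_channels
  flat <- is.null(spatial)  # fusion specs start from a feature vector
  n_features <- if (flat) spec$in_channels else NA_integer_
  rows <- list()
  for (ly in spec$layers) {
    switch(ly$kind,
      conv3d = {
        if (flat) stop("conv layer after flatten", call. = FALSE)
        if (!identical(ly$padding, "same") || any(ly$stride != 1L)) {
          stop("only same-padded unit-stride convolutions are supported",
               call. = FALSE)
        }
        channels <- ly$channels_out
      },
      maxpool3d = {
        if (flat) stop("pool layer after flatten", call. = FALSE)
        spatial <- if (identical(ly$pool_rounding, "floor")) {
          spatial %/% ly$stride
        } else {
          (spatial + ly$stride - 1L) %/% ly$stride
        }
        if (any(spatial < 1L)) {
          stop(sprintf("layer %s collapses axis %s to zero", ly$name,
                       axis_names[which(spatial < 1L)[1]]), call. = FALSE)
        }
      },
      flatten = {
        n_features <- as.integer(prod(spatial) * channels)
        flat <- TRUE
      },
      dense = {
        if (!flat) stop("dense layer requires flattened input", call. = FALSE)
        n_features <- ly$units
      },
      dropout = NULL,
      concat_inputs = {
        n_features <- as.integer(sum(ly$input_lengths))
        flat <- TRUE
      },
      stop(sprintf("unknown layer kind '%s'", ly$kind), call. = FALSE)
    )
    rows[[length(rows) + 1L]] <- tibble::tibble(
      layer = ly$name, kind = ly$kind,
      dim_x = if (flat) NA_integer_ else spatial[1],
      dim_y = if (flat) NA_integer_ else spatial[2],
      dim_z = if (flat) NA_integer_ else spatial[3],
      channels = if (flat) NA_integer_ else channels,
      n_features = if (flat) n_features else NA_integer_
    )
  }
  dplyr::bind_rows(rows)
}

#' Closed-form trainable parameter counts
#'
#' A convolution with `C_out` filters of kernel `k1 k2 k3` over `C_in`
#' channels has `C_out * (k1 k2 k3 C_in + 1)` parameters (weights plus
#' biases); a dense layer of `u` units over fan-in `f` has `u * (f + 1)`;
#' pooling, flatten, dropout and concatenation have none.
#'
#' @param spec an `arch_spec`.
#' @param input_shape optional spatial input override.
#' @return Tibble with `layer`, `kind`, `n_params`; total in
#'   `attr(, "total")` and via `sum()`.
#' @export
#' @examples
#' cp <- count_parameters(baseline_spec())
#' sum(cp$n_params)  # 5448274
count_parameters <- function(spec, input_shape = NULL) {
  stopifnot(inherits(spec, "arch_spec"))
  shapes <- forward_shapes(spec, input_shape)
  c_in <- spec$in_channels
  fan_in <- if (is.null(spec$input_shape) &&
                spec$layers[[1]]$kind != "concat_inputs") spec$in_channels
            else NA_integer_
  rows <- list()
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    n <- switch(ly$kind,
      conv3d = {
        n <- ly$channels_out * (prod(ly$kernel) * c_in + 1)
        c_in <- ly$channels_out
        n
      },
      dense = {
        n <- ly$units * (fan_in + 1)
        fan_in <- ly$units
        n
      },
      flatten = { fan_in <- shapes$n_features[i]; 0 },
      concat_inputs = { fan_in <- shapes$n_features[i]; 0 },
      0
    )
    rows[[length(rows) + 1L]] <- tibble::tibble(
      layer = ly$name, kind = ly$kind, n_params = as.numeric(n)
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "total") <- sum(out$n_params)
  out
}

#' Architecture summary table
#'
#' One row per layer with kernel, stride, output size and parameter count —
#' the conventional way such networks are tabulated.
#'
#' @param spec an `arch_spec`.
#' @param input_shape optional spatial input override.
#' @return A tibble.
#' @export
arch_summary <- function(spec, input_shape = NULL) {
  shapes <- forward_shapes(spec, input_shape)
  params <- count_parameters(spec, input_shape)
  fmt3 <- function(k) paste(k, collapse = " x ")
  kern <- vapply(spec$layers, function(ly) {
    if (!is.null(ly$kernel)) fmt3(ly$kernel)
    else if (ly$kind == "dense") as.character(ly$units)
    else "-"
  }, character(1))
  strd <- vapply(spec$layers, function(ly) {
    if (!is.null(ly$stride)) fmt3(ly$stride) else "-"
  }, character(1))
  outsz <- vapply(seq_len(nrow(shapes)), function(i) {
    if (!is.na(shapes$dim_x[i])) {
      sprintf("%d x %d x %d (x%d)", shapes$dim_x[i], shapes$dim_y[i],
              shapes$dim_z[i], shapes$channels[i])
    } else sprintf("1 x %d", shapes$n_features[i])
  }, character(1))
  tibble::tibble(
    layer = shapes$layer, kind = shapes$kind, kernel = kern, stride = strd,
    output_size = outsz, parameters = params$n_params
  )
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf("<arch_spec> %s", x$name))
  if (!is.null(x$input_shape)) {
    cat(sprintf(" | input %s x %d\n",
                paste(x$input_shape, collapse = " x "), x$in_channels))
  } else {
    cat(sprintf(" | input 1 x %d features\n", x$in_channels))
  }
  s <- arch_summary(x)
  print(as.data.frame(s), row.names = FALSE)
  cat(sprintf("total trainable parameters: %s\n",
              format(sum(s$parameters), big.mark = ",")))
  invisible(x)
}

#' Serialize / read an architecture spec as JSON
#'
#' @param spec an `arch_spec`.
#' @param path file path.
#' @return `path` (write) or an `arch_spec` (read).
#' @export
write_arch_spec <- function(spec, path) {
  stopifnot(inherits(spec, "arch_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_arch_spec
#' @export
read_arch_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  layers <- lapply(j$layers, function(ly) {
    for (f in c("channels_out", "units", "kernel", "stride", "input_lengths")) {
      if (!is.null(ly[[f]])) ly[[f]] <- as.integer(ly[[f]])
    }
    ly
  })
  new_arch_spec(j$name,
                if (is.null(j$input_shape)) NULL else as.integer(j$input_shape),
                as.integer(j$in_channels), layers)
}
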