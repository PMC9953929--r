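# A compact trainable 3D CNN engine. Convolutions are evaluated as an
# im2col gather followed by a BLAS matrix product; the backward pass is the
# transposed product plus a rowsum scatter-add. Max-pooling with
# kernel == stride and ceil rounding is a reshape/permute plus a columnwise
# argmax (padding with -Inf). Everything operates on batches laid out as
# (x, y, z, channel, sample) arrays, or (feature, sample) matrices once
# flattened. This is deliberately minimal: exactly the layer kinds the
# architecture specs use, nothing more.

.nn_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (is.null(.nn_cache[[key]])) .nn_cache[[key]] <- build()
  .nn_cache[[key]]
}

# linear indices into the zero-padded batch array realizing im2col:
# rows = kernel offset (fastest) x input channel, cols = output voxel x sample
im2col_index <- function(sp, C, kernel, N) {
  key <- paste("im2col", paste(sp, collapse = ","), C,
               paste(kernel, collapse = ","), N, sep = "|")
  cache_get(key, function() {
    r <- (kernel - 1L) %/% 2L
    p <- sp + 2L * r
    i <- seq_len(sp[1]); j <- seq_len(sp[2]); l <- seq_len(sp[3])
    base <- outer(outer(i, (j - 1) * p[1], "+"), (l - 1) * p[1] * p[2], "+")
    off <- outer(outer(0:(kernel[1] - 1L), (0:(kernel[2] - 1L)) * p[1], "+"),
                 (0:(kernel[3] - 1L)) * p[1] * p[2], "+")
    per_vox <- prod(p)
    offC <- rep(as.vector(off), C) +
      rep((0:(C - 1)) * per_vox, each = prod(kernel))
    idx1 <- outer(offC, as.vector(base), "+")      # K x P, one sample
    K <- nrow(idx1); P <- ncol(idx1)
    samp <- (seq_len(N) - 1) * per_vox * C
    idx <- as.integer(rep(as.vector(idx1), N) + rep(samp, each = K * P))
    list(idx = idx, K = K, P = P, pad = r, pdim = p)
  })
}

pad_batch <- function(x, r, fill = 0) {
  d <- dim(x); sp <- d[1:3]
  if (all(r == 0L)) return(x)
  pa <- array(fill, c(sp + 2L * r, d[4], d[5]))
  pa[(r[1] + 1):(r[1] + sp[1]), (r[2] + 1):(r[2] + sp[2]),
     (r[3] + 1):(r[3] + sp[3]), , ] <- x
  pa
}

conv3d_forward <- function(x, W, b, kernel, activation) {
  d <- dim(x); sp <- d[1:3]; C <- d[4]; N <- d[5]
  ic <- im2col_index(sp, C, kernel, N)
  pa <- pad_batch(x, ic$pad)
  cols <- matrix(pa[ic$idx], nrow = ic$K)
  z <- W %*% cols + b
  mask <- NULL
  if (identical(activation, "relu")) {
    mask <- z > 0
    z <- z * mask
  }
  C_out <- nrow(W)
  y <- array(aperm(array(z, c(C_out, ic$P, N)), c(2, 1, 3)),
             c(sp, C_out, N))
  list(y = y, cache = list(cols = cols, mask = mask, in_dim = d, ic = ic))
}

conv3d_backward <- function(dy, cache, W, kernel) {
  d <- cache$in_dim; sp <- d[1:3]; C <- d[4]; N <- d[5]
  ic <- cache$ic
  C_out <- nrow(W)
  dz <- matrix(aperm(array(dy, c(ic$P, C_out, N)), c(2, 1, 3)), nrow = C_out)
  if (!is.null(cache$mask)) dz <- dz * cache$mask
  dW <- dz %*% t(cache$cols)
  db <- rowSums(dz)
  # input gradient as a transposed convolution: same-padded convolution of
  # the output gradient with the kernel flipped on every axis (exact adjoint
  # for odd kernels with symmetric zero padding)
  k3 <- prod(kernel)
  Wt <- matrix(0, C, k3 * C_out)
  o <- seq_len(k3)
  for (cout in seq_len(C_out)) {
    for (ch in seq_len(C)) {
      Wt[ch, (k3 + 1L - o) + (cout - 1L) * k3] <-
        W[cout, o + (ch - 1L) * k3]
    }
  }
  dz_arr <- array(aperm(array(dz, c(C_out, ic$P, N)), c(2, 1, 3)),
                  c(sp, C_out, N))
  ic2 <- im2col_index(sp, C_out, kernel, N)
  pa2 <- pad_batch(dz_arr, ic2$pad)
  cols2 <- matrix(pa2[ic2$idx], nrow = ic2$K)
  dxm <- Wt %*% cols2
  dx <- array(aperm(array(dxm, c(C, ic$P, N)), c(2, 1, 3)), c(sp, C, N))
  list(dx = dx, dW = dW, db = db)
}

pool_perm_index <- function(dims7, perm) {
  key <- paste("poolperm", paste(dims7, collapse = ","), sep = "|")
  cache_get(key, function() {
    as.integer(aperm(array(seq_len(prod(dims7)), dims7), perm))
  })
}

maxpool3d_forward <- function(x, stride) {
  d <- dim(x); sp <- d[1:3]; C <- d[4]; N <- d[5]
  o <- (sp + stride - 1L) %/% stride        # ceil rounding
  ps <- o * stride
  pa <- array(-Inf, c(ps, C, N))
  pa[seq_len(sp[1]), seq_len(sp[2]), seq_len(sp[3]), , ] <- x
  dims7 <- c(stride[1], o[1], stride[2], o[2], stride[3], o[3], C * N)
  perm <- c(1L, 3L, 5L, 2L, 4L, 6L, 7L)
  pidx <- pool_perm_index(dims7, perm)
  pv <- pa[pidx]
  k3 <- prod(stride)
  m <- matrix(pv, nrow = k3)
  am <- max.col(t(m), ties.method = "first")
  R <- ncol(m)
  vals <- m[(seq_len(R) - 1L) * k3 + am]
  y <- array(vals, c(o, C, N))
  chosen <- pidx[(seq_len(R) - 1L) * k3 + am]
  list(y = y, cache = list(in_dim = d, pdim = c(ps, C, N), chosen = chosen))
}

maxpool3d_backward <- function(dy, cache) {
  d <- cache$in_dim; sp <- d[1:3]
  dpa <- numeric(prod(cache$pdim))
  dpa[cache$chosen] <- as.vector(dy)
  dpa <- array(dpa, cache$pdim)
  dpa[seq_len(sp[1]), seq_len(sp[2]), seq_len(sp[3]), , , drop = FALSE]
}

dense_forward <- function(x, W, b, activation, training) {
  z <- W %*% x + b
  mask <- NULL
  if (identical(activation, "relu")) {
    mask <- z > 0
    z <- z * mask
  } else if (identical(activation, "softmax")) {
    z <- sweep(z, 2, apply(z, 2, max))
    e <- exp(z)
    z <- sweep(e, 2, colSums(e), "/")
  }
  list(y = z, cache = list(x = x, mask = mask))
}

softmax_probs <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Build a runnable model from an architecture spec
#'
#' Instantiates trainable weights for every conv/dense layer of the spec
#' (He-normal for ReLU layers, Glorot-normal for the softmax head, zero
#' biases). The resulting model maps a batch of volumes (or feature vectors,
#' for fusion specs) to per-class probabilities that sum to one per sample.
#' Its introspected trainable-parameter count equals
#' `sum(count_parameters(spec)$n_params)` exactly.
#'
#' @param spec an `arch_spec`.
#' @param seed optional integer seed for weight initialization (the caller's
#'   RNG state is untouched).
#' @return A `cnn3d_model`.
#' @seealso [predict_proba()], [n_parameters()], [train_model()]
#' @export
build_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "arch_spec"))
  shapes <- forward_shapes(spec)
  with_local_seed(seed, {
    params <- vector("list", length(spec$layers))
    c_in <- spec$in_channels
    fan_in <- if (is.null(spec$input_shape)) spec$in_channels else NA_integer_
    for (i in seq_along(spec$layers)) {
      ly <- spec$layers[[i]]
      if (ly$kind == "conv3d") {
        k <- prod(ly$kernel) * c_in
        sd <- sqrt(2 / k)
        params[[i]] <- list(
          W = matrix(stats::rnorm(ly$channels_out * k, sd = sd),
                     nrow = ly$channels_out),
          b = numeric(ly$channels_out)
        )
        c_in <- ly$channels_out
      } else if (ly$kind == "dense") {
        sd <- if (identical(ly$activation, "softmax")) {
          sqrt(2 / (fan_in + ly$units))
        } else sqrt(2 / fan_in)
        params[[i]] <- list(
          W = matrix(stats::rnorm(ly$units * fan_in, sd = sd),
                     nrow = ly$units),
          b = numeric(ly$units)
        )
        fan_in <- ly$units
      } else if (ly$kind %in% c("flatten", "concat_inputs")) {
        fan_in <- shapes$n_features[i]
      }
    }
    structure(list(spec = spec, params = params), class = "cnn3d_model")
  })
}

#' @export
print.cnn3d_model <- function(x, ...) {
  cat(sprintf("<cnn3d_model> %s | %s trainable parameters\n", x$spec$name,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Introspected trainable parameter count of a built model
#'
#' Counts the actual weight and bias array elements held by the model, as
#' opposed to the closed form of [count_parameters()].
#'
#' @param model a `cnn3d_model`.
#' @return Integer-valued numeric count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "cnn3d_model"))
  sum(vapply(model$params, function(p) {
    if (is.null(p)) 0 else length(p$W) + length(p$b)
  }, numeric(1)))
}

# full forward pass; collect = "probs" | "features" | "caches" | "trace".
# "features" stops at (and returns) the flattened conv features.
nn_forward <- function(model, x, training = FALSE, collect = "probs") {
  layers <- model$spec$layers
  caches <- if (collect == "caches") vector("list", length(layers))
  trace <- if (collect == "trace") vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    res <- switch(ly$kind,
      conv3d = conv3d_forward(x, model$params[[i]]$W, model$params[[i]]$b,
                              ly$kernel, ly$activation),
      maxpool3d = maxpool3d_forward(x, ly$stride),
      flatten = {
        d <- dim(x)
        list(y = matrix(x, ncol = d[length(d)]), cache = list(in_dim = d))
      },
      concat_inputs = list(y = x, cache = NULL),
      dense = dense_forward(x, model$params[[i]]$W, model$params[[i]]$b,
                            ly$activation, training),
      dropout = {
        if (training && ly$rate > 0) {
          mask <- (stats::runif(length(x)) >= ly$rate) / (1 - ly$rate)
          mask <- array(mask, dim(x))
          list(y = x * mask, cache = list(mask = mask))
        } else list(y = x, cache = list(mask = NULL))
      },
      stop(sprintf("model '%s': unknown layer kind '%s'",
                   model$spec$name, ly$kind), call. = FALSE)
    )
    x <- res$y
    if (collect == "caches") caches[[i]] <- res$cache
    if (collect == "trace") trace[[i]] <- dim(x)
    if (collect == "features" && ly$kind == "flatten") return(x)
  }
  switch(collect,
    probs = x,
    features = x,  # dense-only models: final activations
    caches = list(probs = x, caches = caches),
    trace = trace
  )
}

# gradient of weighted cross-entropy + L2 wrt all parameters.
# y_idx in {1, 2}; w_sample per-sample loss weights.
nn_backward <- function(model, fwd, y_idx, w_sample) {
  layers <- model$spec$layers
  n <- length(layers)
  N <- length(y_idx)
  probs <- fwd$probs
  Y <- matrix(0, nrow(probs), N)
  Y[cbind(y_idx, seq_len(N))] <- 1
  dy <- (probs - Y) * rep(w_sample / N, each = nrow(probs))
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    ly <- layers[[i]]
    cache <- fwd$caches[[i]]
    if (ly$kind == "dense") {
      dz <- dy
      if (!is.null(cache$mask)) dz <- dz * cache$mask
      dW <- dz %*% t(cache$x)
      if (identical(ly$regularization, "l2") && ly$l2 > 0) {
        dW <- dW + 2 * ly$l2 * model$params[[i]]$W
      }
      grads[[i]] <- list(dW = dW, db = rowSums(dz))
      dy <- crossprod(model$params[[i]]$W, dz)
    } else if (ly$kind == "dropout") {
      if (!is.null(cache$mask)) dy <- dy * cache$mask
    } else if (ly$kind == "flatten") {
      dy <- array(dy, cache$in_dim)
    } else if (ly$kind == "concat_inputs") {
      # input gradient not needed (features are precomputed and frozen)
    } else if (ly$kind == "maxpool3d") {
      dy <- maxpool3d_backward(dy, cache)
    } else if (ly$kind == "conv3d") {
      bk <- conv3d_backward(dy, cache, model$params[[i]]$W, ly$kernel)
      dW <- bk$dW
      if (identical(ly$regularization, "l2") && ly$l2 > 0) {
        dW <- dW + 2 * ly$l2 * model$params[[i]]$W
      }
      grads[[i]] <- list(dW = dW, db = bk$db)
      dy <- bk$dx
    }
  }
  grads
}

# weighted cross-entropy loss (data term + L2 penalty)
nn_loss <- function(model, probs, y_idx, w_sample) {
  N <- length(y_idx)
  p <- pmax(probs[cbind(y_idx, seq_len(N))], 1e-12)
  data_loss <- sum(w_sample * (-log(p))) / N
  reg <- 0
  for (i in seq_along(model$spec$layers)) {
    ly <- model$spec$layers[[i]]
    if (!is.null(model$params[[i]]) && identical(ly$regularization, "l2") &&
        ly$l2 > 0) {
      reg <- reg + ly$l2 * sum(model$params[[i]]$W^2)
    }
  }
  data_loss + reg
}

adam_init <- function(model) {
  list(t = 0, m = lapply(model$params, function(p) {
    if (is.null(p)) NULL else list(W = p$W * 0, b = p$b * 0)
  }), v = lapply(model$params, function(p) {
    if (is.null(p)) NULL else list(W = p$W * 0, b = p$b * 0)
  }))
}

adam_step <- function(model, state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(model$params)) {
    if (is.null(grads[[i]])) next
    for (f in c("W", "b")) {
      g <- grads[[i]][[paste0("d", f)]]
      state$m[[i]][[f]] <- beta1 * state$m[[i]][[f]] + (1 - beta1) * g
      state$v[[i]][[f]] <- beta2 * state$v[[i]][[f]] + (1 - beta2) * g * g
      mhat <- state$m[[i]][[f]] / bc1
      vhat <- state$v[[i]][[f]] / bc2
      model$params[[i]][[f]] <- model$params[[i]][[f]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(model = model, state = state)
}

#' Class probabilities from a built model
#'
#' Runs the model in evaluation mode (dropout off).
#'
#' @param model a `cnn3d_model`.
#' @param x a batch: `(x, y, z, channel, sample)` array for conv models (a
#'   bare 3D array or [vol3d] is treated as one single-channel sample), or a
#'   `(feature, sample)` matrix for fusion models.
#' @return Matrix of `n_samples x 2` probabilities, columns `AD` and `CN`.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "cnn3d_model"))
  x <- as_nn_batch(x, model$spec)
  probs <- nn_forward(model, x, training = FALSE, collect = "probs")
  out <- t(probs)
  colnames(out) <- c("AD", "CN")
  out
}

# flattened conv features (input to the fusion stage), eval mode
conv_features <- function(model, x) {
  x <- as_nn_batch(x, model$spec)
  nn_forward(model, x, training = FALSE, collect = "features")
}

# coerce vol3d / 3D array / list of them to the batch layout the spec expects
as_nn_batch <- function(x, spec) {
  if (inherits(x, "vol3d")) x <- x$data
  if (is.list(x)) {
    arrs <- lapply(x, function(v) if (inherits(v, "vol3d")) v$data else v)
    d <- dim(arrs[[1]])
    x <- array(unlist(arrs, use.names = FALSE), c(d, 1L, length(arrs)))
    return(x)
  }
  if (is.null(spec$input_shape)) {
    if (is.matrix(x)) return(x)
    return(matrix(x, ncol = 1))
  }
  d <- dim(x)
  if (length(d) == 3L) x <- array(x, c(d, 1L, 1L))
  else if (length(d) == 4L) x <- array(x, c(d[1:3], 1L, d[4]))
  x
}
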