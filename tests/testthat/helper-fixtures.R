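# shared fixtures: everything is generated in code at test time

rand_vol <- function(shape = c(8, 10, 8), seed = 1, voxel = 1.5) {
  set.seed(seed)
  vol3d(array(runif(prod(shape)), shape), voxel_size_mm = voxel)
}

# a tiny architecture that exercises every layer kind but trains in seconds
tiny_subnet_spec <- function(patch_shape = c(16, 16, 16)) {
  patch_subnet_spec(patch_shape, channels = c(2L, 4L, 8L, 16L),
                    dense_units = c(32L, 16L, 2L))
}

# brute-force dense 3D convolution with reflected boundary (oracle for
# smooth_gaussian); k is an odd-length 1D kernel applied separably
dense_separable_conv <- function(arr, w) {
  r <- (length(w) - 1) / 2
  d <- dim(arr)
  refl <- function(i, n) {
    m <- (i - 1) %% (2 * n)
    ifelse(m < n, m + 1, 2 * n - m)
  }
  for (axis in 1:3) {
    out <- array(0, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
      acc <- 0
      for (t in -r:r) {
        idx <- c(i, j, l)
        idx[axis] <- refl(idx[axis] + t, d[axis])
        acc <- acc + w[t + r + 1] * arr[idx[1], idx[2], idx[3]]
      }
      out[i, j, l] <- acc
    }
    arr <- out
  }
  arr
}

# labelled random-feature dataset for head-only training tests
toy_feature_dataset <- function(n = 20, f = 6, sep = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c("AD", "CN"), length.out = n)
  x <- matrix(rnorm(f * n), f, n)
  x[1, y == "AD"] <- x[1, y == "AD"] + sep
  list(x = x, y = y, ids = sprintf("s%02d", seq_len(n)))
}
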