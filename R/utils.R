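# run code under a temporary RNG state, restoring the caller's stream
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a child seed from a parent seed and stream indices, < 2^31
derive_seed <- function(seed, ...) {
  ix <- c(seed, ...)
  s <- 0
  for (v in ix) s <- (s * 69069 + as.numeric(v) + 1) %% 2147483629
  as.integer(s)
}

# round-half-down: 33.5 -> 33, 33.6 -> 34
round_half_down <- function(x) ceiling(x - 0.5)

check_len3 <- function(x, what) {
  x <- as.integer(x)
  if (length(x) != 3L || anyNA(x)) {
    stop(sprintf("`%s` must be an integer triple", what), call. = FALSE)
  }
  x
}

axis_names <- c("x", "y", "z")
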