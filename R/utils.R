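# Internal helpers shared across modules.

# Run `expr` under a locally seeded RNG without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Reflect-pad a matrix by `k` pixels on every side.
reflectPad <- function(x, k) {
  M <- nrow(x); N <- ncol(x)
  ri <- c(rev(seq_len(min(k, M))), seq_len(M), M + 1 - rev(seq_len(min(k, M))))
  # for k >= M fall back to clamping (tiny images)
  if (k > M) ri <- pmin(pmax(c(rep(1, k - M), ri, rep(M, k - M)), 1), M)
  ci <- c(rev(seq_len(min(k, N))), seq_len(N), N + 1 - rev(seq_len(min(k, N))))
  if (k > N) ci <- pmin(pmax(c(rep(1, k - N), ci, rep(N, k - N)), 1), N)
  x[ri, ci, drop = FALSE]
}

# Sum over a (2k+1) x (2k+1) window via shifted slices of the padded matrix.
boxSum <- function(x, k) {
  p <- reflectPad(x, k)
  M <- nrow(x); N <- ncol(x)
  out <- matrix(0, M, N)
  for (di in -k:k) for (dj in -k:k)
    out <- out + p[(k + 1 + di):(k + M + di), (k + 1 + dj):(k + N + dj)]
  out
}

asGrayMatrix <- function(image) {
  if (is(image, "GrayImage")) image@.Data else {
    stopifnot(is.matrix(image), is.numeric(image))
    image
  }
}

stopIfNot01 <- function(x, what) {
  if (any(x < 0 | x > 1)) stop(what, " must lie in [0, 1]", call. = FALSE)
}
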