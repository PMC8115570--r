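# Internal numerical helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All exported stochastic operations
# funnel randomness through this so that they are pure functions of
# (arguments, seed).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# 2-D convolution, "same" output size, zero padding, via FFT.
conv2_same <- function(x, k) {
  stopifnot(is.matrix(x), is.matrix(k))
  kh <- nrow(k); kw <- ncol(k)
  ph <- nrow(x) + kh - 1L
  pw <- ncol(x) + kw - 1L
  X <- matrix(0, ph, pw)
  X[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  K <- matrix(0, ph, pw)
  K[seq_len(kh), seq_len(kw)] <- k
  full <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / (ph * pw)
  r0 <- (kh - 1L) %/% 2L
  c0 <- (kw - 1L) %/% 2L
  full[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x)), drop = FALSE]
}

# Convolve one image with several kernels, reusing the padded image FFT.
conv2_bank <- function(x, kernels) {
  kh <- max(vapply(kernels, nrow, 1L))
  kw <- max(vapply(kernels, ncol, 1L))
  ph <- nrow(x) + kh - 1L
  pw <- ncol(x) + kw - 1L
  X <- matrix(0, ph, pw)
  X[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  FX <- stats::fft(X)
  lapply(kernels, function(k) {
    K <- matrix(0, ph, pw)
    K[seq_len(nrow(k)), seq_len(ncol(k))] <- k
    full <- Re(stats::fft(FX * stats::fft(K), inverse = TRUE)) / (ph * pw)
    r0 <- (nrow(k) - 1L) %/% 2L
    c0 <- (ncol(k) - 1L) %/% 2L
    full[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x)), drop = FALSE]
  })
}

# Row-weight matrix for exact area (block-average) interpolation from
# n_in to n_out bins: W[i, j] = fractional overlap of output bin i with
# input bin j, rows summing to one.
area_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1L
    j1 <- min(ceiling(hi), n_in)
    for (j in j0:j1) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[i, j] <- ov
    }
  }
  W / scale
}

# Small per-session cache for area weight matrices (they only depend on
# the in/out sizes and are reused for every frame and mask).
.gazevam_cache <- new.env(parent = emptyenv())

area_weights_cached <- function(n_in, n_out) {
  key <- paste0("aw_", n_in, "_", n_out)
  w <- .gazevam_cache[[key]]
  if (is.null(w)) {
    w <- area_weights(n_in, n_out)
    .gazevam_cache[[key]] <- w
  }
  w
}

# Area-interpolated resize of a matrix to h x w.
resize_matrix <- function(x, h, w) {
  area_weights_cached(nrow(x), h) %*% x %*% t(area_weights_cached(ncol(x), w))
}

# Rec. 601 luma from an H x W x 3 array (or pass-through for matrices).
rgb_to_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  stopifnot(length(dim(frame)) == 3L)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

# Min-max scale a matrix to [0, 1]; a constant matrix maps to all zeros.
minmax01 <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("non-finite values in channel")
  d <- rng[2] - rng[1]
  if (d <= 0) return(matrix(0, nrow(x), ncol(x)))
  (x - rng[1]) / d
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_frame <- function(x) {
  (is.matrix(x) || (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L)) &&
    is.numeric(x)
}

frame_dims <- function(frame) dim(frame)[1:2]
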