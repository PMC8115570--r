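# Shared fixtures, built once per test file and memoised.

.fixtures <- new.env(parent = emptyenv())

tiny_manifest <- function(n_segments = 2, frames_per_segment = 25) {
  scene_manifest(n_segments, frames_per_segment, fps = 10,
                 screen_size = c(135, 240))
}

tiny_stimulus <- function() {
  if (is.null(.fixtures$stim))
    .fixtures$stim <- generate_stimulus(tiny_manifest(), seed = 42)
  .fixtures$stim
}

tiny_prep <- function() {
  if (is.null(.fixtures$prep))
    .fixtures$prep <- preprocess_stimulus(tiny_stimulus())
  .fixtures$prep
}

tiny_stack <- function() {
  if (is.null(.fixtures$stack)) {
    pp <- tiny_prep()
    .fixtures$stack <- extract_feature_stack(
      pp$frames[[2]], pp$side[2], prev_frame = pp$frames[[1]],
      masks = list(face = pp$masks$face[[2]], person = pp$masks$person[[2]]))
  }
  .fixtures$stack
}

# labelled pixel vectors with a few informative columns, for selection and
# network tests
toy_vectors <- function(n = 300, p = 10, seed = 7) {
  set.seed(seed)
  x <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- as.integer(x[, 1] + x[, 2] > 1)
  list(x = x, y = y)
}
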