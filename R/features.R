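#' Canonical per-pixel feature channel registry
#'
#' The 28 channels, in frozen order: 12 steerable-pyramid band-pass
#' subbands (4 scales x 3 orientations) plus the low-pass residual (13);
#' four conspicuity channels (colour, intensity, orientation, skin); the
#' three RGB channels; three semantic channels (horizon, face, people);
#' two geometric distances (to frame centre, to scene-half centre) and the
#' two binary scene flags (biological, geometric); and one motion channel.
#' Every feature stack is validated against this registry.
#'
#' @return Character vector of 28 channel names.
#' @export
vam_channels <- function() {
  c(paste0("steer_s", rep(1:4, each = 3), "_o", rep(c(0, 60, 120), 4)),
    "steer_lowpass",
    "consp_color", "consp_intensity", "consp_orientation", "consp_skin",
    "red", "green", "blue",
    "horizon", "face", "people",
    "dist_frame_center", "dist_scene_center",
    "flag_biological", "flag_geometric",
    "motion")
}

# ---------------------------------------------------------------------------
# Steerable pyramid (frequency-domain, Simoncelli-style log-raised-cosine
# radial bands x cos^2 angular masks).

steerable_masks <- function(h, w, n_scales = 4, n_orient = 3) {
  key <- sprintf("steer_%d_%d_%d_%d", h, w, n_scales, n_orient)
  m <- .gazevam_cache[[key]]
  if (!is.null(m)) return(m)
  fy <- (seq_len(h) - 1) / h
  fy[fy >= 0.5] <- fy[fy >= 0.5] - 1
  fx <- (seq_len(w) - 1) / w
  fx[fx >= 0.5] <- fx[fx >= 0.5] - 1
  FY <- matrix(fy, h, w)
  FX <- matrix(fx, h, w, byrow = TRUE)
  r <- sqrt(FX^2 + FY^2)
  theta <- atan2(FY, FX)
  r[1, 1] <- 1e-12

  radial <- lapply(seq_len(n_scales), function(s) {
    rs <- 0.25 / 2^(s - 1)
    x <- log2(r / rs)
    b <- matrix(0, h, w)
    sel <- abs(x) <= 1
    b[sel] <- cos(pi / 2 * x[sel])
    b
  })
  angles <- (seq_len(n_orient) - 1) * pi / n_orient
  angular <- lapply(angles, function(a) cos(theta - a)^2)

  bands <- list()
  for (s in seq_len(n_scales))
    for (o in seq_len(n_orient))
      bands[[length(bands) + 1L]] <- radial[[s]] * angular[[o]]
  # low-pass residual below the lowest band centre
  r_lo <- 0.25 / 2^(n_scales - 1) / 2
  x <- clamp(log2(r / r_lo), 0, 1)
  lowpass <- cos(pi / 2 * x)
  m <- list(bands = bands, lowpass = lowpass)
  .gazevam_cache[[key]] <- m
  m
}

#' Steerable-pyramid feature channels
#'
#' Decomposes the luma of a frame into 4 scales x 3 orientations of
#' band-pass subbands (computed in the frequency domain with
#' log-raised-cosine radial windows and cos^2 angular windows, returned as
#' absolute responses at full frame resolution) plus the low-pass
#' residual: 13 channels, each min-max scaled to `[0, 1]`.
#'
#' @param frame matrix or H x W x 3 array in `[0, 1]`.
#' @param scale min-max scale each channel to `[0, 1]` (the default);
#'   `FALSE` returns raw absolute subband responses, useful for comparing
#'   energies across orientations.
#' @return H x W x 13 array, dimnames on the channel axis.
#' @export
steerable_channels <- function(frame, scale = TRUE) {
  g <- rgb_to_gray(frame)
  h <- nrow(g); w <- ncol(g)
  msk <- steerable_masks(h, w)
  G <- stats::fft(g)
  n <- h * w
  sc <- if (scale) minmax01 else identity
  out <- array(0, c(h, w, 13L))
  for (i in seq_along(msk$bands)) {
    resp <- Re(stats::fft(G * msk$bands[[i]], inverse = TRUE)) / n
    out[, , i] <- sc(abs(resp))
  }
  low <- Re(stats::fft(G * msk$lowpass, inverse = TRUE)) / n
  out[, , 13L] <- sc(abs(low))
  dimnames(out) <- list(NULL, NULL, vam_channels()[1:13])
  out
}

# ---------------------------------------------------------------------------
# Itti-style conspicuity channels.

gaussian_pyramid <- function(x, n_levels) {
  pyr <- vector("list", n_levels)
  pyr[[1]] <- x
  for (k in 2:n_levels) {
    prev <- pyr[[k - 1]]
    pyr[[k]] <- resize_matrix(prev, max(nrow(prev) %/% 2L, 4L),
                              max(ncol(prev) %/% 2L, 4L))
  }
  pyr
}

# Sum of |center - surround| across-scale differences, at full resolution.
center_surround <- function(x, centers = c(2, 3), delta = 2) {
  n_levels <- max(centers) + delta
  pyr <- gaussian_pyramid(x, n_levels)
  h <- nrow(x); w <- ncol(x)
  acc <- matrix(0, h, w)
  for (cl in centers) {
    sl <- cl + delta
    s_up <- resize_matrix(pyr[[sl]], nrow(pyr[[cl]]), ncol(pyr[[cl]]))
    d <- abs(pyr[[cl]] - s_up)
    acc <- acc + resize_matrix(d, h, w)
  }
  acc
}

gabor_kernel <- function(theta, sigma = 2.5, lambda = 6, size = 15) {
  r <- (size - 1) / 2
  xs <- matrix(seq(-r, r), size, size, byrow = TRUE)
  ys <- matrix(seq(-r, r), size, size)
  xr <- xs * cos(theta) + ys * sin(theta)
  yr <- -xs * sin(theta) + ys * cos(theta)
  k <- exp(-(xr^2 + 0.25 * yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / lambda)
  k - mean(k)  # zero DC response
}

gabor_bank <- function() {
  key <- "gabor_bank"
  b <- .gazevam_cache[[key]]
  if (is.null(b)) {
    b <- lapply(c(0, pi / 4, pi / 2, 3 * pi / 4), gabor_kernel)
    .gazevam_cache[[key]] <- b
  }
  b
}

#' Conspicuity feature channels (colour, intensity, orientation, skin)
#'
#' Itti-style centre-surround conspicuity maps: intensity uses
#' across-scale differences of a Gaussian pyramid of the luma; colour uses
#' the same operator on red-green and blue-yellow opponency maps;
#' orientation is the pooled energy of a four-orientation Gabor bank on
#' the mean-removed luma; skin is a chrominance likelihood (Gaussian on
#' the YCbCr skin locus).  Each channel is min-max scaled to `[0, 1]`
#' (skin uses its analytic `[0, 1]` range).
#'
#' @param frame H x W x 3 array in `[0, 1]`.
#' @return H x W x 4 array.
#' @export
conspicuity_channels <- function(frame) {
  stopifnot(length(dim(frame)) == 3L)
  r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3]
  intens <- (r + g + b) / 3
  rg <- r - g
  by <- b - (r + g) / 2

  consp_int <- minmax01(center_surround(intens))
  consp_col <- minmax01(center_surround(rg) + center_surround(by))

  gm <- intens - mean(intens)
  resp <- conv2_bank(gm, gabor_bank())
  energy <- Reduce(`+`, lapply(resp, function(x) x^2))
  consp_ori <- minmax01(energy)

  cb <- 0.5 - 0.168736 * r - 0.331264 * g + 0.5 * b
  cr <- 0.5 + 0.5 * r - 0.418688 * g - 0.081312 * b
  skin <- exp(-((cb - 0.40)^2 + (cr - 0.60)^2) / (2 * 0.07^2))

  out <- array(0, c(dim(frame)[1:2], 4L))
  out[, , 1] <- consp_col
  out[, , 2] <- consp_int
  out[, , 3] <- consp_ori
  out[, , 4] <- skin
  dimnames(out) <- list(NULL, NULL, vam_channels()[14:17])
  out
}

#' RGB colour channels
#'
#' @param frame H x W x 3 array in `[0, 1]`.
#' @return The three channels as an H x W x 3 array (exact copies).
#' @export
color_channels <- function(frame) {
  stopifnot(length(dim(frame)) == 3L)
  out <- frame
  dimnames(out) <- list(NULL, NULL, vam_channels()[18:20])
  out
}

#' Default semantic detectors
#'
#' Pluggable stand-ins used when no oracle masks are available: the
#' horizon scorer rates each row by its vertical-gradient (horizontal
#' edge) energy, normalised to `[0, 1]` and replicated across columns;
#' the face scorer is a smoothed skin-chrominance likelihood; the people
#' scorer widens the face scorer with a coarser smoothing.  These are
#' deliberately simple, deterministic baselines behind the detector
#' interface; synthetic runs use exact oracle masks instead.
#'
#' @return Named list of functions `frame -> H x W score matrix in [0,1]`.
#' @export
default_detectors <- function() {
  skin_map <- function(frame) {
    r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3]
    cb <- 0.5 - 0.168736 * r - 0.331264 * g + 0.5 * b
    cr <- 0.5 + 0.5 * r - 0.418688 * g - 0.081312 * b
    exp(-((cb - 0.40)^2 + (cr - 0.60)^2) / (2 * 0.07^2))
  }
  list(
    horizon = function(frame) {
      gy <- rgb_to_gray(frame)
      h <- nrow(gy)
      grad <- rbind(abs(gy[-1, , drop = FALSE] - gy[-h, , drop = FALSE]), 0)
      score <- rowMeans(grad)
      if (max(score) > 0) score <- score / max(score)
      matrix(score, h, ncol(gy))
    },
    face = function(frame) {
      s <- conv2_same(skin_map(frame), gaussian_kernel(9, 2))
      clamp(s, 0, 1)
    },
    people = function(frame) {
      s <- conv2_same(skin_map(frame), gaussian_kernel(15, 4))
      clamp(s / max(max(s), 1e-12), 0, 1)
    }
  )
}

#' Semantic feature channels (horizon, face, people)
#'
#' When oracle masks are supplied (synthetic stimuli), the face and people
#' channels are exact copies of the masks, which keeps downstream tests
#' deterministic.  Otherwise the registered detector for each channel is
#' applied; a channel with neither oracle nor detector is an error.
#'
#' @param frame H x W x 3 array.
#' @param masks optional list with logical matrices `face` and `person`
#'   (from the synthetic generator).
#' @param detectors named list of detector functions (see
#'   [default_detectors()]); set to `NULL` to forbid detector fallback.
#' @return H x W x 3 array (horizon, face, people), values in `[0, 1]`.
#' @export
semantic_channels <- function(frame, masks = NULL,
                              detectors = default_detectors()) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  get_chan <- function(name, oracle) {
    if (!is.null(oracle)) return(oracle * 1)
    det <- detectors[[name]]
    if (is.null(det))
      stop("no detector registered for channel '", name,
           "' and no oracle mask supplied")
    m <- det(frame)
    if (!all(dim(m) == c(h, w)))
      stop("detector '", name, "' returned a map of the wrong shape")
    clamp(m, 0, 1)
  }
  out <- array(0, c(h, w, 3L))
  out[, , 1] <- get_chan("horizon", NULL)
  out[, , 2] <- get_chan("face", masks$face)
  out[, , 3] <- get_chan("people", masks$person)
  dimnames(out) <- list(NULL, NULL, vam_channels()[21:23])
  out
}

#' Geometric feature channels
#'
#' Four channels driven by frame geometry and the manifest: the Euclidean
#' distance from each pixel to the frame's centre pixel and to the centre
#' pixel of its scene (the screen half containing it), both normalised by
#' the largest attainable distance so the corners score 1; and the two
#' complementary binary flags marking the biological and geometric halves.
#'
#' @param dim working grid `c(rows, cols)`.
#' @param side `"left"` or `"right"`: the half showing biological motion
#'   for this frame.
#' @return `dim[1] x dim[2] x 4` array.
#' @export
geometry_channels <- function(dim = c(200, 350), side = c("left", "right")) {
  side <- match.arg(side)
  h <- dim[1]; w <- dim[2]
  key <- sprintf("geom_%d_%d", h, w)
  base <- .gazevam_cache[[key]]
  if (is.null(base)) {
    R0 <- matrix(0:(h - 1), h, w)
    C0 <- matrix(0:(w - 1), h, w, byrow = TRUE)
    ctr <- c(h %/% 2L, w %/% 2L)
    d_frame <- sqrt((R0 - ctr[1])^2 + (C0 - ctr[2])^2)
    d_frame <- d_frame / max(d_frame)
    mid <- w %/% 2L
    left <- C0 < mid
    # centre pixel of each half
    lc <- c(h %/% 2L, mid %/% 2L)
    rc <- c(h %/% 2L, mid + (w - mid) %/% 2L)
    d_left <- sqrt((R0 - lc[1])^2 + (C0 - lc[2])^2)
    d_left <- d_left / max(d_left[left])
    d_right <- sqrt((R0 - rc[1])^2 + (C0 - rc[2])^2)
    d_right <- d_right / max(d_right[!left])
    d_scene <- ifelse(left, d_left, d_right)
    base <- list(d_frame = d_frame, d_scene = pmin(d_scene, 1), left = left)
    .gazevam_cache[[key]] <- base
  }
  bio <- if (side == "left") base$left else !base$left
  out <- array(0, c(h, w, 4L))
  out[, , 1] <- base$d_frame
  out[, , 2] <- base$d_scene
  out[, , 3] <- bio * 1
  out[, , 4] <- (!bio) * 1
  dimnames(out) <- list(NULL, NULL, vam_channels()[24:27])
  out
}

#' Motion feature channel
#'
#' Per-pixel motion magnitude between the previous and current frame,
#' using the same estimator as the frame-aggregation rule.  The first
#' frame of a sequence (no predecessor) gets an all-zero map by
#' convention.
#'
#' @param prev_frame previous frame or `NULL`.
#' @param frame current frame.
#' @inheritParams motion_map
#' @return H x W x 1 array in `[0, 1]`.
#' @export
motion_channel <- function(prev_frame, frame,
                           estimator = c("difference", "flow"),
                           max_displacement = 10) {
  d <- dim(frame)[1:2]
  m <- if (is.null(prev_frame)) matrix(0, d[1], d[2])
       else motion_map(prev_frame, frame, estimator, max_displacement)
  out <- array(m, c(d, 1L))
  dimnames(out) <- list(NULL, NULL, vam_channels()[28])
  out
}

#' Extract the full 28-channel feature stack for one frame
#'
#' Concatenates all channel families in the canonical registry order and
#' validates the result (28 channels, all finite, flags binary).
#'
#' @param frame preprocessed H x W x 3 frame.
#' @param side biological side for this frame (`"left"`/`"right"`).
#' @param prev_frame previous preprocessed frame or `NULL` (first frame).
#' @param masks optional oracle masks (`face`, `person`) for the semantic
#'   channels.
#' @param detectors detector list for semantic channels without oracles.
#' @param estimator,max_displacement motion estimator settings.
#' @return H x W x 28 array with channel dimnames, class `feature_stack`.
#' @export
extract_feature_stack <- function(frame, side, prev_frame = NULL,
                                  masks = NULL,
                                  detectors = default_detectors(),
                                  estimator = c("difference", "flow"),
                                  max_displacement = 10) {
  stopifnot(length(dim(frame)) == 3L)
  d <- dim(frame)[1:2]
  parts <- list(
    steerable = steerable_channels(frame),
    conspicuity = conspicuity_channels(frame),
    color = color_channels(frame),
    semantic = semantic_channels(frame, masks, detectors),
    geometry = geometry_channels(d, side),
    motion = motion_channel(prev_frame, frame, estimator, max_displacement)
  )
  out <- array(0, c(d, 28L))
  at <- 0L
  for (nm in names(parts)) {
    p <- parts[[nm]]
    if (!all(is.finite(p)))
      stop("non-finite values in feature family '", nm, "'")
    k <- dim(p)[3]
    out[, , at + seq_len(k)] <- p
    at <- at + k
  }
  stopifnot(at == 28L)
  dimnames(out) <- list(NULL, NULL, vam_channels())
  class(out) <- c("feature_stack", class(out))
  out
}

#' Average feature stacks over an aggregated frame set
#'
#' @param stacks list of same-shape feature stacks (the member frames of
#'   one frame set).
#' @return The pixelwise mean stack.
#' @export
frameset_features <- function(stacks) {
  if (length(stacks) < 1) stop("need at least one member stack")
  out <- Reduce(`+`, stacks) / length(stacks)
  dimnames(out) <- dimnames(stacks[[1]])
  class(out) <- c("feature_stack", class(out))
  out
}

#' Assemble labelled training vectors from a mean feature stack
#'
#' One feature vector per selected coordinate, label copied from the
#' coordinate sample.
#'
#' @param stack H x W x 28 feature stack (typically a frame-set mean).
#' @param coords a [select_coordinates()] result.
#' @return List of class `pixel_vectors` with `x` (matrix, one row per
#'   coordinate, 28 named columns) and `y` (0/1 integer labels).
#' @export
build_training_vectors <- function(stack, coords) {
  d <- dim(stack)
  if (any(coords$row < 0 | coords$row >= d[1] |
          coords$col < 0 | coords$col >= d[2]))
    stop("coordinate outside frame bounds")
  n <- nrow(coords)
  x <- matrix(0, n, d[3])
  for (ch in seq_len(d[3]))
    x[, ch] <- stack[cbind(coords$row + 1L, coords$col + 1L, ch)]
  colnames(x) <- dimnames(stack)[[3]]
  structure(list(x = x, y = as.integer(coords$class)),
            class = "pixel_vectors")
}
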