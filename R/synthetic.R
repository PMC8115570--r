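#' Group-conditional gaze phenotype parameters
#'
#' Parameterises the synthetic gaze generator.  Each emitted gaze sample
#' lands on the geometric half of the screen with probability `p_geometric`
#' (the side-preference contrast that separates the case and control
#' phenotypes in preferential-looking paradigms); within a half it is drawn
#' from a mixture of a Gaussian around the face centroid (biological half
#' only), a Gaussian around the half's centre (centre bias), and uniform
#' noise over the half.
#'
#' @param p_geometric probability that a sample lands on the geometric half.
#' @param center_bias_sigma standard deviation, in native screen pixels, of
#'   the centre-bias Gaussian.
#' @param face_attraction probability that a biological-half sample targets
#'   the face oracle mask centroid rather than the half centre.
#' @param dropout_rate fraction of ticks emitted as invalid (validity 0),
#'   emulating tracker signal loss.
#' @param noise_weight probability that a fixation is replaced by a uniform
#'   draw over its chosen half.
#' @param fixation_hz rate at which new fixation targets are drawn; between
#'   draws the gaze dwells on the current target (plus tracker jitter), the
#'   basic temporal coherence of real gaze.
#' @param jitter_sigma per-tick tracker noise around the fixation target,
#'   native screen pixels.
#' @param seed optional integer; convenience default seed carried with the
#'   parameters.
#' @return An object of class `phenotype_params`.
#' @examples
#' case <- phenotype_params(p_geometric = 0.8)
#' control <- phenotype_params(p_geometric = 0.2)
#' @export
phenotype_params <- function(p_geometric = 0.5, center_bias_sigma = 100,
                             face_attraction = 0.6, dropout_rate = 0.05,
                             noise_weight = 0.02, fixation_hz = 3,
                             jitter_sigma = 3, seed = NULL) {
  probs <- c(p_geometric = p_geometric, face_attraction = face_attraction,
             dropout_rate = dropout_rate, noise_weight = noise_weight)
  if (any(probs < 0 | probs > 1))
    stop("phenotype probabilities must lie in [0, 1]")
  if (center_bias_sigma <= 0) stop("center_bias_sigma must be positive")
  if (fixation_hz <= 0) stop("fixation_hz must be positive")
  if (jitter_sigma < 0) stop("jitter_sigma must be non-negative")
  structure(list(p_geometric = p_geometric,
                 center_bias_sigma = center_bias_sigma,
                 face_attraction = face_attraction,
                 dropout_rate = dropout_rate,
                 noise_weight = noise_weight,
                 fixation_hz = fixation_hz,
                 jitter_sigma = jitter_sigma,
                 seed = seed),
            class = "phenotype_params")
}

#' Generate a synthetic two-panel stimulus video
#'
#' Renders a deterministic (given `seed`) stand-in for the clinical
#' stimulus: on the biological half a cluster of textured moving ellipses
#' ("people") each carrying a high-contrast skin-toned face disc, on the
#' geometric half a rotating fractal-like radial interference pattern.  A
#' black border surrounds the content so that border cropping is exercised
#' downstream.  Alongside the frames, per-frame binary oracle masks are
#' produced for faces, people, and the biological and geometric screen
#' halves; the oracle masks stand in for the semantic detectors when no
#' real detector is available.
#'
#' Frames are quantised to 8-bit depth so that they round-trip losslessly
#' through PNG fixtures.
#'
#' @param manifest a [scene_manifest()].
#' @param seed integer seed; the generator is a pure function of
#'   `(manifest, seed)`.
#' @param border_frac fraction of each screen dimension taken by the black
#'   border on each side.
#' @return An object of class `stimulus`: list with `frames` (list of
#'   H x W x 3 arrays in `[0,1]`), `masks` (lists `face`, `person`,
#'   `biological`, `geometric` of logical matrices, one per frame) and the
#'   `manifest`.
#' @examples
#' m <- scene_manifest(n_segments = 2, frames_per_segment = 25, fps = 10,
#'                     screen_size = c(135, 240))
#' stim <- generate_stimulus(m, seed = 1)
#' length(stim$frames)
#' @export
generate_stimulus <- function(manifest, seed = 1, border_frac = 0.08) {
  if (!inherits(manifest, "scene_manifest"))
    stop("invalid manifest: expected a scene_manifest")
  validate_manifest(manifest)
  if (border_frac < 0 || border_frac >= 0.4)
    stop("border_frac must lie in [0, 0.4)")
  H <- manifest$screen_size[1]
  W <- manifest$screen_size[2]
  fps <- manifest$fps
  bh <- round(border_frac * H)
  bw <- round(border_frac * W)
  rows <- (bh + 1L):(H - bh)
  mid <- W %/% 2L
  nf <- n_frames(manifest)
  segs <- manifest$segments

  left_mask <- matrix(FALSE, H, W); left_mask[, seq_len(mid)] <- TRUE
  right_mask <- !left_mask

  with_seed(seed, {
    # per-segment randomized content parameters
    seg_par <- lapply(seq_len(nrow(segs)), function(i) {
      list(
        actor_phase = stats::runif(3, 0, 2 * pi),
        actor_freq = stats::runif(3, 0.25, 0.6),
        actor_col = matrix(stats::runif(9, 0.3, 0.9), 3, 3),
        fract_lobes = sample(3:6, 1),
        fract_omega = stats::runif(1, 0.6, 1.6),
        fract_kr = stats::runif(1, 0.10, 0.22),
        # sub-videos are distinct clips: alternate dark/bright palettes so
        # consecutive segments differ as much as real scene cuts do
        bg = (if (i %% 2 == 1) 0.06 else 0.70) + stats::runif(1, 0, 0.05),
        warm = i %% 2 == 0
      )
    })

    frames <- vector("list", nf)
    face_masks <- vector("list", nf)
    person_masks <- vector("list", nf)
    bio_masks <- vector("list", nf)
    geo_masks <- vector("list", nf)

    for (si in seq_len(nrow(segs))) {
      p <- seg_par[[si]]
      bio_left <- segs$biological_side[si] == "left"
      bio_cols <- if (bio_left) (bw + 1L):mid else (mid + 1L):(W - bw)
      geo_cols <- if (bio_left) (mid + 1L):(W - bw) else (bw + 1L):mid
      RR_b <- matrix(rows, length(rows), length(bio_cols))
      CC_b <- matrix(bio_cols, length(rows), length(bio_cols), byrow = TRUE)
      RR_g <- matrix(rows, length(rows), length(geo_cols))
      CC_g <- matrix(geo_cols, length(rows), length(geo_cols), byrow = TRUE)
      gr0 <- mean(rows); gc0 <- mean(geo_cols)
      rad <- sqrt((RR_g - gr0)^2 + (CC_g - gc0)^2)
      ang <- atan2(RR_g - gr0, CC_g - gc0)
      ell_rh <- 0.16 * length(rows)
      ell_rw <- 0.10 * length(bio_cols)
      face_r <- 0.35 * ell_rw

      for (f in segs$start_frame[si]:segs$end_frame[si]) {
        t <- (f - 1) / fps
        frame <- array(0, dim = c(H, W, 3))
        fmask <- matrix(FALSE, H, W)
        pmask <- matrix(FALSE, H, W)

        # biological half: moving textured ellipses with face discs
        bio <- array(p$bg, dim = c(dim(RR_b), 3))
        bio[, , 1] <- clamp(p$bg + 0.04, 0, 1)
        for (a in 1:3) {
          cr <- mean(rows) +
            0.28 * length(rows) * sin(2 * pi * p$actor_freq[a] * t + p$actor_phase[a])
          cc <- mean(bio_cols) +
            0.30 * length(bio_cols) *
              cos(2 * pi * p$actor_freq[a] * t + p$actor_phase[a] * 1.7 + a)
          body <- ((RR_b - cr) / ell_rh)^2 + ((CC_b - cc) / ell_rw)^2 <= 1
          tex <- 0.8 + 0.2 * sin(RR_b / 2 + a) * cos(CC_b / 3)
          for (ch in 1:3) {
            pl <- bio[, , ch]
            pl[body] <- (p$actor_col[a, ch] * tex)[body]
            bio[, , ch] <- pl
          }
          fr <- cr - 0.75 * ell_rh
          face <- (RR_b - fr)^2 + (CC_b - cc)^2 <= face_r^2
          skin <- c(0.94, 0.78, 0.62)
          for (ch in 1:3) {
            pl <- bio[, , ch]
            pl[face] <- skin[ch]
            bio[, , ch] <- pl
          }
          sub_f <- fmask[rows, bio_cols]; sub_f[face] <- TRUE
          fmask[rows, bio_cols] <- sub_f
          sub_p <- pmask[rows, bio_cols]; sub_p[body | face] <- TRUE
          pmask[rows, bio_cols] <- sub_p
        }
        frame[rows, bio_cols, ] <- clamp(bio, 0, 1)

        # geometric half: rotating fractal-like interference pattern
        v <- 0.5 + 0.5 * cos(p$fract_kr * rad + p$fract_lobes * ang +
                               p$fract_omega * 2 * pi * t) *
          cos(0.45 * p$fract_kr * rad - p$fract_omega * pi * t)
        if (p$warm) {
          frame[rows, geo_cols, 1] <- 0.62 + 0.38 * v
          frame[rows, geo_cols, 2] <- 0.55 + 0.38 * v
          frame[rows, geo_cols, 3] <- 0.18 + 0.18 * v
        } else {
          frame[rows, geo_cols, 1] <- 0.08 + 0.20 * v
          frame[rows, geo_cols, 2] <- 0.12 + 0.22 * v
          frame[rows, geo_cols, 3] <- 0.30 + 0.40 * v
        }

        frames[[f]] <- round(clamp(frame, 0, 1) * 255) / 255
        face_masks[[f]] <- fmask
        person_masks[[f]] <- pmask
        bio_masks[[f]] <- if (bio_left) left_mask else right_mask
        geo_masks[[f]] <- if (bio_left) right_mask else left_mask
      }
    }

    structure(list(frames = frames,
                   masks = list(face = face_masks, person = person_masks,
                                biological = bio_masks, geometric = geo_masks),
                   manifest = manifest),
              class = "stimulus")
  })
}

#' @export
print.stimulus <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Synthetic stimulus: %d frames of %dx%d px, %d segments\n",
              length(x$frames), d[1], d[2], nrow(x$manifest$segments)))
  invisible(x)
}

#' Generate a group-conditional synthetic gaze stream
#'
#' Emits one gaze sample per tracker tick (minus dropout, which removes
#' ticks entirely) over the duration of the stimulus.  Fixation targets are
#' drawn from the phenotype mixture described in [phenotype_params()] at
#' `fixation_hz`; between draws the gaze dwells on the current target plus
#' per-tick tracker jitter.  Coordinates are integer screen pixels
#' (0-based, `gaze_x_px` = column, `gaze_y_px` = row).
#'
#' @param stimulus a [generate_stimulus()] result (face mask centroids are
#'   taken from its oracle masks).
#' @param params a [phenotype_params()].
#' @param sampling_rate tracker rate in Hz (default 120).
#' @param subject_id identifier copied into every sample row.
#' @param seed integer seed; defaults to `params$seed`.
#' @return An object of class `gaze_stream`: a data frame with columns
#'   `subject_id`, `timestamp_ms`, `gaze_x_px`, `gaze_y_px`, `validity`,
#'   with the screen size in attribute `screen_size`.
#' @export
generate_gaze <- function(stimulus, params, sampling_rate = 120,
                          subject_id = "s1", seed = params$seed) {
  stopifnot(inherits(stimulus, "stimulus"),
            inherits(params, "phenotype_params"))
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  manifest <- stimulus$manifest
  H <- manifest$screen_size[1]
  W <- manifest$screen_size[2]
  mid <- W %/% 2L
  fps <- manifest$fps
  nf <- length(stimulus$frames)
  duration <- nf / fps

  # per-frame face centroid and biological side (screen coordinates)
  face_centroid <- t(vapply(seq_len(nf), function(f) {
    m <- stimulus$masks$face[[f]]
    if (any(m)) {
      idx <- which(m, arr.ind = TRUE)
      colMeans(idx) - 1  # 0-based
    } else c(H / 2, W / 2)
  }, numeric(2)))
  side <- frame_side(manifest, seq_len(nf))

  n <- floor(duration * sampling_rate)
  if (n < 1) return(empty_gaze(subject_id, c(H, W)))
  t_ms <- round((seq_len(n) - 1) / sampling_rate * 1000, 1)
  frame <- pmin(floor((seq_len(n) - 1) / sampling_rate * fps) + 1L, nf)

  with_seed(if (is.null(seed)) 1L else seed, {
    # gaze dwells on fixation targets drawn at fixation_hz; ticks within a
    # fixation share the target plus tracker jitter.  A scene cut always
    # triggers a fresh fixation (viewers re-orient at cuts).
    fix_id <- floor((seq_len(n) - 1) / sampling_rate * params$fixation_hz)
    seg <- findInterval(frame, manifest$segments$start_frame)
    grp <- cumsum(c(TRUE, diff(fix_id) != 0 | diff(seg) != 0))
    onset <- !duplicated(grp)
    m <- sum(onset)
    f_onset <- frame[onset]

    geo <- stats::runif(m) < params$p_geometric
    bio_left <- side[f_onset] == "left"
    # column range of the half each fixation lands on
    on_left <- ifelse(geo, !bio_left, bio_left)
    c_lo <- ifelse(on_left, 0, mid)
    c_hi <- ifelse(on_left, mid - 1, W - 1)

    to_face <- !geo & (stats::runif(m) < params$face_attraction)
    mu_r <- ifelse(to_face, face_centroid[f_onset, 1], (H - 1) / 2)
    mu_c <- ifelse(to_face, face_centroid[f_onset, 2], (c_lo + c_hi) / 2)
    sig <- ifelse(to_face, params$center_bias_sigma / 2,
                  params$center_bias_sigma)
    fr <- stats::rnorm(m, mu_r, sig)
    fc <- stats::rnorm(m, mu_c, sig)
    unif <- stats::runif(m) < params$noise_weight
    fr[unif] <- stats::runif(sum(unif), 0, H - 1)
    fc[unif] <- (c_lo + stats::runif(m, 0, 1) * (c_hi - c_lo))[unif]
    fr <- clamp(fr, 0, H - 1)
    fc <- clamp(fc, c_lo, c_hi)

    # expand fixations to ticks
    tick_of <- grp
    r <- fr[tick_of] + stats::rnorm(n, 0, params$jitter_sigma)
    cc <- fc[tick_of] + stats::rnorm(n, 0, params$jitter_sigma)
    r <- round(clamp(r, 0, H - 1))
    cc <- round(clamp(cc, c_lo[tick_of], c_hi[tick_of]))

    # dropout ticks are missing samples: the tracker emitted nothing
    keep <- stats::runif(n) >= params$dropout_rate
    out <- if (!any(keep)) {
      empty_gaze(subject_id, c(H, W))[, ]
    } else {
      data.frame(subject_id = subject_id,
                 timestamp_ms = t_ms[keep],
                 gaze_x_px = as.integer(cc[keep]),
                 gaze_y_px = as.integer(r[keep]),
                 validity = 1L,
                 stringsAsFactors = FALSE)
    }
    attr(out, "screen_size") <- c(H, W)
    class(out) <- c("gaze_stream", "data.frame")
    out
  })
}

empty_gaze <- function(subject_id, screen_size) {
  out <- data.frame(subject_id = character(0), timestamp_ms = numeric(0),
                    gaze_x_px = integer(0), gaze_y_px = integer(0),
                    validity = integer(0), stringsAsFactors = FALSE)
  attr(out, "screen_size") <- screen_size
  class(out) <- c("gaze_stream", "data.frame")
  out
}

#' Read and write gaze streams as tab-separated text
#'
#' The dialect is bit-exact and documented: a header line
#' `subject_id<TAB>timestamp_ms<TAB>gaze_x_px<TAB>gaze_y_px<TAB>validity`,
#' then one tab-separated row per sample.  `gaze_x_px`/`gaze_y_px` are
#' 0-based integer screen pixels (column, row); `validity` is 0 or 1;
#' timestamps are milliseconds.
#'
#' @param stream a `gaze_stream` data frame.
#' @param path TSV file path.
#' @param screen_size optional `c(height, width)` recorded on the result of
#'   `read_gaze_tsv` (not stored in the file).
#' @return `read_gaze_tsv` returns a `gaze_stream`; `write_gaze_tsv`
#'   returns `path` invisibly.
#' @export
write_gaze_tsv <- function(stream, path) {
  cols <- c("subject_id", "timestamp_ms", "gaze_x_px", "gaze_y_px", "validity")
  stopifnot(all(cols %in% names(stream)))
  utils::write.table(stream[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_gaze_tsv
#' @export
read_gaze_tsv <- function(path, screen_size = NULL) {
  if (!file.exists(path)) stop("gaze file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp_ms", "gaze_x_px", "gaze_y_px", "validity")
  if (!all(need %in% names(df)))
    stop("gaze TSV is missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$gaze_x_px <- as.integer(df$gaze_x_px)
  df$gaze_y_px <- as.integer(df$gaze_y_px)
  df$validity <- as.integer(df$validity)
  attr(df, "screen_size") <- screen_size
  class(df) <- c("gaze_stream", "data.frame")
  df
}

#' Write a complete synthetic fixture set to disk
#'
#' Persists a stimulus (PNG frame directory plus PNG oracle masks), its
#' manifest (YAML) and any number of per-subject gaze streams (TSV) under
#' `outdir`, in the formats the package's readers understand.  Everything
#' written round-trips losslessly.
#'
#' @param stimulus a [generate_stimulus()] result.
#' @param streams named list of `gaze_stream` objects (names become file
#'   stems under `gaze/`); may be empty.
#' @param outdir existing directory to populate.
#' @return Invisibly, a list of the paths written.
#' @export
write_fixtures <- function(stimulus, streams = list(), outdir) {
  stopifnot(inherits(stimulus, "stimulus"))
  if (!dir.exists(outdir))
    stop("output directory does not exist: ", outdir)
  for (d in c("frames", "masks", "gaze"))
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  mpath <- file.path(outdir, "manifest.yaml")
  write_manifest(stimulus$manifest, mpath)
  nf <- length(stimulus$frames)
  fpaths <- character(nf)
  for (f in seq_len(nf)) {
    fpaths[f] <- file.path(outdir, "frames", sprintf("frame_%04d.png", f))
    png::writePNG(stimulus$frames[[f]], fpaths[f])
    for (mk in names(stimulus$masks)) {
      png::writePNG(stimulus$masks[[mk]][[f]] * 1,
                    file.path(outdir, "masks", sprintf("%s_%04d.png", mk, f)))
    }
  }
  gpaths <- character(0)
  for (nm in names(streams)) {
    gp <- file.path(outdir, "gaze", paste0(nm, ".tsv"))
    write_gaze_tsv(streams[[nm]], gp)
    gpaths <- c(gpaths, gp)
  }
  invisible(list(manifest = mpath, frames = fpaths, gaze = gpaths))
}

#' Read a stimulus fixture directory written by [write_fixtures()]
#'
#' @param dir fixture directory containing `manifest.yaml`, `frames/` and
#'   `masks/`.
#' @return A `stimulus` object equal to the one written.
#' @export
read_stimulus <- function(dir) {
  if (!dir.exists(dir)) stop("fixture directory not found: ", dir)
  manifest <- read_manifest(file.path(dir, "manifest.yaml"))
  nf <- n_frames(manifest)
  frames <- vector("list", nf)
  masks <- list(face = vector("list", nf), person = vector("list", nf),
                biological = vector("list", nf), geometric = vector("list", nf))
  for (f in seq_len(nf)) {
    frames[[f]] <- png::readPNG(file.path(dir, "frames",
                                          sprintf("frame_%04d.png", f)))
    for (mk in names(masks)) {
      m <- png::readPNG(file.path(dir, "masks", sprintf("%s_%04d.png", mk, f)))
      masks[[mk]][[f]] <- m > 0.5
    }
  }
  structure(list(frames = frames, masks = masks, manifest = manifest),
            class = "stimulus")
}
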