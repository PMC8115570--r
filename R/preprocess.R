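#' Crop the black border around a frame
#'
#' Returns the tight bounding box of non-black content.  A pixel is
#' "black" when all its channels are below `threshold` (slightly above
#' zero to be robust to compression noise).  The bounding box used is
#' recorded in attribute `crop_box` as `c(row1, row2, col1, col2)`
#' (1-based, inclusive).
#'
#' @param frame numeric matrix or H x W x 3 array with intensities in
#'   `[0, 1]`.
#' @param threshold intensity below which a pixel counts as black.
#' @return The cropped frame, with attribute `crop_box`.
#' @export
crop_border <- function(frame, threshold = 0.02) {
  stopifnot(is_frame(frame))
  mx <- if (is.matrix(frame)) frame else pmax(frame[, , 1], frame[, , 2], frame[, , 3])
  keep_r <- which(apply(mx, 1, max) >= threshold)
  keep_c <- which(apply(mx, 2, max) >= threshold)
  if (length(keep_r) == 0 || length(keep_c) == 0)
    stop("frame is entirely black; cannot crop border")
  box <- c(min(keep_r), max(keep_r), min(keep_c), max(keep_c))
  out <- if (is.matrix(frame)) {
    frame[box[1]:box[2], box[3]:box[4], drop = FALSE]
  } else {
    frame[box[1]:box[2], box[3]:box[4], , drop = FALSE]
  }
  attr(out, "crop_box") <- box
  out
}

#' Resize a frame to the working resolution
#'
#' Uses exact area (block-average) interpolation, which anti-aliases the
#' downscaling so that the feature channels are computed on alias-free
#' frames.  Intensities above 1 are assumed 8-bit and rescaled to `[0, 1]`.
#'
#' @param frame numeric matrix or H x W x 3 array.
#' @param dim target `c(rows, cols)`; default the 200 x 350 working grid.
#' @return The resized frame (same channel count), intensities in `[0, 1]`.
#' @export
resize_frame <- function(frame, dim = c(200, 350)) {
  stopifnot(is_frame(frame), length(dim) == 2)
  if (max(frame) > 1) frame <- frame / 255
  if (is.matrix(frame)) {
    out <- resize_matrix(frame, dim[1], dim[2])
  } else {
    out <- array(0, c(dim, 3L))
    for (ch in 1:3) out[, , ch] <- resize_matrix(frame[, , ch], dim[1], dim[2])
  }
  clamp(out, 0, 1)
}

# Resize a logical mask with area interpolation + 0.5 threshold.
resize_mask <- function(mask, dim) {
  resize_matrix(mask * 1, dim[1], dim[2]) >= 0.5
}

#' Drop transition frames at segment boundaries
#'
#' At every interior boundary between two consecutive sub-videos, the last
#' `n_trim` frames of the earlier segment and the first `n_trim` frames of
#' the later one are removed, so that cross-fade/cut artefacts never enter
#' the learning or diagnosis sets.  The manifest is re-indexed to the kept
#' frames.
#'
#' @param frames list of frames (any per-frame payload; only the count is
#'   inspected here).
#' @param manifest a [scene_manifest()] describing `frames`.
#' @param n_trim frames removed on each side of an interior boundary.
#' @return list with `kept` (original indices of surviving frames) and
#'   `manifest` (segments re-indexed to the kept frames).
#' @export
remove_transitions <- function(frames, manifest, n_trim = 10) {
  validate_manifest(manifest)
  segs <- manifest$segments
  if (length(frames) != n_frames(manifest))
    stop("frame count does not match manifest")
  nseg <- nrow(segs)
  if (nseg == 1L) {
    return(list(kept = seq_along(frames), manifest = manifest))
  }
  lens <- segs$end_frame - segs$start_frame + 1L
  if (any(lens < 2L * n_trim + 1L))
    stop("segment shorter than ", 2L * n_trim + 1L,
         " frames; cannot remove transitions")
  kept <- integer(0)
  new_segs <- segs
  pos <- 0L
  for (i in seq_len(nseg)) {
    a <- segs$start_frame[i] + if (i > 1L) n_trim else 0L
    b <- segs$end_frame[i] - if (i < nseg) n_trim else 0L
    kept <- c(kept, a:b)
    new_segs$start_frame[i] <- pos + 1L
    pos <- pos + (b - a + 1L)
    new_segs$end_frame[i] <- pos
  }
  list(kept = kept,
       manifest = new_manifest(new_segs, manifest$screen_size, manifest$fps))
}

#' Preprocess a stimulus into the working frame sequence
#'
#' Applies the full frame preprocessing chain: crop the black border
#' (bounding box estimated on the first frame and applied to all), resize
#' to the 200 x 350 working grid with area interpolation, and remove
#' transition frames at segment boundaries.  Oracle masks, when present,
#' are carried through the identical geometric transform.
#'
#' @param stimulus a `stimulus` object ([generate_stimulus()] /
#'   [read_stimulus()]).
#' @param dim working resolution `c(rows, cols)`.
#' @param n_trim transition frames trimmed at each side of interior
#'   segment boundaries.
#' @param threshold black-border intensity threshold.
#' @return An object of class `frame_sequence`: list with `frames` (list
#'   of `dim[1] x dim[2] x 3` arrays), `masks` (resized oracle masks or
#'   `NULL`), `side` (biological side per kept frame), `frame_times`
#'   (display start, ms, original timeline), `orig_index`, `manifest`
#'   (re-indexed), `crop_box`, `src_size`, `fps` and `dim`.
#' @export
preprocess_stimulus <- function(stimulus, dim = c(200, 350), n_trim = 10,
                                threshold = 0.02) {
  stopifnot(inherits(stimulus, "stimulus"))
  manifest <- stimulus$manifest
  first <- crop_border(stimulus$frames[[1]], threshold)
  box <- attr(first, "crop_box")
  tr <- remove_transitions(stimulus$frames, manifest, n_trim)
  kept <- tr$kept
  frames <- vector("list", length(kept))
  masks <- NULL
  has_masks <- !is.null(stimulus$masks)
  if (has_masks)
    masks <- lapply(stimulus$masks, function(x) vector("list", length(kept)))
  for (j in seq_along(kept)) {
    f <- kept[j]
    fr <- stimulus$frames[[f]][box[1]:box[2], box[3]:box[4], , drop = FALSE]
    frames[[j]] <- resize_frame(fr, dim)
    if (has_masks) {
      for (mk in names(stimulus$masks)) {
        m <- stimulus$masks[[mk]][[f]][box[1]:box[2], box[3]:box[4], drop = FALSE]
        masks[[mk]][[j]] <- resize_mask(m, dim)
      }
    }
  }
  out <- list(frames = frames,
              masks = masks,
              side = frame_side(manifest, kept),
              frame_times = (kept - 1) * 1000 / manifest$fps,
              orig_index = kept,
              manifest = tr$manifest,
              crop_box = box,
              src_size = manifest$screen_size,
              fps = manifest$fps,
              dim = as.integer(dim))
  class(out) <- "frame_sequence"
  out
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("Preprocessed frame sequence: %d frames of %dx%d px (%d pixels)\n",
              length(x$frames), x$dim[1], x$dim[2], prod(x$dim)))
  invisible(x)
}

#' Map raw gaze samples into preprocessed frame coordinates
#'
#' Applies to the gaze coordinates the exact crop + area-resize affine
#' transform that was applied to the frames, assigns each sample the kept
#' frame whose display interval contains its timestamp, and flags samples
#' that fall outside the crop box, carry `validity = 0`, or land on a
#' removed (transition) frame.  Pixel binning is half-open: a sample at
#' screen pixel `(y, x)` maps to working pixel
#' `floor((y - row1 + 0.5) * out_h / crop_h)` (0-based), and likewise for
#' columns.
#'
#' @param stream a `gaze_stream` (raw screen coordinates).
#' @param prep a `frame_sequence` from [preprocess_stimulus()].
#' @return An object of class `mapped_gaze`: data frame with columns
#'   `subject_id`, `timestamp_ms`, `row`, `col` (0-based working-grid
#'   pixels), `frame` (kept-frame index, `NA` when unassignable) and
#'   `valid`.  Only `valid` samples enter fixation maps.
#' @export
map_gaze <- function(stream, prep) {
  stopifnot(inherits(prep, "frame_sequence"))
  need <- c("subject_id", "timestamp_ms", "gaze_x_px", "gaze_y_px", "validity")
  stopifnot(all(need %in% names(stream)))
  t <- stream$timestamp_ms
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("gaze timestamps must be strictly increasing")
  box <- prep$crop_box
  crop_h <- box[2] - box[1] + 1L
  crop_w <- box[4] - box[3] + 1L
  out_h <- prep$dim[1]
  out_w <- prep$dim[2]

  # 1-based screen pixel of each sample
  y1 <- stream$gaze_y_px + 1L
  x1 <- stream$gaze_x_px + 1L
  in_crop <- y1 >= box[1] & y1 <= box[2] & x1 >= box[3] & x1 <= box[4]

  row <- floor((y1 - box[1] + 0.5) * out_h / crop_h)
  col <- floor((x1 - box[3] + 0.5) * out_w / crop_w)
  row <- clamp(row, 0, out_h - 1L)
  col <- clamp(col, 0, out_w - 1L)

  # frame whose display interval [t_f, t_f + 1/fps) contains the timestamp
  nf_orig <- n_frames_orig(prep)
  orig_frame <- floor(t / 1000 * prep$fps) + 1L
  in_time <- t >= 0 & orig_frame >= 1L & orig_frame <= nf_orig
  kept_of_orig <- rep(NA_integer_, nf_orig)
  kept_of_orig[prep$orig_index] <- seq_along(prep$orig_index)
  frame <- rep(NA_integer_, length(t))
  frame[in_time] <- kept_of_orig[orig_frame[in_time]]

  valid <- stream$validity == 1L & in_crop & in_time & !is.na(frame)
  out <- data.frame(subject_id = stream$subject_id,
                    timestamp_ms = t,
                    row = as.integer(row),
                    col = as.integer(col),
                    frame = frame,
                    valid = valid,
                    stringsAsFactors = FALSE)
  out$row[!in_crop] <- NA_integer_
  out$col[!in_crop] <- NA_integer_
  attr(out, "grid_dim") <- prep$dim
  class(out) <- c("mapped_gaze", "data.frame")
  out
}

n_frames_orig <- function(prep) {
  # original frame count before transition removal
  max(prep$orig_index)
}
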