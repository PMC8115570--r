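#' Describe a two-panel stimulus video
#'
#' A scene manifest records how a preferential-looking stimulus video is
#' organised: a sequence of contiguous segments (sub-videos) shown back to
#' back, each displaying biological motion (people interacting) on one half
#' of the screen and geometric (fractal) motion on the other.  The manifest
#' is consumed by the synthetic generator, the preprocessing stage (which
#' must know segment boundaries to drop transition frames) and the feature
#' bank (which needs the biological/geometric side per frame).
#'
#' Defaults mirror the stimulus design used to learn the attention models:
#' nine roughly six-second segments at 1920x1080, with the biological side
#' alternating between segments so that side preference cannot be confounded
#' with a fixed screen half.
#'
#' @param n_segments number of sequentially displayed sub-videos.
#' @param frames_per_segment frames in each sub-video.
#' @param fps display rate, frames per second.
#' @param screen_size integer vector `c(height, width)` in pixels.
#' @param biological_side character vector, one of `"left"`/`"right"` per
#'   segment, naming the screen half showing biological motion.
#' @return An object of class `scene_manifest`: a list with a `segments`
#'   data frame (`start_frame`, `end_frame`, `biological_side`; 1-based,
#'   inclusive), `screen_size` and `fps`.
#' @examples
#' m <- scene_manifest(n_segments = 3, frames_per_segment = 30, fps = 10,
#'                     screen_size = c(270, 480))
#' m$segments
#' @export
scene_manifest <- function(n_segments = 9, frames_per_segment = 60, fps = 10,
                           screen_size = c(1080, 1920),
                           biological_side = rep(c("left", "right"),
                                                 length.out = n_segments)) {
  if (n_segments < 1) stop("manifest must have at least one segment")
  if (frames_per_segment < 1) stop("segments must contain at least one frame")
  if (length(screen_size) != 2 || any(screen_size < 2))
    stop("screen_size must be c(height, width) with both >= 2")
  if (fps <= 0) stop("fps must be positive")
  biological_side <- match.arg(biological_side, c("left", "right"),
                               several.ok = TRUE)
  if (length(biological_side) != n_segments)
    stop("biological_side must name a side for every segment")
  start <- seq(1L, by = as.integer(frames_per_segment),
               length.out = n_segments)
  segs <- data.frame(
    start_frame = start,
    end_frame = start + as.integer(frames_per_segment) - 1L,
    biological_side = biological_side,
    stringsAsFactors = FALSE
  )
  new_manifest(segs, as.integer(screen_size), fps)
}

new_manifest <- function(segments, screen_size, fps) {
  m <- list(segments = segments,
            screen_size = as.integer(screen_size),
            fps = as.numeric(fps))
  class(m) <- "scene_manifest"
  validate_manifest(m)
}

validate_manifest <- function(m) {
  segs <- m$segments
  if (nrow(segs) < 1) stop("manifest has no segments")
  if (any(segs$end_frame < segs$start_frame))
    stop("manifest segment with end before start")
  if (segs$start_frame[1] != 1L)
    stop("manifest segments must start at frame 1")
  if (nrow(segs) > 1 &&
      any(segs$start_frame[-1] != segs$end_frame[-nrow(segs)] + 1L))
    stop("manifest segments must be contiguous and non-overlapping")
  if (!all(segs$biological_side %in% c("left", "right")))
    stop("biological_side must be 'left' or 'right' for every segment")
  m
}

#' @export
print.scene_manifest <- function(x, ...) {
  cat(sprintf("Scene manifest: %d segments, %d frames, %gx%g px @ %g fps\n",
              nrow(x$segments), n_frames(x),
              x$screen_size[1], x$screen_size[2], x$fps))
  print(x$segments)
  invisible(x)
}

n_frames <- function(manifest) manifest$segments$end_frame[nrow(manifest$segments)]

# Side of the screen showing biological motion for a given (1-based) frame.
frame_side <- function(manifest, frame) {
  segs <- manifest$segments
  i <- findInterval(frame, segs$start_frame)
  if (any(i < 1L | frame > segs$end_frame[i]))
    stop("frame index outside manifest range")
  segs$biological_side[i]
}

#' Read and write scene manifests
#'
#' Manifests are persisted as a small YAML key-value document with fields
#' `screen_height`, `screen_width`, `fps` and a `segments` list of
#' `{start_frame, end_frame, biological_side}` records.  Reading a written
#' manifest reproduces the original object exactly.
#'
#' @param manifest a [scene_manifest()].
#' @param path file path for the YAML document.
#' @return `read_manifest` returns a `scene_manifest`;
#'   `write_manifest` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "scene_manifest"))
  segs <- manifest$segments
  doc <- list(
    screen_height = manifest$screen_size[1],
    screen_width = manifest$screen_size[2],
    fps = manifest$fps,
    segments = lapply(seq_len(nrow(segs)), function(i) {
      list(start_frame = segs$start_frame[i],
           end_frame = segs$end_frame[i],
           biological_side = segs$biological_side[i])
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  doc <- yaml::read_yaml(path)
  segs <- do.call(rbind, lapply(doc$segments, function(s) {
    data.frame(start_frame = as.integer(s$start_frame),
               end_frame = as.integer(s$end_frame),
               biological_side = as.character(s$biological_side),
               stringsAsFactors = FALSE)
  }))
  new_manifest(segs, c(doc$screen_height, doc$screen_width), doc$fps)
}
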