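#' Per-pixel motion map between two frames
#'
#' The default estimator is the normalised absolute temporal intensity
#' difference on the luma channel, which is already in `[0, 1]` for
#' `[0, 1]` frames.  An alternative dense normal-flow magnitude estimator
#' is available behind the same contract: per-pixel displacement magnitude
#' `|It| / sqrt(Ix^2 + Iy^2 + eps)` clipped at `max_displacement` pixels
#' and divided by it.
#'
#' @param frame_a,frame_b same-shape frames (matrix or H x W x 3).
#' @param estimator `"difference"` (default) or `"flow"`.
#' @param max_displacement clip/normalisation constant, in pixels, for the
#'   flow estimator.
#' @return Matrix of per-pixel motion values in `[0, 1]`.
#' @export
motion_map <- function(frame_a, frame_b,
                       estimator = c("difference", "flow"),
                       max_displacement = 10) {
  estimator <- match.arg(estimator)
  if (!identical(dim(frame_a)[1:2], dim(frame_b)[1:2]))
    stop("frames must have the same shape")
  ga <- rgb_to_gray(frame_a)
  gb <- rgb_to_gray(frame_b)
  if (estimator == "difference") {
    return(abs(gb - ga))
  }
  h <- nrow(ga); w <- ncol(ga)
  ix <- matrix(0, h, w)
  iy <- matrix(0, h, w)
  ix[, 2:(w - 1)] <- (ga[, 3:w] - ga[, 1:(w - 2)]) / 2
  iy[2:(h - 1), ] <- (ga[3:h, ] - ga[1:(h - 2), ]) / 2
  it <- gb - ga
  mag <- abs(it) / sqrt(ix^2 + iy^2 + 1e-4)
  pmin(mag, max_displacement) / max_displacement
}

#' Mean motion value between two frames
#'
#' Sums the per-pixel motion values and divides by the number of pixels,
#' giving a scalar in `[0, 1]` used by the frame-aggregation rule.
#'
#' @inheritParams motion_map
#' @return Scalar mean motion in `[0, 1]`.
#' @examples
#' a <- matrix(0, 3, 3); b <- a; b[2, 2] <- 0.9
#' mean_motion(a, b)  # 0.9 / 9 = 0.1
#' @export
mean_motion <- function(frame_a, frame_b,
                        estimator = c("difference", "flow"),
                        max_displacement = 10) {
  mean(motion_map(frame_a, frame_b, estimator, max_displacement))
}

#' Aggregate consecutive low-motion frames
#'
#' Single frames rarely collect enough gaze samples to train on, so runs
#' of nearly static frames are pooled.  The rule is greedy and
#' left-to-right: keep a running aggregate (the pixelwise mean of its
#' members); if the mean motion between the current aggregate's mean frame
#' and the next frame is below `threshold`, absorb the next frame and
#' update the mean, otherwise close the set and start a new one.  The
#' comparison is aggregate-vs-next (directional), not frame-vs-frame.
#'
#' The default threshold 0.33 was calibrated on the original stimulus; for
#' a different video it should be reviewed.
#'
#' @param frames list of same-shape frames, or a `frame_sequence` (its
#'   `frames` are used).
#' @param threshold mean-motion threshold in `(0, 1]` below which frames
#'   are merged.
#' @param estimator,max_displacement passed to [mean_motion()].
#' @return List of `frame_set` objects, each with `members` (contiguous
#'   frame indices), `mean_frame`, and `motion_to_next` (the mean motion
#'   that closed the set; `NA` for the last).  The sets partition the
#'   sequence in order.
#' @export
aggregate_frames <- function(frames, threshold = 0.33,
                             estimator = c("difference", "flow"),
                             max_displacement = 10) {
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  estimator <- match.arg(estimator)
  if (length(frames) < 1) stop("need at least one frame")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  sets <- list()
  members <- 1L
  mean_frame <- frames[[1]]
  for (f in seq_along(frames)[-1]) {
    m <- mean_motion(mean_frame, frames[[f]], estimator, max_displacement)
    if (m < threshold) {
      k <- length(members)
      mean_frame <- (mean_frame * k + frames[[f]]) / (k + 1)
      members <- c(members, f)
    } else {
      sets[[length(sets) + 1L]] <- new_frame_set(members, mean_frame, m)
      members <- f
      mean_frame <- frames[[f]]
    }
  }
  sets[[length(sets) + 1L]] <- new_frame_set(members, mean_frame, NA_real_)
  sets
}

new_frame_set <- function(members, mean_frame, motion_to_next) {
  structure(list(members = members, mean_frame = mean_frame,
                 motion_to_next = motion_to_next),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("Frame set: frames %d..%d (%d members), motion to next = %s\n",
              min(x$members), max(x$members), length(x$members),
              format(x$motion_to_next, digits = 3)))
  invisible(x)
}

#' Pool gaze samples over aggregated frame sets
#'
#' Assigns every valid mapped gaze sample the id of the frame set its
#' frame belongs to.  Sample counts are conserved: each valid sample with
#' a frame inside some set appears in exactly one set.
#'
#' @param mapped a `mapped_gaze` data frame (see [map_gaze()]) or a list
#'   of them (multiple subjects), which are row-bound.
#' @param framesets list of `frame_set` from [aggregate_frames()].
#' @return A `mapped_gaze` data frame restricted to valid samples on
#'   aggregated frames, with an extra `set_id` column.
#' @export
aggregate_gaze <- function(mapped, framesets) {
  if (is.list(mapped) && !is.data.frame(mapped))
    mapped <- do.call(rbind, mapped)
  nmax <- max(vapply(framesets, function(s) max(s$members), 1L))
  set_of_frame <- rep(NA_integer_, nmax)
  for (i in seq_along(framesets))
    set_of_frame[framesets[[i]]$members] <- i
  keep <- mapped$valid & !is.na(mapped$frame) & mapped$frame <= nmax
  out <- mapped[keep, , drop = FALSE]
  out$set_id <- set_of_frame[out$frame]
  out <- out[!is.na(out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
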