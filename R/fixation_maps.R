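#' Normalised 2-D Gaussian kernel
#'
#' @param size odd kernel side length.
#' @param sigma standard deviation in pixels.
#' @return `size x size` matrix summing to one.
#' @export
gaussian_kernel <- function(size = 5, sigma = 1) {
  if (size %% 2 != 1) stop("kernel size must be odd")
  r <- (size - 1) / 2
  d <- seq(-r, r)
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Group-level smoothed fixation map for a frame set
#'
#' Accumulates, over all subjects of a group, the number of valid gaze
#' samples landing on each working-grid pixel during the frames of one
#' aggregated frame set, then smooths the count matrix with a normalised
#' 5 x 5 Gaussian (zero padding at the boundary).  Total mass is conserved
#' for interior fixations.
#'
#' @param samples a `mapped_gaze` data frame already restricted to the
#'   group's subjects and to one frame set (e.g. by [aggregate_gaze()]
#'   and subsetting on `set_id`); only rows with `valid == TRUE` count.
#' @param dim working grid `c(rows, cols)`.
#' @param kernel smoothing kernel; `NULL` skips smoothing.
#' @return Numeric `dim[1] x dim[2]` matrix of (smoothed) fixation counts,
#'   class `group_fixation_map`.
#' @export
group_fixation_map <- function(samples, dim = c(200, 350),
                               kernel = gaussian_kernel(5, 1)) {
  counts <- fixation_counts(samples, dim)
  if (!is.null(kernel)) {
    counts <- conv2_same(counts, kernel)
    # squash FFT round-off so never-fixated cells are exactly zero
    counts[abs(counts) < 1e-9] <- 0
  }
  structure(counts, class = c("group_fixation_map", class(counts)))
}

# Raw (unsmoothed) per-pixel gaze sample counts.
fixation_counts <- function(samples, dim) {
  counts <- matrix(0, dim[1], dim[2])
  ok <- samples$valid & !is.na(samples$row) & !is.na(samples$col)
  if (any(ok)) {
    idx <- samples$row[ok] + 1L + samples$col[ok] * dim[1]
    tab <- tabulate(idx, nbins = prod(dim))
    counts[] <- tab
  }
  counts
}

#' Binary individual fixation map for one frame
#'
#' A pixel is 1 iff at least one valid sample of the subject falls on it
#' while the given frame is displayed; repeated hits are not counted
#' (binarisation is idempotent).
#'
#' @param mapped a `mapped_gaze` data frame for one subject.
#' @param frame kept-frame index.
#' @param dim working grid `c(rows, cols)`.
#' @param dilate radius (px) of a disc dilation applied to the fixated
#'   pixels; 0 (the default) marks raw hits only.
#' @return Binary (0/1 integer) `dim[1] x dim[2]` matrix.
#' @export
individual_fixation_map <- function(mapped, frame, dim = c(200, 350),
                                    dilate = 0) {
  sub <- mapped[mapped$valid & !is.na(mapped$frame) & mapped$frame == frame, ,
                drop = FALSE]
  bits <- matrix(0L, dim[1], dim[2])
  if (nrow(sub) > 0) {
    if (dilate > 0) {
      r <- as.integer(ceiling(dilate))
      off <- expand.grid(dr = -r:r, dc = -r:r)
      off <- off[off$dr^2 + off$dc^2 <= dilate^2, ]
      for (k in seq_len(nrow(off))) {
        rr <- sub$row + off$dr[k]
        cc <- sub$col + off$dc[k]
        ok <- rr >= 0 & rr < dim[1] & cc >= 0 & cc < dim[2]
        bits[cbind(rr[ok] + 1L, cc[ok] + 1L)] <- 1L
      }
    } else {
      bits[cbind(sub$row + 1L, sub$col + 1L)] <- 1L
    }
  }
  bits
}

#' Select balanced training coordinates from a fixation map
#'
#' Picks the `n_pos` map cells with the highest (smoothed) fixation values
#' as class-1 (fixated) exemplars — ties broken deterministically by
#' (value descending, row ascending, column ascending) — and draws `n_neg`
#' cells with exactly zero fixation value uniformly without replacement as
#' class-0 exemplars.
#'
#' @param map a `group_fixation_map` (or any numeric matrix of
#'   non-negative values).
#' @param n_pos,n_neg number of class-1 / class-0 coordinates.
#' @param seed integer seed controlling the zero-cell draw.
#' @return An object of class `coordinate_sample`: data frame with columns
#'   `row`, `col` (0-based) and `class` (1/0), exactly `n_pos + n_neg`
#'   rows, no duplicates.
#' @export
select_coordinates <- function(map, n_pos = 350, n_neg = 350, seed = 1) {
  stopifnot(is.matrix(map))
  h <- nrow(map); w <- ncol(map)
  v <- as.vector(map)
  ri <- rep(seq_len(h), times = w)
  ci <- rep(seq_len(w), each = h)
  npos_avail <- sum(v > 0)
  nzero_avail <- sum(v == 0)
  if (npos_avail < n_pos)
    stop(sprintf("only %d cells with positive value; %d class-1 coordinates requested",
                 npos_avail, n_pos))
  if (nzero_avail < n_neg)
    stop(sprintf("only %d zero-valued cells; %d class-0 coordinates requested",
                 nzero_avail, n_neg))
  ord <- order(-v, ri, ci)
  top <- ord[seq_len(n_pos)]
  zeros <- which(v == 0)
  neg <- with_seed(seed, sample(zeros, n_neg, replace = FALSE))
  out <- data.frame(row = c(ri[top], ri[neg]) - 1L,
                    col = c(ci[top], ci[neg]) - 1L,
                    class = rep(c(1L, 0L), c(n_pos, n_neg)))
  class(out) <- c("coordinate_sample", "data.frame")
  out
}
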