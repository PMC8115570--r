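test_that("crop_border finds the tight content bounding box", {
  fr <- array(0, c(135, 240, 3))
  fr[21:115, 31:210, ] <- 0.5
  out <- crop_border(fr)
  expect_identical(dim(out), c(95L, 180L, 3L))
  expect_identical(attr(out, "crop_box"), c(21L, 115L, 31L, 210L))

  # borderless frame comes back unchanged
  full <- array(0.4, c(20, 30, 3))
  out2 <- crop_border(full)
  expect_equal(unclass(out2), full, ignore_attr = TRUE)
  expect_identical(attr(out2, "crop_box"), c(1L, 20L, 1L, 30L))

  expect_error(crop_border(array(0, c(10, 10, 3))), "black")
})

test_that("resize_frame produces the 200x350 working grid by area interpolation", {
  fr <- array(runif(95 * 180 * 3), c(95, 180, 3))
  out <- resize_frame(fr)
  expect_identical(dim(out), c(200L, 350L, 3L))
  expect_equal(prod(dim(out)[1:2]), 70000)

  # constant input stays constant
  cst <- resize_frame(array(0.37, c(50, 80, 3)))
  expect_true(all(abs(cst - 0.37) < 1e-12))

  # integer-factor downscale equals explicit block averaging
  chk <- matrix(rep(c(0, 1), length.out = 8 * 14), 8, 14)
  oracle <- matrix(0, 4, 7)
  for (i in 1:4) for (j in 1:7)
    oracle[i, j] <- mean(chk[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  got <- resize_frame(array(chk, c(8, 14, 1))[, , 1, drop = TRUE], dim = c(4, 7))
  expect_equal(got, oracle, tolerance = 1e-12, ignore_attr = TRUE)

  # area interpolation preserves the mean exactly for any geometry
  x <- matrix(runif(37 * 53), 37, 53)
  expect_equal(mean(resize_frame(x, dim = c(200, 350))), mean(x),
               tolerance = 1e-10)
})

test_that("remove_transitions drops 10 frames each side of interior cuts", {
  m <- scene_manifest(n_segments = 9, frames_per_segment = 60)
  tr <- remove_transitions(as.list(seq_len(540)), m)
  expect_length(tr$kept, 380)  # 540 - 8 boundaries * 20
  # order preserved, only boundary frames removed
  expect_true(!is.unsorted(tr$kept))
  expect_true(all(diff(tr$kept) %in% c(1L, 21L)))
  # first segment keeps its opening frames, last keeps its closing frames
  expect_identical(tr$kept[1], 1L)
  expect_identical(tr$kept[length(tr$kept)], 540L)
  # manifest re-indexed contiguously over kept frames
  segs <- tr$manifest$segments
  expect_equal(segs$start_frame[1], 1)
  expect_equal(segs$end_frame[9], 380)

  # single segment: nothing removed
  m1 <- scene_manifest(n_segments = 1, frames_per_segment = 30)
  tr1 <- remove_transitions(as.list(seq_len(30)), m1)
  expect_identical(tr1$kept, seq_len(30))

  # too-short segments are an error
  m2 <- scene_manifest(n_segments = 3, frames_per_segment = 15)
  expect_error(remove_transitions(as.list(seq_len(45)), m2), "21")
})

# minimal hand-built frame_sequence for closed-form gaze mapping checks
fake_prep <- function(crop_box = c(1L, 1080L, 1L, 1920L), fps = 30,
                      n_orig = 90, kept = seq_len(90)) {
  structure(list(crop_box = crop_box, dim = c(200L, 350L), fps = fps,
                 orig_index = kept),
            class = "frame_sequence")
}

fake_stream <- function(t, x, y, validity = 1L) {
  data.frame(subject_id = "s", timestamp_ms = t, gaze_x_px = x,
             gaze_y_px = y, validity = validity)
}

test_that("gaze mapping applies the exact crop+resize affine transform", {
  pp <- fake_prep()
  # original screen centre maps to the centre working pixel
  mg <- map_gaze(fake_stream(10, 960L, 540L), pp)
  expect_identical(mg$row, 100L)
  expect_identical(mg$col, 175L)
  expect_identical(mg$frame, 1L)
  expect_true(mg$valid)

  # sample inside the cropped-away border is excluded
  pp2 <- fake_prep(crop_box = c(101L, 980L, 1L, 1920L))
  mg2 <- map_gaze(fake_stream(10, 960L, 50L), pp2)
  expect_false(mg2$valid)

  # sample before the first frame is excluded
  mg3 <- map_gaze(fake_stream(-5, 960L, 540L), pp)
  expect_false(mg3$valid)

  # invalid tracker samples are excluded
  mg4 <- map_gaze(fake_stream(10, 960L, 540L, validity = 0L), pp)
  expect_false(mg4$valid)

  # samples on removed transition frames are excluded
  pp5 <- fake_prep(kept = c(1:10, 31:90))
  mg5 <- map_gaze(fake_stream(1000 * 20 / 30 + 1, 960L, 540L), pp5)  # frame 21
  expect_false(mg5$valid)

  expect_error(map_gaze(fake_stream(c(10, 10), c(1L, 2L), c(1L, 2L)), pp),
               "strictly increasing")
})

test_that("gaze mapping is the affine image of the frame transform", {
  # marking a pixel and resizing the indicator lands its mass on the same
  # working cell that map_gaze assigns to the pixel
  set.seed(5)
  pp <- fake_prep(crop_box = c(11L, 123L, 21L, 222L))
  for (rep in 1:10) {
    y <- sample(11:123, 1)
    x <- sample(21:222, 1)
    ind <- matrix(0, 113, 202)
    ind[y - 10, x - 20] <- 1
    res <- gazevam:::resize_matrix(ind, 200, 350)
    hit <- which(res == max(res), arr.ind = TRUE)
    mg <- map_gaze(fake_stream(10, as.integer(x - 1), as.integer(y - 1)), pp)
    expect_true(any(hit[, 1] == mg$row + 1L & hit[, 2] == mg$col + 1L))
  }
})

test_that("preprocess_stimulus ties the pieces together", {
  pp <- tiny_prep()
  expect_s3_class(pp, "frame_sequence")
  expect_length(pp$frames, 30)  # 2 segments x 25 - 2 * 10
  expect_identical(dim(pp$frames[[1]]), c(200L, 350L, 3L))
  expect_identical(dim(pp$masks$face[[1]]), c(200L, 350L))
  expect_identical(pp$side, gazevam:::frame_side(tiny_stimulus()$manifest,
                                                 pp$orig_index))
  expect_true(all(diff(pp$frame_times) > 0))
})
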