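test_that("the feature stack honours the frozen 28-channel registry", {
  stack <- tiny_stack()
  expect_identical(dim(stack)[3], 28L)
  expect_identical(dimnames(stack)[[3]], vam_channels())
  expect_length(vam_channels(), 28)
  expect_true(all(is.finite(stack)))
  # flag channels are binary and complementary
  bio <- stack[, , "flag_biological"]
  geo <- stack[, , "flag_geometric"]
  expect_true(all(bio %in% c(0, 1)))
  expect_true(all(bio + geo == 1))
  # low-level channels live in [0, 1]
  expect_true(all(stack >= 0 & stack <= 1))
})

test_that("steerable decomposition yields 13 orientation/scale channels", {
  frame <- matrix(runif(64 * 96), 64, 96)
  ch <- steerable_channels(frame)
  expect_identical(dim(ch)[3], 13L)

  # constant image: all band-pass responses vanish before scaling
  flat <- steerable_channels(matrix(0.5, 64, 96), scale = FALSE)
  expect_true(all(abs(flat[, , 1:12]) < 1e-10))

  # a vertical edge concentrates energy in the vertical-selective band
  edge <- matrix(0, 64, 64)
  edge[, 33:64] <- 1
  raw <- steerable_channels(edge, scale = FALSE)
  for (s in 1:4) {
    e0 <- sum(raw[, , sprintf("steer_s%d_o0", s)]^2)
    e60 <- sum(raw[, , sprintf("steer_s%d_o60", s)]^2)
    e120 <- sum(raw[, , sprintf("steer_s%d_o120", s)]^2)
    expect_gt(e0, e60)
    expect_gt(e0, e120)
  }
})

test_that("conspicuity channels behave like centre-surround operators", {
  h <- 64; w <- 96
  gray <- array(0.5, c(h, w, 3))
  cc <- conspicuity_channels(gray)
  expect_true(all(cc[, , "consp_color"] == 0))
  expect_true(all(cc[, , "consp_orientation"] == 0))

  # bright blob on a dark field: intensity conspicuity peaks at the blob
  blob <- array(0.02, c(h, w, 3))
  blob[29:35, 45:51, ] <- 1
  ci <- conspicuity_channels(blob)[, , "consp_intensity"]
  peak <- which(ci == max(ci), arr.ind = TRUE)
  expect_true(any(abs(peak[, 1] - 32) <= 3 & abs(peak[, 2] - 48) <= 3))

  # independent one-scale centre-surround oracle agrees on the peak
  g <- (blob[, , 1] + blob[, , 2] + blob[, , 3]) / 3
  surround <- gazevam:::resize_matrix(gazevam:::resize_matrix(g, h %/% 4, w %/% 4), h, w)
  oracle <- abs(g - surround)
  opk <- which(oracle == max(oracle), arr.ind = TRUE)
  expect_true(any(abs(opk[, 1] - 32) <= 4 & abs(opk[, 2] - 48) <= 4))

  # pure green is far outside the skin chrominance locus
  green <- array(0, c(8, 8, 3)); green[, , 2] <- 1
  expect_lt(max(conspicuity_channels(green)[, , "consp_skin"]), 1e-6)
})

test_that("colour channels are exact copies", {
  fr <- array(runif(8 * 9 * 3), c(8, 9, 3))
  cc <- color_channels(fr)
  expect_equal(unclass(cc), unclass(fr), ignore_attr = TRUE)
  red <- array(0, c(2, 2, 3)); red[, , 1] <- 1
  rc <- color_channels(red)
  expect_equal(rc[1, 1, ], c(red = 1, green = 0, blue = 0), ignore_attr = TRUE)
  gray <- array(0.3, c(2, 2, 3))
  expect_true(all(color_channels(gray) == 0.3))
})

test_that("semantic channels prefer oracle masks and fail without detectors", {
  fr <- array(runif(20 * 30 * 3), c(20, 30, 3))
  fmask <- matrix(FALSE, 20, 30); fmask[3:5, 4:6] <- TRUE
  pmask <- matrix(FALSE, 20, 30)
  ch <- semantic_channels(fr, masks = list(face = fmask, person = pmask))
  expect_equal(ch[, , "face"], fmask * 1, ignore_attr = TRUE)
  expect_true(all(ch[, , "people"] == 0))

  # a stub detector's band shows up only where it scores
  stub <- function(frame) {
    m <- matrix(0, nrow(frame), ncol(frame)); m[7:9, ] <- 1; m
  }
  ch2 <- semantic_channels(fr, masks = list(face = fmask, person = pmask),
                           detectors = list(horizon = stub))
  expect_true(all(ch2[7:9, , "horizon"] == 1))
  expect_true(all(ch2[-(7:9), , "horizon"] == 0))

  expect_error(semantic_channels(fr, masks = NULL, detectors = list()),
               "no detector")
})

test_that("geometry channels encode normalised distances and scene flags", {
  g <- geometry_channels(c(200, 350), side = "left")
  # centre pixel of the frame scores zero, the far corner scores one
  expect_equal(unname(g[101, 176, "dist_frame_center"]), 0)
  expect_equal(max(g[, , "dist_frame_center"]), 1)
  expect_equal(unname(g[1, 1, "dist_frame_center"]), 1)
  # biological flag marks the left half
  expect_true(all(g[, 1:175, "flag_biological"] == 1))
  expect_true(all(g[, 176:350, "flag_biological"] == 0))
  expect_true(all(g[, , "flag_biological"] + g[, , "flag_geometric"] == 1))
  # scene-centre distance is zero at each half's centre pixel
  expect_equal(unname(g[101, 88, "dist_scene_center"]), 0)
  expect_equal(unname(g[101, 263, "dist_scene_center"]), 0)
  expect_true(all(g[, , "dist_scene_center"] <= 1))

  # left-right flip composed with a side swap leaves the flags invariant
  gr <- geometry_channels(c(200, 350), side = "right")
  expect_equal(g[, , "flag_biological"], gr[, 350:1, "flag_biological"])
  expect_equal(g[, , "dist_scene_center"], gr[, 350:1, "dist_scene_center"])
})

test_that("motion channel matches the estimator and zero conventions", {
  fr <- tiny_prep()$frames[[3]]
  prev <- tiny_prep()$frames[[2]]
  mc <- motion_channel(prev, fr)
  luma <- function(f) 0.299 * f[, , 1] + 0.587 * f[, , 2] + 0.114 * f[, , 3]
  expect_equal(mc[, , 1], abs(luma(fr) - luma(prev)))
  expect_true(all(motion_channel(NULL, fr) == 0))
  expect_true(all(motion_channel(fr, fr) == 0))

  # a single moved block leaves the rest of the difference map at zero
  a <- matrix(0.1, 30, 40); b <- a; b[10:15, 20:25] <- 0.9
  mm <- motion_channel(a, b)[, , 1]
  expect_true(all(mm[-(10:15), ] == 0))
  expect_true(all(mm[10:15, 20:25] > 0))
})

test_that("frame-set features are the pixelwise mean of member stacks", {
  s1 <- array(0, c(4, 5, 28)); s2 <- array(1, c(4, 5, 28))
  dimnames(s1) <- dimnames(s2) <- list(NULL, NULL, vam_channels())
  expect_true(all(frameset_features(list(s1, s2)) == 0.5))
  expect_equal(unclass(frameset_features(list(s1))), unclass(s1),
               ignore_attr = TRUE)

  set.seed(2)
  stacks <- replicate(3, array(runif(4 * 5 * 28), c(4, 5, 28)), simplify = FALSE)
  got <- frameset_features(stacks)
  oracle <- array(0, c(4, 5, 28))
  for (i in 1:4) for (j in 1:5) for (k in 1:28)
    oracle[i, j, k] <- mean(c(stacks[[1]][i, j, k], stacks[[2]][i, j, k],
                              stacks[[3]][i, j, k]))
  expect_equal(unclass(got), oracle, ignore_attr = TRUE)
  expect_error(frameset_features(list()), "at least one")
})

test_that("training vectors copy stack values and labels", {
  stack <- tiny_stack()
  set.seed(9)
  coords <- data.frame(row = sample(0:199, 700, TRUE),
                       col = sample(0:349, 700, TRUE),
                       class = rep(c(1L, 0L), each = 350))
  pv <- build_training_vectors(stack, coords)
  expect_identical(nrow(pv$x), 700L)
  expect_identical(sum(pv$y == 1), 350L)
  i <- 17
  expect_equal(pv$x[i, ], stack[coords$row[i] + 1, coords$col[i] + 1, ],
               ignore_attr = TRUE)
  bad <- data.frame(row = 200L, col = 0L, class = 1L)
  expect_error(build_training_vectors(stack, bad), "bounds")
})
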