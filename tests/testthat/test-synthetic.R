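test_that("stimulus frame count and region masks follow the manifest", {
  m <- scene_manifest(n_segments = 9, frames_per_segment = 60, fps = 10,
                      screen_size = c(135, 240))
  stim <- generate_stimulus(m, seed = 3)
  expect_length(stim$frames, 540)

  # biological-region mask equals the manifest's half for every frame of
  # the segment
  mid <- 120
  seg1 <- m$segments[1, ]
  side1 <- seg1$biological_side
  for (f in c(seg1$start_frame, seg1$end_frame)) {
    bm <- stim$masks$biological[[f]]
    if (side1 == "left") {
      expect_true(all(bm[, 1:mid]) && !any(bm[, (mid + 1):240]))
    } else {
      expect_true(all(bm[, (mid + 1):240]) && !any(bm[, 1:mid]))
    }
    expect_identical(stim$masks$geometric[[f]], !bm)
  }
  # frames at declared size, 8-bit quantised, in [0,1]
  expect_identical(dim(stim$frames[[1]]), c(135L, 240L, 3L))
  expect_true(all(stim$frames[[5]] >= 0 & stim$frames[[5]] <= 1))
  expect_equal(stim$frames[[5]], round(stim$frames[[5]] * 255) / 255)
})

test_that("generators are pure functions of (config, seed)", {
  m <- tiny_manifest()
  s1 <- generate_stimulus(m, seed = 9)
  s2 <- generate_stimulus(m, seed = 9)
  expect_identical(s1, s2)
  s3 <- generate_stimulus(m, seed = 10)
  expect_false(identical(s1$frames[[1]], s3$frames[[1]]))

  g1 <- generate_gaze(s1, phenotype_params(), 120, "a", seed = 4)
  g2 <- generate_gaze(s1, phenotype_params(), 120, "a", seed = 4)
  expect_identical(g1, g2)
})

test_that("invalid manifests are rejected", {
  expect_error(scene_manifest(n_segments = 0), "at least one segment")
  expect_error(scene_manifest(biological_side = c("left", "up")))
  expect_error(scene_manifest(n_segments = 3,
                              biological_side = c("left", "right")),
               "every segment")
  expect_error(generate_stimulus(list()), "manifest")
})

test_that("gaze side preference follows p_geometric", {
  stim <- tiny_stimulus()
  m <- stim$manifest

  # degenerate probability: every sample on the geometric half
  g <- generate_gaze(stim, phenotype_params(p_geometric = 1, dropout_rate = 0,
                                            center_bias_sigma = 20),
                     sampling_rate = 120, subject_id = "s", seed = 1)
  frame <- pmin(floor(g$timestamp_ms / 1000 * m$fps) + 1, length(stim$frames))
  bio_left <- gazevam:::frame_side(m, frame) == "left"
  on_geo <- ifelse(bio_left, g$gaze_x_px >= 120, g$gaze_x_px < 120)
  expect_true(all(on_geo))

  # binomial check at the fixation level: draw one fixation per tick so the
  # samples are independent and the exact binomial tolerance applies
  p <- 0.3
  rate <- 2000  # 5 s of stimulus -> 10000 independent samples
  gp <- generate_gaze(stim, phenotype_params(p_geometric = p, dropout_rate = 0,
                                             fixation_hz = rate,
                                             center_bias_sigma = 20),
                      sampling_rate = rate, subject_id = "s", seed = 2)
  expect_gte(nrow(gp), 10000)
  frame <- pmin(floor(gp$timestamp_ms / 1000 * m$fps) + 1, length(stim$frames))
  bio_left <- gazevam:::frame_side(m, frame) == "left"
  on_geo <- ifelse(bio_left, gp$gaze_x_px >= 120, gp$gaze_x_px < 120)
  tol <- 4 * sqrt(p * (1 - p) / nrow(gp))
  expect_lt(abs(mean(on_geo) - p), tol)

  # dropout removes ticks entirely
  g0 <- generate_gaze(stim, phenotype_params(dropout_rate = 1), 120, "s",
                      seed = 3)
  expect_identical(nrow(g0), 0L)

  # samples within screen bounds
  g <- generate_gaze(stim, phenotype_params(center_bias_sigma = 200), 120,
                     "s", seed = 4)
  expect_true(all(g$gaze_x_px >= 0 & g$gaze_x_px < 240))
  expect_true(all(g$gaze_y_px >= 0 & g$gaze_y_px < 135))
})

test_that("phenotype parameters are validated", {
  expect_error(phenotype_params(p_geometric = 1.2), "\\[0, 1\\]")
  expect_error(phenotype_params(center_bias_sigma = 0), "positive")
  expect_error(phenotype_params(dropout_rate = -0.1), "\\[0, 1\\]")
})

test_that("fixtures round-trip losslessly through the package readers", {
  m <- scene_manifest(n_segments = 2, frames_per_segment = 3, fps = 10,
                      screen_size = c(40, 64))
  stim <- generate_stimulus(m, seed = 5)
  g <- generate_gaze(tiny_stimulus(), phenotype_params(dropout_rate = 0.2),
                     120, "kid_01", seed = 6)
  outdir <- withr::local_tempdir()
  write_fixtures(stim, list(kid_01 = g), outdir)

  m2 <- read_manifest(file.path(outdir, "manifest.yaml"))
  expect_identical(m2, m)
  g2 <- read_gaze_tsv(file.path(outdir, "gaze", "kid_01.tsv"))
  expect_identical(g2$timestamp_ms, g$timestamp_ms)
  expect_identical(g2$gaze_x_px, g$gaze_x_px)
  expect_identical(g2$gaze_y_px, g$gaze_y_px)
  expect_identical(g2$validity, g$validity)

  stim2 <- read_stimulus(outdir)
  expect_equal(stim2$frames, stim$frames)
  expect_identical(stim2$masks, stim$masks)

  expect_error(write_fixtures(stim, list(), "/nonexistent/dir/xyz"),
               "/nonexistent/dir/xyz")
})
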