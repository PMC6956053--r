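test_that("preprocess stretches contrast and collapses bit depth and color", {
  m <- matrix(50, 4, 4)
  expect_equal(preprocess_frame(m), m)  # constant image is a no-op
  m2 <- matrix(c(10, 60, 110, 10), 2, 2)
  out <- preprocess_frame(m2)
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  expect_equal(out[2, 1], (60 - 10) / 100 * 255)
  # 8- vs 16-bit input give identical stretched output
  base <- matrix(runif(100, 0.2, 0.9), 10, 10)
  expect_equal(preprocess_frame(round(base * 255)),
               preprocess_frame(round(base * 255) * 257 / 257))
  rgb <- array(rep(base, 3), dim = c(10, 10, 3))
  expect_equal(preprocess_frame(rgb), preprocess_frame(base))
})

test_that("segmentation downstream is invariant to the input bit depth", {
  st <- generate_image_stack(small_imaging_scenario(seed = 3), 4)
  f8 <- round(st$frames[[2]] * 255)        # 8-bit quantization
  f16 <- round(st$frames[[2]] * 65535)     # 16-bit quantization
  thr8 <- texture_threshold(preprocess_frame(f8))
  thr16 <- texture_threshold(preprocess_frame(f16))
  m8 <- segment_bacteria(preprocess_frame(f8), threshold = thr8)
  m16 <- segment_bacteria(preprocess_frame(f16), threshold = thr16)
  expect_gt(sum(m8 == m16) / length(m8), 0.99)
})

test_that("segmentation is invariant to affine intensity changes", {
  st <- generate_image_stack(small_imaging_scenario(seed = 5), 4)
  f <- st$frames[[3]]
  m1 <- segment_bacteria(preprocess_frame(f), percentile_p = 70)
  m2 <- segment_bacteria(preprocess_frame(2.5 * f + 17), percentile_p = 70)
  expect_equal(m1, m2)
})

test_that("border detection reads a two-line fixture and rejects blanks", {
  set.seed(8)
  frame <- matrix(200 + rnorm(300 * 400, sd = 2), 300, 400)
  frame[20, ] <- 10
  frame[260, ] <- 10
  g <- detect_channel_borders(frame)
  expect_equal(g$width_px, 240, tolerance = 1)
  expect_equal(g$inclination_deg, 0, tolerance = 0.3)
  expect_equal(unname(g$weighted_center["row"]), 140, tolerance = 1.5)

  blank <- matrix(128 + rnorm(300 * 400), 300, 400)
  expect_error(detect_channel_borders(blank), "failed")
})

test_that("rotation round trip recovers border positions within 1 px", {
  st <- generate_image_stack(imaging_scenario(seed = 2, noise_sd = 0.01), 3)
  f1 <- preprocess_frame(st$frames[[1]])
  g0 <- detect_channel_borders(f1)
  base_walls <- range(which(rowMeans(rectify_and_crop(f1, g0)) < 100))
  for (th in c(-10, -5.3, 3, 8, 10)) {
    fr <- rotate_frame(f1, th)
    g <- detect_channel_borders(fr)
    expect_equal(g$inclination_deg, -th, tolerance = 0.15)
    expect_equal(g$width_px, g0$width_px, tolerance = 1)
    walls <- range(which(rowMeans(rectify_and_crop(fr, g)) < 100))
    expect_lte(max(abs(walls - base_walls)), 1)
  }
})

test_that("rectified crop follows the weighted center", {
  st <- generate_image_stack(small_imaging_scenario(seed = 6), 3)
  f1 <- preprocess_frame(st$frames[[1]])
  g <- detect_channel_borders(f1)
  c1 <- rectify_and_crop(f1, g)
  # identity rotation: crop equals the corresponding row slice of the input
  half <- g$width_px / 2
  r1 <- floor(g$weighted_center[1] - half) - 6L
  r2 <- ceiling(g$weighted_center[1] + half) + 6L
  expect_equal(c1, f1[r1:r2, ])
  # displacing the center shifts the crop window accordingly
  g2 <- g
  g2$weighted_center[1] <- g$weighted_center[1] + 10
  c2 <- rectify_and_crop(f1, g2)
  expect_equal(c2, f1[(r1 + 10):(r2 + 10), ])
  # crop beyond the frame bounds is padded with the median
  g3 <- g
  g3$weighted_center[1] <- 4
  expect_no_error(rectify_and_crop(f1, g3))
})

test_that("colonized fraction is exact arithmetic on binary masks", {
  expect_equal(colonized_fraction(matrix(1L, 5, 5)), 100)
  expect_equal(colonized_fraction(matrix(0L, 5, 5)), 0)
  mask <- matrix(0L, 240, 1200)
  mask[seq_len(72000)] <- 1L
  expect_equal(colonized_fraction(mask), 25)
  expect_error(colonized_fraction(matrix(2, 2, 2)), "binary")
  expect_error(colonized_fraction(matrix(integer(0), 0, 0)), "empty")
})

test_that("mask values are binary and bacteria-free frames hit the offset", {
  st <- generate_image_stack(small_imaging_scenario(
    front_arrival_time_s = Inf, seed = 7), 4)
  f <- preprocess_frame(st$frames[[1]])
  thr <- texture_threshold(f)
  m <- segment_bacteria(preprocess_frame(st$frames[[3]]), threshold = thr)
  expect_true(all(m %in% c(0L, 1L)))
  expect_equal(colonized_fraction(m), 30, tolerance = 2)
})

test_that("fully colonized frames segment above 95% of the crop", {
  sc <- small_imaging_scenario(front_arrival_time_s = 0,
                               colonization_duration_s = 1, seed = 8)
  st <- generate_image_stack(sc, 4)
  ref <- generate_image_stack(small_imaging_scenario(
    front_arrival_time_s = Inf, seed = 8), 2)
  g <- detect_channel_borders(preprocess_frame(ref$frames[[1]]))
  ref_crop <- rectify_and_crop(preprocess_frame(ref$frames[[1]]), g)
  thr <- texture_threshold(ref_crop)
  crop <- rectify_and_crop(preprocess_frame(st$frames[[3]]), g)
  m <- segment_bacteria(crop, threshold = thr)
  expect_gte(colonized_fraction(m) / 100, 0.95)
})

test_that("growth phases are extracted per contract", {
  # flat curve at 30%: lag-only, offset reported
  flat <- extract_growth_phases(0:9 * 600, rep(30, 10) + c(0, 0.1) )
  expect_false(flat$detected)
  expect_equal(flat$offset_pct, 30, tolerance = 0.2)
  # monotone step 30 -> 100 in one frame: duration = one frame interval
  pct <- c(30, 30, 30, 100, 100, 100)
  step <- extract_growth_phases(0:5 * 600, pct)
  expect_true(step$detected)
  expect_equal(step$colonization_duration_s, 600, tolerance = 30)
  expect_error(extract_growth_phases(c(0, 600), c(1, 2)), ">= 4")
})

test_that("end-to-end stack analysis recovers duration and offset", {
  st <- generate_image_stack(imaging_scenario(seed = 31), 15)
  res <- analyze_stack(st)
  expect_equal(res$curve$offset_pct, 30, tolerance = 2)
  expect_equal(res$curve$colonization_duration_s, 3900, tolerance = 600)
  expect_equal(res$geometry$width_px, 240, tolerance = 4)
  # measured fractions are monotone up to one small noise dip
  dips <- diff(res$colonized_pct)
  expect_lte(sum(dips < -2), 0)
})

test_that("between-segment lag reflects shifted arrival times", {
  mk <- function(arrival, seed) {
    analyze_stack(generate_image_stack(small_imaging_scenario(
      front_arrival_time_s = arrival, seed = seed), 14))$curve
  }
  a <- mk(2400, 21)
  b <- mk(3000, 22)
  expect_equal(between_segment_lag(a, a), 0)
  expect_equal(between_segment_lag(a, b), 600, tolerance = 600)
  flat <- extract_growth_phases(0:9 * 600, rep(30, 10) + c(0, 0.1))
  expect_error(between_segment_lag(a, flat), "detected")
})

test_that("segment overlap width follows the mask agreement band", {
  full <- matrix(1L, 40, 500)
  expect_equal(check_segment_overlap(full, full, 100, 4), 100)
  expect_equal(check_segment_overlap(full, 1L - full, 100, 4), 0)
  # front that crossed segment A and covers 60 um of segment B's start
  a <- matrix(1L, 40, 500)
  b <- matrix(0L, 40, 500)
  b[, seq_len(240)] <- 1L  # 60 um at 4 px/um
  ov <- check_segment_overlap(a, b, 100, 4)
  expect_equal(ov, 60, tolerance = 1)
  expect_true(ov >= 15 && ov <= 100)
})
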