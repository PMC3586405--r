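test_that("glottal segmentation recovers the exact rendered pixel count", {
  out <- synth_strobe_sequence(strobe_spec(gap_area_px = 1234))
  seg <- segment_glottal_space(out$frames[[1]])
  expect_true(seg$detected)
  expect_identical(seg$area_px, 1234L)
  expect_identical(sum(seg$mask), 1234L)
})

test_that("segmentation is invariant to a uniform intensity offset", {
  out <- synth_strobe_sequence(strobe_spec(gap_area_px = 900))
  f1 <- out$frames[[1]]
  f2 <- strobe_frame(f1$image + 30)
  expect_identical(segment_glottal_space(f1)$mask,
                   segment_glottal_space(f2)$mask)
})

test_that("a uniform bright frame yields no-glottis-detected", {
  seg <- segment_glottal_space(strobe_frame(matrix(200, 80, 80)))
  expect_false(seg$detected)
  expect_identical(seg$area_px, 0L)
})

test_that("segmentation stays within 5% under pixel noise", {
  out <- synth_strobe_sequence(strobe_spec(gap_area_px = 1200,
                                           noise_sd = 0.05 * 255, seed = 4))
  seg <- segment_glottal_space(out$frames[[1]], closing = TRUE)
  expect_lt(abs(seg$area_px - 1200) / 1200, 0.05)
})

test_that("ROI restricts the search region", {
  out <- synth_strobe_sequence(strobe_spec(gap_area_px = 800))
  img <- out$frames[[1]]$image
  img[1:10, 1:60] <- 0   # dark clutter outside the ROI
  with_roi <- strobe_frame(img, roi = c(20, 30, 90, 100))
  expect_identical(segment_glottal_space(with_roi)$area_px, 800L)
})

test_that("lesion size is recovered within 10% and sides map to the patient", {
  # a bump on the image-right edge is on the PATIENT's left fold
  out <- synth_strobe_sequence(strobe_spec(
    shape = "vgap", edge_angles_deg = c(-12, 12), gap_height = 100,
    lesion_side = "right", lesion_px = 150))
  mask <- segment_glottal_space(out$frames[[1]])$mask
  sz <- lesion_sizes(out$frames[[1]], mask)
  expect_equal(unname(sz["right_size_px"]), 0)
  expect_lt(abs(sz["left_size_px"] - 150) / 150, 0.10)

  # lesion-free construction
  free <- synth_strobe_sequence(strobe_spec(
    shape = "vgap", edge_angles_deg = c(-12, 12), gap_height = 100))
  szf <- lesion_sizes(free$frames[[1]],
                      segment_glottal_space(free$frames[[1]])$mask)
  expect_equal(unname(szf), c(0, 0))
  # and on the curved elliptical gap
  ell <- synth_strobe_sequence(strobe_spec(gap_area_px = 1500))
  sze <- lesion_sizes(ell$frames[[1]],
                      segment_glottal_space(ell$frames[[1]])$mask)
  expect_equal(unname(sze), c(0, 0))
})

test_that("mirroring the image swaps right and left lesion sizes", {
  out <- synth_strobe_sequence(strobe_spec(
    shape = "vgap", edge_angles_deg = c(-12, 12), gap_height = 100,
    lesion_side = "left", lesion_px = 150))
  f <- out$frames[[1]]
  mask <- segment_glottal_space(f)$mask
  sz <- lesion_sizes(f, mask)
  fm <- strobe_frame(f$image[, ncol(f$image):1])
  szm <- lesion_sizes(fm, segment_glottal_space(fm)$mask)
  expect_equal(unname(sz["right_size_px"]), unname(szm["left_size_px"]))
  expect_equal(unname(sz["left_size_px"]), unname(szm["right_size_px"]))
  # the --mirrored flag performs the same swap
  expect_equal(unname(lesion_sizes(f, mask, mirrored = TRUE)),
               rev(unname(sz)))
})

test_that("deviation angle matches constructed fold geometry", {
  v30 <- synth_strobe_sequence(strobe_spec(shape = "vgap",
                                           edge_angles_deg = c(-15, 15)))
  m <- segment_glottal_space(v30$frames[[1]])$mask
  expect_equal(deviation_angle(m), 30, tolerance = 0.5)

  par <- synth_strobe_sequence(strobe_spec(shape = "vgap",
                                           edge_angles_deg = c(8, 8),
                                           apex_width = 24, gap_height = 90))
  expect_equal(deviation_angle(segment_glottal_space(par$frames[[1]])$mask),
               0, tolerance = 0.5)

  # rotating the whole scene by 10 degrees leaves the inter-edge angle
  rot <- synth_strobe_sequence(strobe_spec(shape = "vgap",
                                           edge_angles_deg = c(-5, 25)))
  expect_equal(deviation_angle(segment_glottal_space(rot$frames[[1]])$mask),
               30, tolerance = 1)

  single_row <- matrix(FALSE, 20, 20)
  single_row[10, 5:15] <- TRUE
  expect_error(deviation_angle(single_row), class = "phl_geometry")
})

test_that("movement index combines amplitude and regularity", {
  # period 12 frames, 36 frames: the sampled sinusoid hits its extremes,
  # so areas oscillate exactly between 400 and 800 px
  out <- synth_strobe_sequence(strobe_spec(gap_area_px = 600, n_frames = 36,
                                           mod_amplitude = 1 / 3,
                                           mod_period = 12))
  mv <- movement_index(out$frames)
  expect_equal(mv$amplitude, 1 / 3, tolerance = 1e-6)
  expect_gt(mv$regularity, 0.97)
  expect_equal(mv$movement_index, 1 / 3, tolerance = 0.03)

  # constant sequence -> exactly 0
  const <- synth_strobe_sequence(strobe_spec(gap_area_px = 600,
                                             n_frames = 6))
  expect_identical(movement_index(const$frames)$movement_index, 0)

  # shuffling frames of a sinusoidal sequence lowers regularity
  shuffled <- out$frames[withr::with_seed(11, sample(36))]
  mvs <- movement_index(shuffled)
  expect_lt(mvs$regularity, mv$regularity)

  expect_error(movement_index(out$frames[1:3]),
               class = "phl_insufficient_frames")
})

test_that("movement index is bounded and zero only for constant series", {
  for (seed in 1:4) {
    out <- synth_strobe_sequence(strobe_spec(
      gap_area_px = 500, n_frames = 16, mod_amplitude = 0.2 * seed / 4,
      mod_period = 7, mod_phase_sd = 0.3, seed = seed))
    mc <- phonolaryn:::movement_components(out$ground_truth$gap_area_px)
    expect_gte(mc$movement_index, 0)
    expect_lte(mc$movement_index, 1)
    if (length(unique(out$ground_truth$gap_area_px)) > 1) {
      expect_gt(mc$movement_index, 0)
    }
  }
})

test_that("strobe_measures aggregates the sequence", {
  out <- synth_strobe_sequence(strobe_spec(
    shape = "vgap", edge_angles_deg = c(-15, 15), gap_height = 90,
    lesion_side = "right", lesion_px = 120))
  sm <- strobe_measures(out$frames)
  expect_gt(sm$glottal_area_px, 0)
  expect_gt(sm$left_size_px, 0)
  expect_equal(sm$deviation_deg, 30, tolerance = 1)
  expect_true(sm$closure_type %in%
                c("complete", "hourglass", "posterior", "irregular",
                  "anterior", "longitudinal"))
  expect_error(strobe_measures(list(strobe_frame(matrix(200, 40, 40)))),
               class = "phl_invalid_input")
})
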