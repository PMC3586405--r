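test_that("pitch tracking recovers pure tones within 1 Hz across the band", {
  for (freq in c(80, 150, 220, 350, 500)) {
    tr <- estimate_pitch_track(make_sine(freq, duration = 0.5))
    f0 <- tr$f0_values[tr$f0_values > 0]
    expect_gt(length(f0), 5)
    expect_lt(abs(mean(f0) - freq), 1)
  }
})

test_that("silence and too-short input are handled", {
  sr <- 16000
  silent <- voice_recording(numeric(8000), sr)
  tr <- estimate_pitch_track(silent)
  expect_true(all(tr$f0_values == 0))
  expect_error(estimate_pitch_track(voice_recording(numeric(100), sr)),
               class = "phl_invalid_input")
  expect_error(estimate_pitch_track(make_sine(200), f0_min = 300,
                                    f0_max = 200),
               class = "phl_invalid_input")
})

test_that("clean synthetic voice F0 is recovered within 0.5%", {
  v <- synth_voice(voice_spec(f0 = 178.12, duration = 1.2, seed = 3))
  tr <- estimate_pitch_track(v$recording)
  f0 <- mean(tr$f0_values[tr$f0_values > 0])
  expect_lt(abs(f0 - 178.12) / 178.12, 0.005)
})

test_that("analysis segment is centered on the voiced middle portion", {
  # 3 s fully voiced at 200 Hz, 50 cycles -> 0.25 s centered near 1.5 s
  seg <- select_analysis_segment(make_sine(200, duration = 3))
  expect_equal(unname(diff(seg)), 0.25, tolerance = 0.01)
  expect_equal(unname(mean(seg)), 1.5, tolerance = 0.05)
  # 1 s at 100 Hz -> 0.5 s
  seg2 <- select_analysis_segment(make_sine(100, duration = 1))
  expect_equal(unname(diff(seg2)), 0.5, tolerance = 0.02)
  # the one-second cap binds for long low-pitched targets
  seg3 <- select_analysis_segment(make_sine(100, duration = 3),
                                  target_cycles = 200)
  expect_lte(diff(seg3), 1.0 + 1e-9)
  expect_error(select_analysis_segment(make_noise()),
               class = "phl_no_voicing")
})

test_that("cycle extraction marks pure-tone periods exactly", {
  rec <- make_sine(100, duration = 1)
  tr <- estimate_pitch_track(rec)
  cy <- extract_cycles(rec, tr, c(0.25, 0.75))
  expect_true(abs(length(cy$period_durations) - 50) <= 1)
  expect_true(all(abs(cy$period_durations - 0.010) < 1e-4))
})

test_that("cycle extraction resolves alternating periods", {
  v <- synth_voice(voice_spec(f0 = 200, jitter_pct = 2, duration = 1,
                              seed = 3, pattern = "alternating"))
  tr <- estimate_pitch_track(v$recording)
  seg <- select_analysis_segment(v$recording, track = tr)
  cy <- extract_cycles(v$recording, tr, seg)
  ptp <- 100 * (max(cy$period_durations) - min(cy$period_durations)) /
    mean(cy$period_durations)
  expect_equal(ptp, 2, tolerance = 0.25)
})

test_that("unvoiced material yields insufficient-cycles errors", {
  rec <- make_noise()
  tr <- estimate_pitch_track(rec)
  expect_error(extract_cycles(rec, tr, c(0.1, 0.5)),
               class = "phl_insufficient_cycles")
})

test_that("jitter follows its defining formula", {
  expect_equal(jitter_local(cycle_sequence(rep(0.005, 20), rep(1, 20))), 0)
  alt <- rep(c(4.95e-3, 5.05e-3), 10)
  expect_equal(jitter_local(cycle_sequence(alt, rep(1, 20))),
               100 * mean(abs(diff(alt))) / mean(alt))
  expect_equal(jitter_local(cycle_sequence(alt, rep(1, 20))),
               2, tolerance = 0.06)  # 19 of 20 diffs are 0.1 ms
  expect_error(jitter_local(cycle_sequence(c(1, 2) * 1e-3, c(1, 1))),
               class = "phl_insufficient_cycles")
})

test_that("shimmer follows its formula and is gain invariant", {
  expect_equal(shimmer_local(cycle_sequence(rep(5e-3, 10), rep(0.8, 10))), 0)
  alt <- rep(c(1.0, 1.1), 10)
  s <- shimmer_local(cycle_sequence(rep(5e-3, 20), alt))
  expect_equal(s, 100 * mean(abs(diff(alt))) / mean(alt))
  expect_equal(s, 100 * 0.1 / 1.05, tolerance = 0.01)
  s3 <- shimmer_local(cycle_sequence(rep(5e-3, 20), 3 * alt))
  expect_equal(s, s3)
  expect_error(shimmer_local(cycle_sequence(rep(5e-3, 5), c(1, 1, 0, 1, 1))),
               class = "phl_invalid_input")
})

test_that("jitter is invariant under time scaling with adjusted sample rate", {
  v <- synth_voice(voice_spec(f0 = 160, jitter_pct = 1.5, duration = 1.2,
                              seed = 8))
  measure <- function(rec) {
    tr <- estimate_pitch_track(rec)
    jitter_local(extract_cycles(rec, tr,
                                select_analysis_segment(rec, track = tr)))
  }
  j1 <- measure(v$recording)
  half_speed <- voice_recording(v$recording$samples,
                                v$recording$sample_rate / 2)
  j2 <- measure(half_speed)
  expect_equal(j1, j2, tolerance = 0.1)
})

test_that("HNR caps on pure tones, reads ~0 dB at equal noise power, and is monotone", {
  rec <- make_sine(220, duration = 0.8)
  tr <- estimate_pitch_track(rec)
  seg <- select_analysis_segment(rec, track = tr)
  expect_gte(hnr(rec, seg, tr), 40)

  v0 <- synth_voice(voice_spec(f0 = 180, hnr_db = 0, duration = 1.2,
                               seed = 3))
  tr0 <- estimate_pitch_track(v0$recording)
  seg0 <- select_analysis_segment(v0$recording, track = tr0)
  expect_lt(abs(hnr(v0$recording, seg0, tr0)), 1)

  vals <- vapply(c(30, 22, 15, 9, 4), function(h) {
    v <- synth_voice(voice_spec(f0 = 180, hnr_db = h, duration = 1.2,
                                seed = 5))
    tr <- estimate_pitch_track(v$recording)
    hnr(v$recording, select_analysis_segment(v$recording, track = tr), tr)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))

  expect_error(hnr(make_noise(), c(0.1, 0.5),
                   estimate_pitch_track(make_noise())),
               class = "phl_no_voicing")
})

test_that("frequency range spans the low and high vowels", {
  low <- synth_voice(voice_spec(f0 = 98, duration = 0.8, seed = 2),
                     kind = "low_a")
  high <- synth_voice(voice_spec(f0 = 392, duration = 0.8, seed = 2),
                      kind = "high_a")
  fr <- frequency_range(low$recording, high$recording)
  expect_equal(unname(fr["f_low"]), 98, tolerance = 1)
  expect_equal(unname(fr["f_high"]), 392, tolerance = 1)
  expect_equal(unname(fr["range"]), 294, tolerance = 1.5)

  same <- synth_voice(voice_spec(f0 = 200, duration = 0.8, seed = 4))
  r1 <- same$recording; r1$kind <- "low_a"
  r2 <- same$recording; r2$kind <- "high_a"
  expect_equal(unname(frequency_range(r1, r2)["range"]), 0, tolerance = 0.2)

  silent <- voice_recording(numeric(30000), 44100, kind = "high_a")
  expect_error(suppressWarnings(frequency_range(r1, silent)),
               class = "phl_no_voicing")
  # swapped inputs are corrected with a warning
  lo <- low$recording; lo$kind <- "high_a"
  hd <- high$recording; hd$kind <- "low_a"
  expect_warning(fr2 <- frequency_range(hd, lo), "swap")
  expect_equal(unname(fr2["range"]), 294, tolerance = 1.5)
})

test_that("acoustic report on a clean vowel shows no perturbation", {
  v <- synth_voice(voice_spec(f0 = 180, duration = 1.2, seed = 2))
  rep <- acoustic_report(v$recording)
  expect_lt(rep$jitter_pct, 0.05)
  expect_lt(rep$shimmer_pct, 0.05)
  expect_gte(rep$hnr_db, 40)
  expect_true(is.na(rep$freq_range_hz))
  expect_error(acoustic_report(make_noise()), class = "phl_no_voicing")
})

test_that("perturbation measures are non-negative across random voices", {
  for (seed in 1:5) {
    v <- synth_voice(voice_spec(f0 = 120 + 40 * seed,
                                jitter_pct = 0.5 * seed,
                                shimmer_pct = seed, hnr_db = 30,
                                duration = 1, seed = seed))
    tr <- estimate_pitch_track(v$recording)
    cy <- extract_cycles(v$recording, tr,
                         select_analysis_segment(v$recording, track = tr))
    expect_gte(jitter_local(cy), 0)
    expect_gte(shimmer_local(cy), 0)
  }
})
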