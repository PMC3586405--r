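test_that("narrowband spectrogram resolves tones and satisfies Parseval", {
  rec <- make_sine(200, duration = 0.4)
  sp <- narrowband_spectrogram(rec)
  binw <- sp$bin_freqs[2] - sp$bin_freqs[1]
  expect_lte(binw, 25)

  mid <- ncol(sp$magnitude) %/% 2
  peak_bin <- which.max(sp$magnitude[, mid])
  expect_lt(abs(sp$bin_freqs[peak_bin] - 200), binw)
  # energy off the 200 Hz ridge is below 1% of the total
  e <- sp$magnitude[, mid]^2
  near <- abs(sp$bin_freqs - 200) <= 3 * binw
  expect_lt(sum(e[!near]) / sum(e), 0.01)

  # two tones separated by an octave give two ridges
  sr <- 44100
  t <- seq(0, 0.4, by = 1 / sr)
  two <- voice_recording(0.4 * sin(2 * pi * 200 * t) +
                         0.4 * sin(2 * pi * 400 * t), sr)
  sp2 <- narrowband_spectrogram(two)
  e2 <- sp2$magnitude[, ncol(sp2$magnitude) %/% 2]^2
  p200 <- max(e2[abs(sp2$bin_freqs - 200) <= binw])
  p400 <- max(e2[abs(sp2$bin_freqs - 400) <= binw])
  trough <- max(e2[abs(sp2$bin_freqs - 300) <= binw])
  expect_gt(p200, 100 * trough)
  expect_gt(p400, 100 * trough)

  # Parseval: full-spectrum frame energy equals windowed time energy
  w <- sp$window
  s0 <- round(sp$frame_times[mid] * sr - length(w) / 2)
  xw <- rec$samples[(s0 + 1):(s0 + length(w))] * w
  m <- sp$magnitude[, mid]
  nfft <- sp$nfft
  full <- m[1]^2 + 2 * sum(m[2:(length(m) - 1)]^2) + m[length(m)]^2
  expect_equal(full / nfft, sum(xw^2), tolerance = 0.01)

  expect_error(narrowband_spectrogram(voice_recording(numeric(100), 44100)),
               class = "phl_invalid_input")
})

test_that("band harmonicity separates harmonic and noise-replaced bands", {
  v <- synth_voice(voice_spec(f0 = 178, duration = 1, seed = 6))
  rec <- v$recording
  tr <- estimate_pitch_track(rec)
  bh <- band_harmonicity(narrowband_spectrogram(rec), tr)
  expect_gte(bh$fractions[["F1"]], 0.9)
  expect_gte(bh$fractions[["F2"]], 0.9)
  expect_equal(bh$hf_edge, 3000)

  # replace 1000-3000 Hz with noise by FFT surgery
  x <- rec$samples
  n <- length(x)
  X <- stats::fft(x)
  fr <- (seq_len(n) - 1) * rec$sample_rate / n
  fr <- pmin(fr, rec$sample_rate - fr)
  band <- fr >= 1000 & fr <= 3000
  pw <- mean(Mod(X[band])^2)
  repl <- withr::with_seed(7, complex(
    real = stats::rnorm(sum(band)), imaginary = stats::rnorm(sum(band))
  )) * sqrt(pw / 2)
  X[band] <- repl
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  rec2 <- voice_recording(y / max(abs(y)), rec$sample_rate)
  bh2 <- band_harmonicity(narrowband_spectrogram(rec2),
                          estimate_pitch_track(rec2))
  expect_lt(bh2$fractions[["F2"]], 0.3)
  expect_gte(bh2$fractions[["F1"]], 0.8)

  # HF noise level grows monotonically with the injected HF energy
  # fraction (kept small so the voice itself stays dominant)
  X0 <- stats::fft(rec$samples)
  hf <- fr >= 3000
  e_tot <- sum(Mod(X0)^2)
  lv <- vapply(c(1e-4, 1e-3, 1e-2), function(rho) {
    Xh <- X0
    z <- withr::with_seed(8, complex(real = stats::rnorm(sum(hf)),
                                     imaginary = stats::rnorm(sum(hf))))
    Xh[hf] <- Xh[hf] + z * sqrt(rho * e_tot / sum(Mod(z)^2))
    yh <- Re(stats::fft(Xh, inverse = TRUE)) / n
    rech <- voice_recording(yh / max(abs(yh)), rec$sample_rate)
    band_harmonicity(narrowband_spectrogram(rech),
                     estimate_pitch_track(rech))$hf_noise_level
  }, numeric(1))
  expect_true(all(diff(lv) > 0))

  expect_error(band_harmonicity(narrowband_spectrogram(make_noise()),
                                estimate_pitch_track(make_noise())),
               class = "phl_no_voicing")
})

test_that("grade cascade maps the verbal definitions to grades", {
  mk <- function(f1, f2, hf) {
    structure(list(fractions = c(F1 = f1, F2 = f2, HF = 0.1),
                   hf_noise_level = hf, hf_edge = 3000,
                   bands = phonolaryn:::default_bands()),
              class = "band_harmonicity")
  }
  expect_equal(as.character(yanagihara_grade(mk(0.9, 0.9, -60))$grade),
               "Normal")
  expect_equal(as.character(yanagihara_grade(mk(0.9, 0.7, -40))$grade), "I")
  expect_equal(as.character(yanagihara_grade(mk(0.8, 0.4, -30))$grade), "II")
  expect_equal(as.character(yanagihara_grade(mk(0.6, 0.05, -20))$grade),
               "III")
  expect_equal(as.character(yanagihara_grade(mk(0.1, 0.05, -5))$grade), "IV")
})

test_that("the cascade is total and exclusive, and grades order by severity", {
  grid <- expand.grid(f1 = c(0.05, 0.3, 0.6, 0.9),
                      f2 = c(0.05, 0.3, 0.6, 0.9),
                      hf = c(-40, -20, -10))
  for (i in seq_len(nrow(grid))) {
    bh <- structure(list(fractions = c(F1 = grid$f1[i], F2 = grid$f2[i],
                                       HF = 0.1),
                         hf_noise_level = grid$hf[i], hf_edge = 3000,
                         bands = phonolaryn:::default_bands()),
                    class = "band_harmonicity")
    g <- yanagihara_grade(bh)
    expect_true(as.character(g$grade) %in%
                  c("Normal", "I", "II", "III", "IV"))
    expect_true(nzchar(g$rule))
  }
  g1 <- yanagihara_grade(structure(
    list(fractions = c(F1 = 0.9, F2 = 0.9, HF = 0.1),
         hf_noise_level = -60, hf_edge = 3000, bands = phonolaryn:::default_bands()),
    class = "band_harmonicity"))
  g4 <- yanagihara_grade(structure(
    list(fractions = c(F1 = 0.05, F2 = 0.05, HF = 0.5),
         hf_noise_level = -3, hf_edge = 3000, bands = phonolaryn:::default_bands()),
    class = "band_harmonicity"))
  expect_true(g1$grade < g4$grade)
})

test_that("clean synthetic vowels grade Normal across pitches", {
  for (f0 in c(120, 180, 240)) {
    v <- synth_voice(voice_spec(f0 = f0, duration = 1, seed = 5))
    g <- grade_recording(v$recording)
    expect_equal(as.character(g$grade), "Normal")
  }
})

test_that("a manual override grade is carried alongside the automatic one", {
  v <- synth_voice(voice_spec(f0 = 180, duration = 1, seed = 5))
  g <- grade_recording(v$recording, manual = "II")
  expect_equal(as.character(g$manual), "II")
  expect_equal(as.character(g$grade), "Normal")
})
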