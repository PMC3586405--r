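#' Narrowband magnitude spectrogram of a sustained vowel
#'
#' Short-time Fourier magnitude with a long (narrowband) Hann window so
#' that individual harmonics of the voice are resolved as horizontal
#' striations: the classical display on which hoarseness is graded. The
#' default 46 ms window at 75% overlap yields a bin spacing well under
#' 25 Hz for typical sample rates, resolving harmonics of any F0 of at
#' least 80 Hz.
#'
#' @param rec A [voice_recording()].
#' @param window_length Analysis window in seconds (default 0.046).
#' @param overlap Fractional window overlap in `[0, 1)` (default 0.75).
#' @return A `spectrogram`: `magnitude` (bins x frames, linear), `bin_freqs`
#'   (Hz), `frame_times` (s, window centers), `window_length`, `overlap`,
#'   `window` (the Hann taper), `nfft`, `sample_rate`.
#' @export
narrowband_spectrogram <- function(rec, window_length = 0.046,
                                   overlap = 0.75) {
  assert_recording(rec)
  sr <- rec$sample_rate
  # FFT-friendly window with no zero padding: FFT bins then fall on the
  # zeros of the Hann main lobe, so a harmonic's energy is confined to
  # +/- 1 bin of its frequency (padding would smear it across bins)
  w <- stats::nextn(round(window_length * sr), c(2, 3, 5))
  if (length(rec$samples) < w) {
    stop_invalid_input("recording shorter than one spectrogram window")
  }
  if (overlap < 0 || overlap >= 1) {
    stop_invalid_input("overlap must be in [0, 1)")
  }
  hop <- max(1L, round(w * (1 - overlap)))
  nfft <- w
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1))
  starts <- seq.int(1L, length(rec$samples) - w + 1L, by = hop)
  nbin <- nfft %/% 2 + 1L
  mag <- vapply(starts, function(s) {
    X <- stats::fft(c(rec$samples[s:(s + w - 1)] * taper, numeric(nfft - w)))
    Mod(X[seq_len(nbin)])
  }, numeric(nbin))
  structure(
    list(
      magnitude = mag,
      bin_freqs = (seq_len(nbin) - 1) * sr / nfft,
      frame_times = (starts - 1 + w / 2) / sr,
      window_length = window_length,
      overlap = overlap,
      window = taper,
      nfft = nfft,
      sample_rate = sr
    ),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d bins x %d frames, bin spacing %.2f Hz\n",
              nrow(x$magnitude), ncol(x$magnitude),
              x$bin_freqs[2] - x$bin_freqs[1]))
  invisible(x)
}

# Default spectral bands: first-formant region, second-formant region, and
# the high-frequency region above the 3 kHz edge of the grading scheme.
default_bands <- function(hf_edge = 3000, hf_top = 10000) {
  list(F1 = c(200, 1000), F2 = c(1000, hf_edge), HF = c(hf_edge, hf_top))
}

#' Band-wise harmonicity of a narrowband spectrogram
#'
#' Quantifies how much of each band's energy lies on the harmonic comb
#' `k * F0` predicted by the pitch track: per voiced frame, the energy in
#' bins within 1.5 bin spacings of any harmonic frequency (the extent of
#' the Hann main lobe), less the broadband floor estimated from the
#' between-harmonic bins, is divided by the total band energy; fractions
#' are averaged across frames, so a pure voice scores near 1 and pure
#' noise near 0. The
#' high-frequency noise level is the total HF-band energy relative to the
#' total spectrogram energy, in dB. These are the quantitative counterparts
#' of the verbal "harmonic components" versus "noise components" criteria
#' of spectrographic hoarseness grading.
#'
#' @param spec A [narrowband_spectrogram()] result.
#' @param track A [estimate_pitch_track()] result for the same recording.
#' @param bands Named list of `c(lo, hi)` Hz band edges: `F1`, `F2`, `HF`.
#'   The default HF band starts at the conventional 3000 Hz edge.
#' @param hf_edge High-frequency band edge in Hz used when `bands` is not
#'   supplied (default 3000).
#' @return A `band_harmonicity`: `fractions` (named, in `[0, 1]`),
#'   `hf_noise_level` (dB, relative), `hf_edge`, `bands`.
#' @export
band_harmonicity <- function(spec, track, bands = NULL, hf_edge = 3000) {
  if (is.null(bands)) {
    bands <- default_bands(hf_edge, min(10000, 0.98 * spec$sample_rate / 2))
  }
  f0_at <- stats::approx(track$frame_times, track$f0_values,
                         xout = spec$frame_times, rule = 2)$y
  voiced <- f0_at > 0 & stats::approx(track$frame_times,
                                      as.numeric(track$f0_values > 0),
                                      xout = spec$frame_times,
                                      rule = 2)$y > 0.5
  if (!any(voiced)) stop_no_voicing("no voiced frames for harmonicity")

  binw <- spec$bin_freqs[2] - spec$bin_freqs[1]
  energy <- spec$magnitude[, voiced, drop = FALSE]^2
  f0v <- f0_at[voiced]

  frac <- vapply(names(bands), function(bn) {
    lo <- bands[[bn]][1]; hi <- bands[[bn]][2]
    inband <- spec$bin_freqs >= lo & spec$bin_freqs < hi
    if (!any(inband)) return(NA_real_)
    per_frame <- vapply(seq_along(f0v), function(j) {
      # include harmonics just outside the band: their main lobes still
      # deposit harmonic (not noise) energy in the edge bins
      harm <- seq(f0v[j], hi + f0v[j], by = f0v[j])
      dist <- vapply(spec$bin_freqs[inband], function(f) {
        min(abs(f - harm))
      }, numeric(1))
      tot <- sum(energy[inband, j])
      if (tot <= 0) return(NA_real_)
      # 1.5-bin capture: the Hann main lobe of an off-center harmonic
      # extends past +/-1 bin, and its shoulders are harmonic energy.
      # Broadband noise also deposits energy inside the capture windows;
      # the between-harmonic floor estimates that contribution and is
      # subtracted so pure noise scores ~0 and a pure voice ~1.
      on_comb <- dist <= 1.5 * binw
      e <- energy[inband, j]
      floor_e <- if (any(!on_comb)) mean(e[!on_comb]) else 0
      max(sum(e[on_comb]) - floor_e * sum(on_comb), 0) / tot
    }, numeric(1))
    mean(per_frame, na.rm = TRUE)
  }, numeric(1))

  hf_band <- bands$HF
  in_hf <- spec$bin_freqs >= hf_band[1] & spec$bin_freqs < hf_band[2]
  hf_level <- 10 * log10(max(sum(energy[in_hf, ]), 1e-300) /
                         max(sum(energy), 1e-300))
  structure(
    list(fractions = frac, hf_noise_level = hf_level,
         hf_edge = bands$HF[1], bands = bands),
    class = "band_harmonicity"
  )
}

#' @export
print.band_harmonicity <- function(x, ...) {
  cat("<band_harmonicity>\n")
  for (bn in names(x$fractions)) {
    cat(sprintf("  %s harmonic fraction %.3f\n", bn, x$fractions[[bn]]))
  }
  cat(sprintf("  HF noise level %.1f dB (edge %g Hz)\n",
              x$hf_noise_level, x$hf_edge))
  invisible(x)
}

#' Default thresholds of the spectrographic grading cascade
#'
#' The verbal grade definitions are mapped to numeric cuts on the
#' band-harmonicity measures: a harmonic fraction below `mixed` counts as
#' "noise mixed with harmonics", below `predominant` as "noise predominant
#' over harmonics", below `replaced` as "completely replaced by noise";
#' HF noise counts as "intensified" above `hf_iii` dB and "further
#' intensified" above `hf_iv` dB.
#'
#' @return Named list of thresholds.
#' @export
yanagihara_thresholds <- function() {
  list(mixed = 0.8, predominant = 0.5, replaced = 0.15,
       hf_iii = -25, hf_iv = -15)
}

#' Yanagihara hoarseness grade from band harmonicity
#'
#' Deterministic rule cascade over the four classical grades, evaluated
#' from most to least severe so exactly one rule fires:
#' \describe{
#'   \item{IV}{periodic components of the first formant lost
#'     (`F1 < replaced`) with maximal high-frequency noise.}
#'   \item{III}{second formant completely replaced by noise
#'     (`F2 < replaced`) with intensified high-frequency noise.}
#'   \item{II}{noise predominant over harmonics in the second-formant
#'     region (`F2 < predominant`).}
#'   \item{I}{irregular harmonic components mixed with noise in the
#'     formant regions (`min(F1, F2) < mixed`).}
#'   \item{Normal}{otherwise.}
#' }
#'
#' @param bh A [band_harmonicity()] result.
#' @param thresholds Numeric cuts, see [yanagihara_thresholds()].
#' @return A `yanagihara_grade`: `grade` (ordered factor
#'   Normal < I < II < III < IV), `rule` (which rule fired), `bh`.
#' @export
yanagihara_grade <- function(bh, thresholds = yanagihara_thresholds()) {
  if (!inherits(bh, "band_harmonicity")) {
    stop_invalid_input("expected a band_harmonicity object")
  }
  f1 <- bh$fractions[["F1"]]
  f2 <- bh$fractions[["F2"]]
  hf <- bh$hf_noise_level
  th <- thresholds
  if (f1 < th$replaced && hf >= th$hf_iv) {
    g <- "IV"; rule <- "first-formant periodicity lost, HF noise maximal"
  } else if (f2 < th$replaced && hf >= th$hf_iii) {
    g <- "III"; rule <- "second formant replaced by noise, HF noise intensified"
  } else if (f2 < th$predominant) {
    g <- "II"; rule <- "noise predominant over harmonics in second formant"
  } else if (min(f1, f2) < th$mixed) {
    g <- "I"; rule <- "irregular harmonics mixed with noise"
  } else {
    g <- "Normal"; rule <- "harmonic structure intact"
  }
  structure(
    list(grade = grade_factor(g), rule = rule, bh = bh),
    class = "yanagihara_grade"
  )
}

grade_levels <- c("Normal", "I", "II", "III", "IV")

grade_factor <- function(g) {
  factor(g, levels = grade_levels, ordered = TRUE)
}

#' @export
print.yanagihara_grade <- function(x, ...) {
  cat(sprintf("<yanagihara_grade> %s (%s)\n", as.character(x$grade), x$rule))
  invisible(x)
}

#' Grade a sustained vowel recording
#'
#' Convenience wrapper: pitch track, narrowband spectrogram, band
#' harmonicity, grade. A manual override grade (clinician judgement) can
#' be supplied and is recorded alongside the automatic one.
#'
#' @param rec A [voice_recording()].
#' @param manual Optional manual grade, one of
#'   `"Normal", "I", "II", "III", "IV"`; kept alongside the automatic one.
#' @param thresholds See [yanagihara_thresholds()].
#' @param ... Passed to [estimate_pitch_track()].
#' @return A `yanagihara_grade` with an extra `manual` field (`NA` when not
#'   given).
#' @export
grade_recording <- function(rec, manual = NULL,
                            thresholds = yanagihara_thresholds(), ...) {
  track <- estimate_pitch_track(rec, ...)
  spec <- narrowband_spectrogram(rec)
  out <- if (any(track$f0_values > 0)) {
    yanagihara_grade(band_harmonicity(spec, track), thresholds)
  } else {
    # no periodicity survives at all: the extreme of the most severe grade
    structure(
      list(grade = grade_factor("IV"),
           rule = "no periodic components detectable", bh = NULL),
      class = "yanagihara_grade"
    )
  }
  if (!is.null(manual)) {
    manual <- match.arg(manual, grade_levels)
    out$manual <- grade_factor(manual)
  } else {
    out$manual <- grade_factor(NA)
  }
  out
}
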