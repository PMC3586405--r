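#' Glottal cycle sequence
#'
#' Ordered per-cycle period durations (s) and peak amplitudes (linear), the
#' carrier for jitter and shimmer. Constructed by [extract_cycles()] or
#' directly from known values.
#'
#' @param period_durations Numeric vector of per-cycle periods in seconds,
#'   all positive.
#' @param peak_amplitudes Numeric vector, one peak amplitude per cycle.
#' @param peak_times Optional vector of peak times in seconds.
#' @return A `cycle_sequence` object.
#' @export
cycle_sequence <- function(period_durations, peak_amplitudes,
                           peak_times = NULL) {
  if (length(period_durations) != length(peak_amplitudes)) {
    stop_invalid_input("periods and amplitudes must have equal length")
  }
  if (any(!is.finite(period_durations)) || any(period_durations <= 0)) {
    stop_invalid_input("all period durations must be positive and finite")
  }
  structure(
    list(period_durations = as.numeric(period_durations),
         peak_amplitudes = as.numeric(peak_amplitudes),
         peak_times = peak_times),
    class = "cycle_sequence"
  )
}

#' @export
print.cycle_sequence <- function(x, ...) {
  cat(sprintf("<cycle_sequence> %d cycles, mean period %.3f ms\n",
              length(x$period_durations), 1000 * mean(x$period_durations)))
  invisible(x)
}

#' Extract glottal cycles from an analysis segment
#'
#' Cycle marks are located by peak-picking guided by the local F0 of the
#' pitch track: starting from the strongest peak at the head of the
#' segment, each next peak is searched in a window of 0.75-1.3 local
#' periods ahead. Mark times are refined to sub-sample precision by a
#' three-point parabolic fit on a low-pass-filtered copy of the waveform
#' (soft cutoff `lowpass_timing` Hz, narrow enough to suppress the
#' additive-noise timing error while keeping the first two vowel
#' formants). Peak amplitudes are measured the same way on a wider band
#' (`lowpass_amplitude` Hz) so amplitude detail is not lost.
#'
#' @param rec A [voice_recording()].
#' @param track A [estimate_pitch_track()] result for `rec`.
#' @param segment Numeric `c(start, end)` seconds, from
#'   [select_analysis_segment()].
#' @param lowpass_timing Cutoff (Hz) of the low-pass used for cycle-mark
#'   timing (default 2500).
#' @param lowpass_amplitude Cutoff (Hz) of the low-pass used for peak
#'   amplitudes (default 4000).
#' @return A [cycle_sequence()].
#' @export
extract_cycles <- function(rec, track, segment, lowpass_timing = 2500,
                           lowpass_amplitude = 4000) {
  assert_recording(rec)
  sr <- rec$sample_rate
  pm <- cycle_marks(rec, track, segment, lowpass_timing)
  ya <- fft_lowpass(rec$samples[pm$i0p:pm$i1p], sr,
                    min(lowpass_amplitude, 0.45 * sr))
  if (pm$flipped) ya <- -ya
  amps <- vapply(pm$peaks, function(p) parabolic_peak(ya, p)[2], numeric(1))
  periods <- diff(pm$times)
  keep <- periods > 0
  cycle_sequence(periods[keep], amps[-length(amps)][keep],
                 pm$times[-length(pm$times)][keep])
}

# Shared coarse + refined cycle marking. Returns integer peak indices
# (local to the segment), refined absolute times in seconds, segment
# bounds, and whether polarity was flipped.
cycle_marks <- function(rec, track, segment, lowpass = 2500) {
  sr <- rec$sample_rate
  idx <- frames_in_segment(track, segment)
  if (length(idx) == 0 || !any(track$f0_values[idx] > 0)) {
    stop_insufficient_cycles("segment contains no voiced frames",
                             unvoiced = TRUE)
  }
  f0_of <- f0_interpolator(track)
  i0 <- max(1L, floor(segment[1] * sr) + 1L)
  i1 <- min(length(rec$samples), ceiling(segment[2] * sr))
  # filter a padded stretch so edge ripples of the FFT filter fall outside
  # the cycles actually analyzed; all peak indices below are relative to
  # the padded stretch [i0p, i1p]
  pad <- 1024L
  i0p <- max(1L, i0 - pad)
  i1p <- min(length(rec$samples), i1 + pad)
  off <- i0 - i0p
  y <- fft_lowpass(rec$samples[i0p:i1p], sr, min(lowpass, 0.45 * sr))
  flipped <- max(y) < -min(y)
  if (flipped) y <- -y
  n <- i1 - i0 + 1L
  t_abs <- function(p) (i0p - 1 + p - 1) / sr

  T0 <- sr / f0_of(segment[1])
  p <- off + which.max(y[off + seq_len(min(n, ceiling(1.5 * T0)))])
  peaks <- p
  repeat {
    Tl <- sr / f0_of(t_abs(p))
    lo <- p + max(2L, floor(0.75 * Tl))
    hi <- p + ceiling(1.3 * Tl)
    if (hi > off + n) break
    p <- lo - 1L + which.max(y[lo:hi])
    peaks <- c(peaks, p)
  }
  if (length(peaks) < 4) {
    stop_insufficient_cycles(sprintf(
      "only %d complete cycles in segment (need >= 3)",
      max(length(peaks) - 1, 0)
    ))
  }
  times <- vapply(peaks, function(p) {
    t_abs(p) + parabolic_peak(y, p)[1] / sr
  }, numeric(1))
  list(peaks = peaks, times = times, i0 = i0, i1 = i1, i0p = i0p,
       i1p = i1p, flipped = flipped, y = y)
}

# Three-point parabolic refinement around sample p: returns c(offset, value).
parabolic_peak <- function(y, p) {
  n <- length(y)
  if (p <= 1 || p >= n) return(c(0, y[p]))
  ym <- y[p - 1]; y0 <- y[p]; yp <- y[p + 1]
  den <- ym - 2 * y0 + yp
  d <- if (abs(den) > 1e-300) 0.5 * (ym - yp) / den else 0
  d <- max(min(d, 0.5), -0.5)
  c(d, y0 - 0.25 * (ym - yp) * d)
}

# Low-pass with a soft Gaussian rolloff above the cutoff. A hard brick-wall
# edge rings (sinc tails) and drags cycle-mark timing toward neighboring
# cycles; the soft edge does not.
fft_lowpass <- function(x, sr, cutoff) {
  n <- length(x)
  if (cutoff >= sr / 2) return(x)
  m <- stats::nextn(n, c(2, 3, 5))  # awkward lengths make fft() quadratic
  X <- stats::fft(c(x, numeric(m - n)))
  freqs <- (seq_len(m) - 1) * sr / m
  freqs <- pmin(freqs, sr - freqs)  # fold to [0, sr/2]
  H <- ifelse(freqs <= cutoff, 1, exp(-((freqs - cutoff) / (0.15 * cutoff))^2))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / m
}

#' Local jitter (%) of a cycle sequence
#'
#' Mean absolute difference between consecutive period durations divided by
#' the mean period, times 100: the standard period-perturbation measure for
#' sustained vowels.
#'
#' @param cycles A [cycle_sequence()].
#' @return Jitter in percent (non-negative scalar).
#' @export
jitter_local <- function(cycles) {
  T <- cycles$period_durations
  if (length(T) < 3) {
    stop_insufficient_cycles("jitter needs at least 3 cycles")
  }
  100 * mean(abs(diff(T))) / mean(T)
}

#' Local shimmer (%) of a cycle sequence
#'
#' Mean absolute difference between consecutive cycle peak amplitudes
#' divided by the mean amplitude, times 100. Invariant under global gain.
#'
#' @param cycles A [cycle_sequence()].
#' @return Shimmer in percent (non-negative scalar).
#' @export
shimmer_local <- function(cycles) {
  A <- cycles$peak_amplitudes
  if (length(A) < 3) {
    stop_insufficient_cycles("shimmer needs at least 3 cycles")
  }
  if (any(!is.finite(A)) || any(A <= 0)) {
    stop_invalid_input("shimmer requires positive peak amplitudes")
  }
  100 * mean(abs(diff(A))) / mean(A)
}

#' Harmonics-to-noise ratio (dB) of an analysis segment
#'
#' Cycle-synchronous estimate in the tradition of the classical
#' mean-cycle/deviation decomposition: cycles are aligned rigidly at their
#' marks, the periodic component is the mean cycle waveform (with one free
#' gain per cycle to absorb shimmer), and the noise power is the residual
#' in the early part of each cycle, where the waveform is rigidly locked
#' to the excitation instant and therefore insensitive to period
#' perturbation. `HNR = 10 log10(periodic power / noise power)`, capped at
#' `cap` dB for numerically pure signals. When fewer than 5 cycles can be
#' marked the estimate falls back to the normalized autocorrelation peak
#' `r` of the pitch track via `10 log10(r / (1 - r))`.
#'
#' @param rec A [voice_recording()].
#' @param segment Numeric `c(start, end)` seconds.
#' @param track A [estimate_pitch_track()] result for `rec`.
#' @param cap Ceiling in dB (default 40).
#' @return HNR in dB.
#' @export
hnr <- function(rec, segment, track, cap = 40) {
  assert_recording(rec)
  idx <- frames_in_segment(track, segment)
  vidx <- idx[track$f0_values[idx] > 0]
  if (length(vidx) == 0) stop_no_voicing("segment contains no voiced frames")

  ok <- tryCatch({
    pm <- cycle_marks(rec, track, segment)
    length(pm$peaks) >= 5
  }, phl_error = function(e) FALSE)
  if (!ok) {
    r <- mean(track$r_values[vidx])
    if (r >= 1 - 1e-12) return(cap)
    if (r <= 0) return(-cap)
    return(min(10 * log10(r / (1 - r)), cap))
  }

  x <- rec$samples[pm$i0p:pm$i1p]
  if (pm$flipped) x <- -x
  sr <- rec$sample_rate
  nc <- round(stats::median(diff(pm$peaks)))
  # fractional-sample alignment at the refined mark times: integer-grid
  # alignment alone leaves up to half a sample of phase error per cycle,
  # which registers as spurious noise on clean signals
  marks <- pm$times * sr - (pm$i0p - 1) + 1
  marks <- marks[marks + nc <= length(x)]
  if (length(marks) < 5) {
    r <- mean(track$r_values[vidx])
    if (r >= 1 - 1e-12) return(cap)
    return(min(10 * log10(r / (1 - r)), cap))
  }
  M <- vapply(marks, function(p) {
    stats::approx(seq_along(x), x, xout = p + 0:(nc - 1))$y
  }, numeric(nc))
  tpl <- rowMeans(M)
  we <- max(3L, round(0.35 * nc))      # early, perturbation-rigid window
  te <- tpl[1:we]
  g <- as.numeric(crossprod(M[1:we, , drop = FALSE], te)) / sum(te^2)
  res <- M[1:we, , drop = FALSE] - outer(te, g)
  # linear interpolation at fractional mark offsets attenuates white noise
  # by (1-a)^2 + a^2 per cycle; undo that in the noise-power estimate
  a <- marks - floor(marks)
  cfac <- mean((1 - a)^2 + a^2)
  p_noise <- mean(res^2) / cfac
  p_per <- mean(g^2) * mean(tpl^2)
  if (p_noise <= p_per * 1e-12) return(cap)
  max(min(10 * log10(p_per / p_noise), cap), -cap)
}
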