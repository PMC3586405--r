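#' Frequency range from the lowest- and highest-pitch vowels
#'
#' The patient sustains the lowest and the highest /a/ they can produce;
#' the physiological frequency range is the difference of the mean voiced
#' F0 of the two recordings, in Hz. If the recordings are given in the
#' wrong order the bounds are swapped with a warning.
#'
#' @param low_rec,high_rec [voice_recording()] objects (kinds `low_a` /
#'   `high_a` expected, warned otherwise).
#' @param ... Passed to [estimate_pitch_track()].
#' @return Named numeric `c(f_low, f_high, range)` in Hz.
#' @export
frequency_range <- function(low_rec, high_rec, ...) {
  assert_recording(low_rec)
  assert_recording(high_rec)
  if (low_rec$kind != "low_a" || high_rec$kind != "high_a") {
    warning("expected recording kinds low_a / high_a", call. = FALSE)
  }
  mean_f0 <- function(rec, label) {
    tr <- estimate_pitch_track(rec, ...)
    v <- tr$f0_values[tr$f0_values > 0]
    if (length(v) == 0) {
      stop_no_voicing(sprintf("%s recording has no voiced frames", label))
    }
    mean(v)
  }
  f_low <- mean_f0(low_rec, "low-pitch")
  f_high <- mean_f0(high_rec, "high-pitch")
  if (f_low > f_high) {
    warning("low-pitch F0 above high-pitch F0; swapping bounds",
            call. = FALSE)
    tmp <- f_low; f_low <- f_high; f_high <- tmp
  }
  c(f_low = f_low, f_high = f_high, range = f_high - f_low)
}

#' Full objective acoustic report for a sustained /a/
#'
#' Runs the whole acoustic chain on the held vowel: pitch tracking,
#' selection of the ~50-cycle mid-phonation segment, cycle extraction,
#' local jitter and shimmer, autocorrelation HNR, and (when the low- and
#' high-pitch vowels are supplied) the frequency range.
#'
#' @param held_a [voice_recording()] of the sustained comfortable /a/.
#' @param low_a,high_a Optional lowest-/highest-pitch recordings for the
#'   frequency range.
#' @param f0_min,f0_max Pitch search band in Hz.
#' @param target_cycles Cycles the analysis segment should span (default 50).
#' @param hnr_cap HNR ceiling in dB (default 40).
#' @return An `acoustic_report` with fields `f0_mean`, `f0_sd` (Hz),
#'   `jitter_pct`, `shimmer_pct`, `hnr_db`, `freq_range_hz` (or `NA`),
#'   `segment_used` (s), `n_cycles`.
#' @examples
#' rec <- synth_voice(voice_spec(f0 = 180, duration = 1.2, seed = 1))$recording
#' acoustic_report(rec)
#' @export
acoustic_report <- function(held_a, low_a = NULL, high_a = NULL,
                            f0_min = 40, f0_max = 600,
                            target_cycles = 50, hnr_cap = 40) {
  assert_recording(held_a, min_duration = 0.1)
  track <- estimate_pitch_track(held_a, f0_min = f0_min, f0_max = f0_max)
  segment <- select_analysis_segment(held_a, target_cycles = target_cycles,
                                     track = track)
  idx <- frames_in_segment(track, segment)
  f0v <- track$f0_values[idx]
  f0v <- f0v[f0v > 0]
  cycles <- extract_cycles(held_a, track, segment)
  rng <- if (!is.null(low_a) && !is.null(high_a)) {
    frequency_range(low_a, high_a, f0_min = f0_min, f0_max = f0_max)[["range"]]
  } else {
    NA_real_
  }
  structure(
    list(
      f0_mean = mean(f0v),
      f0_sd = if (length(f0v) > 1) stats::sd(f0v) else 0,
      jitter_pct = jitter_local(cycles),
      shimmer_pct = shimmer_local(cycles),
      hnr_db = hnr(held_a, segment, track, cap = hnr_cap),
      freq_range_hz = rng,
      segment_used = segment,
      n_cycles = length(cycles$period_durations)
    ),
    class = "acoustic_report"
  )
}

#' @export
print.acoustic_report <- function(x, ...) {
  cat("<acoustic_report>\n")
  cat(sprintf("  F0      %.2f Hz (sd %.2f)\n", x$f0_mean, x$f0_sd))
  cat(sprintf("  jitter  %.3f %%\n", x$jitter_pct))
  cat(sprintf("  shimmer %.3f %%\n", x$shimmer_pct))
  cat(sprintf("  HNR     %.2f dB\n", x$hnr_db))
  if (is.finite(x$freq_range_hz)) {
    cat(sprintf("  range   %.1f Hz\n", x$freq_range_hz))
  }
  cat(sprintf("  segment %.3f-%.3f s (%d cycles)\n",
              x$segment_used[1], x$segment_used[2], x$n_cycles))
  invisible(x)
}
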