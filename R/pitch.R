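#' Estimate a fundamental-frequency track from a sustained utterance
#'
#' Frame-wise F0 estimation by the normalized cross-correlation function
#' (NCCF): for each analysis frame the correlation between the frame and its
#' lagged copy is normalized by the energies of both windows, the peak inside
#' the candidate lag band is refined by parabolic interpolation, and frames
#' whose peak falls below the voicing threshold are marked unvoiced
#' (`f0 = 0`). Among near-tied correlation maxima the shortest lag wins,
#' which resolves the period-multiple ambiguity of strongly harmonic vowels.
#'
#' @param rec A [voice_recording()].
#' @param f0_min,f0_max Search band in Hz (defaults 40-600 Hz, wide enough
#'   for low-pitched dysphonic and high-pitched sung vowels).
#' @param frame_length Correlation window length in seconds (default 0.04 s,
#'   at least two periods of the lowest male F0 of interest).
#' @param hop Frame hop in seconds (default 0.01 s).
#' @param voicing_threshold Minimum normalized correlation peak for a frame
#'   to count as voiced (default 0.45).
#' @return A `pitch_track`: `frame_times` (s, window centers), `f0_values`
#'   (Hz, 0 = unvoiced), `r_values` (normalized correlation peak per frame),
#'   `frame_length`, `hop`, `f0_min`, `f0_max`.
#' @export
estimate_pitch_track <- function(rec, f0_min = 40, f0_max = 600,
                                 frame_length = 0.04, hop = 0.01,
                                 voicing_threshold = 0.45) {
  assert_recording(rec)
  if (!(f0_min > 0 && f0_min < f0_max)) {
    stop_invalid_input("need 0 < f0_min < f0_max")
  }
  sr <- rec$sample_rate
  x <- rec$samples
  n <- length(x)
  w <- round(frame_length * sr)
  hop_n <- max(1L, round(hop * sr))
  if (n < w) {
    stop_invalid_input("recording shorter than one analysis frame")
  }
  lag_min <- max(2L, floor(sr / f0_max))
  lag_max <- min(ceiling(sr / f0_min), n - w)
  if (lag_max < lag_min) {
    stop_invalid_input("recording too short for the requested F0 band")
  }

  starts <- seq.int(1L, n - w - lag_max + 1L, by = hop_n)
  if (length(starts) == 0) starts <- 1L
  nfft <- 2^ceiling(log2(w + lag_max))
  csum <- c(0, cumsum(x^2))
  # silence gate relative to overall level
  gate <- max(mean(x^2) * 1e-6, 1e-14)

  f0 <- numeric(length(starts))
  rpk <- numeric(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    e1 <- csum[s + w] - csum[s]
    if (e1 / w < gate) next
    x1 <- x[s:(s + w - 1)]
    seg <- x[s:(s + w + lag_max - 1)]
    cc <- Re(stats::fft(Conj(stats::fft(c(x1, numeric(nfft - w)))) *
                        stats::fft(c(seg, numeric(nfft - length(seg)))),
                        inverse = TRUE)) / nfft
    lags <- lag_min:lag_max
    e2 <- csum[s + w + lags] - csum[s + lags]
    r <- cc[lags + 1L] / sqrt(e1 * pmax(e2, 1e-300))
    pk <- pick_lag(r, lags)
    if (is.null(pk)) next
    # parabolic refinement of the correlation peak
    j <- pk - lag_min + 1L
    if (j > 1 && j < length(r)) {
      denom <- r[j - 1] - 2 * r[j] + r[j + 1]
      delta <- if (abs(denom) > 1e-12) 0.5 * (r[j - 1] - r[j + 1]) / denom else 0
      delta <- max(min(delta, 0.5), -0.5)
      r_ref <- r[j] - 0.25 * (r[j - 1] - r[j + 1]) * delta
    } else {
      delta <- 0
      r_ref <- r[j]
    }
    rpk[i] <- min(r_ref, 1)
    if (r_ref >= voicing_threshold) {
      f0[i] <- min(max(sr / (pk + delta), f0_min), f0_max)
    }
  }

  # median smoothing over voiced frames removes isolated octave errors
  vi <- which(f0 > 0)
  if (length(vi) >= 7) {
    f0[vi] <- stats::runmed(f0[vi], 7)
  }

  structure(
    list(
      frame_times = (starts - 1) / sr + frame_length / 2,
      f0_values = f0,
      r_values = rpk,
      frame_length = frame_length,
      hop = hop,
      f0_min = f0_min,
      f0_max = f0_max,
      voicing_threshold = voicing_threshold
    ),
    class = "pitch_track"
  )
}

# Choose the period lag: global maximum, then the shortest-lag local maximum
# whose correlation is within 10% of it (period-multiple disambiguation).
pick_lag <- function(r, lags) {
  if (all(!is.finite(r))) return(NULL)
  jmax <- which.max(r)
  rmax <- r[jmax]
  if (!is.finite(rmax) || rmax <= 0) return(NULL)
  nr <- length(r)
  is_lmax <- c(FALSE, r[2:(nr - 1)] >= r[1:(nr - 2)] &
                      r[2:(nr - 1)] >= r[3:nr], FALSE)
  is_lmax[jmax] <- TRUE
  cand <- which(is_lmax & r >= 0.9 * rmax)
  if (length(cand) == 0) cand <- jmax
  lags[min(cand)]
}

#' @export
print.pitch_track <- function(x, ...) {
  nv <- sum(x$f0_values > 0)
  cat(sprintf("<pitch_track> %d frames (%d voiced), band %g-%g Hz\n",
              length(x$f0_values), nv, x$f0_min, x$f0_max))
  if (nv > 0) {
    cat(sprintf("  voiced F0: mean %.2f Hz, sd %.2f Hz\n",
                mean(x$f0_values[x$f0_values > 0]),
                stats::sd(x$f0_values[x$f0_values > 0])))
  }
  invisible(x)
}

#' Select the analysis segment of a sustained vowel
#'
#' Clinical practice analyses a homogeneous stretch of roughly 50 vibratory
#' cycles taken from the middle of the phonation, never more than one
#' second. This finds the longest voiced run of the pitch track and returns
#' a window of `target_cycles / median F0` seconds (clipped to 1 s and to
#' the run itself) centered on the run's midpoint.
#'
#' @param rec A [voice_recording()].
#' @param target_cycles Number of glottal cycles the segment should span
#'   (default 50).
#' @param track Optional precomputed [estimate_pitch_track()] result.
#' @param max_length Hard cap on segment length in seconds (default 1).
#' @param ... Passed to [estimate_pitch_track()] when `track` is missing.
#' @return Named numeric `c(start, end)` in seconds.
#' @export
select_analysis_segment <- function(rec, target_cycles = 50, track = NULL,
                                    max_length = 1.0, ...) {
  assert_recording(rec)
  if (is.null(track)) track <- estimate_pitch_track(rec, ...)
  voiced <- track$f0_values > 0
  if (!any(voiced)) stop_no_voicing("no voiced frames found in recording")
  runs <- rle(voiced)
  ends <- cumsum(runs$lengths)
  starts_i <- ends - runs$lengths + 1L
  vruns <- which(runs$values)
  best <- vruns[which.max(runs$lengths[vruns])]
  i0 <- starts_i[best]
  i1 <- ends[best]
  half_frame <- track$frame_length / 2
  span0 <- max(track$frame_times[i0] - half_frame, 0)
  span1 <- min(track$frame_times[i1] + half_frame, duration(rec))
  f0_med <- stats::median(track$f0_values[i0:i1])
  len <- min(target_cycles / f0_med, max_length, span1 - span0)
  center <- (span0 + span1) / 2
  c(start = center - len / 2, end = center + len / 2)
}

# Interpolator of voiced F0 over time; constant extrapolation at the ends.
f0_interpolator <- function(track) {
  voiced <- track$f0_values > 0
  if (sum(voiced) == 1) {
    v <- track$f0_values[voiced]
    return(function(t) rep(v, length(t)))
  }
  stats::approxfun(track$frame_times[voiced], track$f0_values[voiced],
                   rule = 2)
}

frames_in_segment <- function(track, segment) {
  which(track$frame_times >= segment[1] & track$frame_times <= segment[2])
}
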