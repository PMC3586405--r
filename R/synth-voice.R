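#' Specification of a synthetic sustained vowel
#'
#' Parameters of the test-voice generator: target F0, local jitter and
#' shimmer in percent, target harmonics-to-noise ratio in dB, duration,
#' sample rate and RNG seed.
#'
#' @param f0 Fundamental frequency in Hz, within 60-600.
#' @param jitter_pct Target local jitter in percent (0-20).
#' @param shimmer_pct Target local shimmer in percent (0-50).
#' @param hnr_db Target HNR in dB; `Inf` disables the noise floor.
#' @param duration Duration in seconds (default 2 s: enough phonation for a
#'   full one-second mid-vowel analysis segment with margins).
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param seed Integer RNG seed; the generator is fully deterministic
#'   given the spec.
#' @param pattern Period/amplitude perturbation pattern: `"gaussian"`
#'   (i.i.d., the default) or `"alternating"` (deterministic +/- square
#'   alternation, useful for exact-recovery checks).
#' @return A `voice_spec` object.
#' @export
voice_spec <- function(f0 = 178.12, jitter_pct = 0, shimmer_pct = 0,
                       hnr_db = Inf, duration = 2, sample_rate = 44100,
                       seed = 1, pattern = c("gaussian", "alternating")) {
  pattern <- match.arg(pattern)
  if (!(f0 >= 60 && f0 <= 600)) stop_spec("f0 must lie in [60, 600] Hz")
  if (jitter_pct < 0 || shimmer_pct < 0) {
    stop_spec("jitter and shimmer percentages must be non-negative")
  }
  if (jitter_pct > 20) stop_spec("jitter above 20% is not synthesizable")
  if (shimmer_pct > 50) stop_spec("shimmer above 50% is not synthesizable")
  if (duration <= 0) stop_spec("duration must be positive")
  if (sample_rate < 8000) stop_spec("sample_rate must be at least 8000 Hz")
  structure(
    list(f0 = f0, jitter_pct = jitter_pct, shimmer_pct = shimmer_pct,
         hnr_db = hnr_db, duration = duration, sample_rate = sample_rate,
         seed = as.integer(seed), pattern = pattern),
    class = "voice_spec"
  )
}

# Rosenberg glottal flow pulse, phase in [0, 1): raised-cosine opening over
# `op`, cosine closing over `cl`, closed otherwise.
rosenberg_flow <- function(phase, op = 0.40, cl = 0.16) {
  g <- numeric(length(phase))
  opening <- phase >= 0 & phase < op
  closing <- phase >= op & phase < op + cl
  g[opening] <- 0.5 * (1 - cos(pi * phase[opening] / op))
  g[closing] <- cos(pi * (phase[closing] - op) / (2 * cl))
  g
}

# Fraction of the mean period occupied by the open+closing phases. The pulse
# is anchored so its closing edge ends exactly at the cycle boundary and the
# open/closing durations are fixed in absolute time (fractions of the MEAN
# period, not of the perturbed one). The glottal closure instants - the
# acoustic events any cycle-marking analyzer latches onto - are then
# separated by exactly the ground-truth periods; tying the pulse shape to
# the perturbed period instead would smear the event timing and make the
# emitted ground truth unobservable in the waveform.
rosenberg_open <- 0.40
rosenberg_close <- 0.16

# Second-order resonator (formant) as a recursive filter.
resonate <- function(x, freq, bw, sr) {
  r <- exp(-pi * bw / sr)
  th <- 2 * pi * freq / sr
  stats::filter(x, c(2 * r * cos(th), -r^2), method = "recursive")
}

#' Synthesize a sustained /a/ with controlled perturbations
#'
#' A Rosenberg glottal pulse train is evaluated in continuous time (pulse
#' events are not quantized to the sample grid), differentiated, and passed
#' through two fixed formant resonators at 700 and 1200 Hz approximating
#' the vowel /a/. Each pulse is anchored so its closing edge ends exactly
#' at the cycle boundary, with open/closing phases of fixed absolute
#' duration: the glottal closure instants - the acoustic landmarks any
#' cycle-marking analysis latches onto - are then separated by exactly the
#' ground-truth periods. Cycle periods are perturbed i.i.d. Gaussian so
#' the expected local jitter equals `jitter_pct`; cycle amplitudes
#' likewise for `shimmer_pct`. White Gaussian noise is mixed at
#' `periodic power * 10^(-hnr_db / 10)` so the periodic-to-noise power
#' ratio equals the requested HNR by construction.
#'
#' @param spec A [voice_spec()].
#' @param kind Recording-kind tag for the emitted [voice_recording()].
#' @return A list: `recording` (a [voice_recording()]) and `ground_truth`
#'   with realized per-cycle `periods` (s), `amplitudes`, the realized
#'   local `jitter_pct` / `shimmer_pct` computed from them, and the
#'   requested `f0` / `hnr_db`.
#' @examples
#' v <- synth_voice(voice_spec(f0 = 120, jitter_pct = 1, seed = 42))
#' v$ground_truth$jitter_pct
#' @export
synth_voice <- function(spec, kind = "held_a") {
  if (!inherits(spec, "voice_spec")) {
    stop_spec("`spec` must be a voice_spec object")
  }
  sr <- spec$sample_rate
  T0 <- 1 / spec$f0
  n_cycles <- ceiling(spec$duration / T0) + 2L

  rng <- local_rng(spec$seed)
  if (spec$pattern == "alternating") {
    # +/- d alternation: E|d_k - d_{k-1}| = 2d, so d = pct / 200
    sq <- rep_len(c(1, -1), n_cycles)
    periods <- T0 * (1 + sq * spec$jitter_pct / 200)
    amps <- pmax(1 + sq * spec$shimmer_pct / 200, 0.05)
  } else {
    # E|d_k - d_{k-1}| = 2*sigma/sqrt(pi) for i.i.d. Gaussian perturbations,
    # so sigma = pct * sqrt(pi) / 200 gives the requested local measure.
    sig_j <- spec$jitter_pct * sqrt(pi) / 200
    sig_s <- spec$shimmer_pct * sqrt(pi) / 200
    periods <- T0 * (1 + rng$norm(n_cycles) * sig_j)
    periods <- pmax(periods, 0.2 * T0)
    amps <- pmax(1 + rng$norm(n_cycles) * sig_s, 0.05)
  }

  onsets <- c(0, cumsum(periods))
  t <- (seq_len(round(spec$duration * sr)) - 1) / sr
  k <- findInterval(t, onsets)
  active <- (rosenberg_open + rosenberg_close) * T0
  u <- (t - (onsets[k + 1L] - active)) / active
  op_frac <- rosenberg_open / (rosenberg_open + rosenberg_close)
  flow <- amps[k] * rosenberg_flow(u, op = op_frac, cl = 1 - op_frac)
  src <- c(0, diff(flow)) * sr / spec$f0   # flow derivative (radiation)
  y <- resonate(src, 700, 110, sr)
  y <- as.numeric(resonate(y, 1200, 140, sr))

  if (is.finite(spec$hnr_db)) {
    p_sig <- mean(y^2)
    noise <- rng$norm(length(y)) * sqrt(p_sig * 10^(-spec$hnr_db / 10))
    y <- y + noise
  }
  y <- 0.9 * y / max(abs(y))

  # ground truth restricted to cycles fully inside the emitted duration
  full <- which(onsets[-1] <= spec$duration)
  gt_periods <- periods[full]
  gt_amps <- amps[full]
  list(
    recording = voice_recording(y, sr, kind = kind),
    ground_truth = list(
      f0 = spec$f0,
      periods = gt_periods,
      amplitudes = gt_amps,
      jitter_pct = 100 * mean(abs(diff(gt_periods))) / mean(gt_periods),
      shimmer_pct = 100 * mean(abs(diff(gt_amps))) / mean(gt_amps),
      hnr_db = spec$hnr_db
    )
  )
}

# Seeded RNG helper that does not disturb the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    s
  }
  draw <- function(fn, n, ...) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    assign(".Random.seed", env$state, globalenv())
    out <- fn(n, ...)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    out
  }
  list(
    norm = function(n, ...) draw(stats::rnorm, n, ...),
    unif = function(n, ...) draw(stats::runif, n, ...),
    int = function(n, max) draw(function(n) sample.int(max, n, replace = TRUE), n)
  )
}
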