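# Shared fixtures, built in code. Sample rates are kept moderate where the
# check does not depend on them, to keep the suite fast.

make_sine <- function(freq, duration = 0.6, sr = 44100, amp = 0.8,
                      kind = "held_a") {
  t <- seq(0, duration, by = 1 / sr)
  voice_recording(amp * sin(2 * pi * freq * t), sr, kind = kind)
}

make_noise <- function(duration = 0.6, sr = 44100, seed = 99) {
  withr::with_seed(seed, {
    voice_recording(0.5 * stats::rnorm(round(duration * sr)) /
                      3, sr)
  })
}

# The cohort-mean voice used throughout: Table-like settings.
table_mean_spec <- function(seed = 1) {
  voice_spec(f0 = 178.12, jitter_pct = 0.35, shimmer_pct = 4.10,
             hnr_db = 23.12, seed = seed)
}

# Brute-force shoelace polygon area over the radar vertices (independent
# oracle for profile_area).
shoelace_area <- function(radii) {
  n <- length(radii)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  x <- radii * cos(ang)
  y <- radii * sin(ang)
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}
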