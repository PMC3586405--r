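#' Voice recording container
#'
#' A `voice_recording` holds one mono exam utterance: a real-valued waveform
#' in `[-1, 1]`, its sample rate, and a tag identifying which of the exam
#' utterances it is. The clinical protocol records a read text, a sustained
#' /a/ at comfortable pitch, the lowest and highest sustainable /a/, a
#' projected-voice sentence and short sung words; all quantitative analyses
#' run on the sustained kinds.
#'
#' @param samples Numeric vector, mono waveform. Values outside `[-1, 1]`
#'   are rescaled to peak 1 with a warning.
#' @param sample_rate Sampling rate in Hz (positive integer).
#' @param kind One of `"text_reading"`, `"held_a"`, `"low_a"`, `"high_a"`,
#'   `"projected"`, `"sung"`.
#' @return An object of class `voice_recording` with fields `samples`,
#'   `sample_rate`, `kind`.
#' @examples
#' sr <- 16000
#' rec <- voice_recording(sin(2 * pi * 200 * seq(0, 1, by = 1 / sr)), sr)
#' rec
#' @export
voice_recording <- function(samples, sample_rate,
                            kind = c("held_a", "low_a", "high_a",
                                     "text_reading", "projected", "sung")) {
  kind <- match.arg(kind)
  if (!is.numeric(samples) || length(samples) == 0) {
    stop_invalid_input("`samples` must be a non-empty numeric vector")
  }
  if (!all(is.finite(samples))) {
    stop_invalid_input("`samples` contains non-finite values")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop_invalid_input("`sample_rate` must be a single positive number")
  }
  samples <- as.numeric(samples)
  peak <- max(abs(samples))
  if (peak > 1) {
    warning("waveform exceeds [-1, 1]; rescaling to peak 1", call. = FALSE)
    samples <- samples / peak
  }
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate), kind = kind),
    class = "voice_recording"
  )
}

#' @export
print.voice_recording <- function(x, ...) {
  cat(sprintf("<voice_recording> kind=%s, %.3f s @ %g Hz\n",
              x$kind, duration(x), x$sample_rate))
  invisible(x)
}

duration <- function(rec) length(rec$samples) / rec$sample_rate

assert_recording <- function(rec, min_duration = 0) {
  if (!inherits(rec, "voice_recording")) {
    stop_invalid_input("expected a `voice_recording` object")
  }
  if (duration(rec) < min_duration) {
    stop_invalid_input(sprintf(
      "recording too short: %.3f s < required %.3f s",
      duration(rec), min_duration
    ))
  }
  invisible(rec)
}
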