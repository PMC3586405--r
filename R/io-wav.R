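# Minimal RIFF/WAVE reader and writer. No audio package ships with the
# supported toolchain, so PCM 16/24-bit and IEEE float chunks are handled
# here directly. Only what the exam needs: mono preferred, stereo down-mixed
# by averaging (with a warning), integer PCM scaled to [-1, 1].

#' Read a WAV file as a voice recording
#'
#' Supports uncompressed PCM (16- or 24-bit) and 32-bit IEEE float WAV.
#' Stereo files are down-mixed to mono by channel averaging with a warning.
#' Integer samples are scaled to `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @param kind Recording-kind tag to attach (see [voice_recording()]).
#' @return A [voice_recording()].
#' @export
read_wav <- function(path, kind = "held_a") {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_parse("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_parse("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format    = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        channels  = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        rate      = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits      = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop_parse("WAV file missing fmt or data chunk: ", path)
  }

  x <- switch(
    as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = read_pcm24(data_raw),
    "32" = {
      if (fmt$format == 3) {
        readBin(data_raw, "numeric", length(data_raw) / 4, 4,
                endian = "little")
      } else {
        readBin(data_raw, "integer", length(data_raw) / 4, 4,
                endian = "little") / 2147483648
      }
    },
    stop_parse(sprintf("unsupported WAV bit depth: %d", fmt$bits))
  )

  if (fmt$channels > 1) {
    warning(sprintf("down-mixing %d channels to mono by averaging",
                    fmt$channels), call. = FALSE)
    n <- floor(length(x) / fmt$channels)
    x <- rowMeans(matrix(x[seq_len(n * fmt$channels)],
                         ncol = fmt$channels, byrow = TRUE))
  }
  voice_recording(pmin(pmax(x, -1), 1), fmt$rate, kind = kind)
}

read_pcm24 <- function(raw) {
  n <- length(raw) / 3
  b <- matrix(as.integer(raw), nrow = 3)
  v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
  v <- ifelse(v >= 8388608, v - 16777216, v)
  v / 8388608
}

#' Write a voice recording to a 16-bit PCM WAV file
#'
#' @param rec A [voice_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  assert_recording(rec)
  pcm <- as.integer(pmin(pmax(round(rec$samples * 32768), -32768), 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # PCM
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(rec$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")                 # block align
  writeBin(16L, con, 2, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
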