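# Portable graymap I/O for strobe frames. PGM is the one image format that
# has a plain-text encoding (P2) readable without any imaging library; the
# binary P5 variant is also supported for compactness. Frame sequences are
# simply numbered files.

#' Read a PGM image as a strobe frame
#'
#' Supports ASCII (P2) and binary (P5) portable graymaps, 8- or 16-bit.
#'
#' @param path Path to a `.pgm` file.
#' @param roi Optional region of interest, see [strobe_frame()].
#' @return A [strobe_frame()].
#' @export
read_pgm <- function(path, roi = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval, with # comments allowed
  while (length(tokens) < 4) {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop_parse("truncated PGM header: ", path)
    line <- sub("#.*$", "", line)
    tokens <- c(tokens, strsplit(trimws(line), "\\s+")[[1]])
    tokens <- tokens[nzchar(tokens)]
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (!magic %in% c("P2", "P5") || anyNA(c(w, h, maxval))) {
    stop_parse("not a valid PGM file: ", path)
  }
  vals <- if (magic == "P2") {
    v <- scan(con, what = integer(), n = w * h, quiet = TRUE,
              comment.char = "#")
    if (length(v) < w * h) stop_parse("truncated PGM data: ", path)
    v
  } else {
    bytes <- if (maxval < 256) 1L else 2L
    raw <- readBin(con, "raw", w * h * bytes)
    if (length(raw) < w * h * bytes) stop_parse("truncated PGM data: ", path)
    if (bytes == 1L) as.integer(raw)
    else as.integer(raw[c(TRUE, FALSE)]) * 256L + as.integer(raw[c(FALSE, TRUE)])
  }
  strobe_frame(matrix(vals, nrow = h, ncol = w, byrow = TRUE), roi = roi)
}

#' Write a strobe frame as an ASCII PGM image
#'
#' @param frame A [strobe_frame()] (intensities are rounded and clamped to
#'   0-255).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(frame, path) {
  if (!inherits(frame, "strobe_frame")) {
    stop_invalid_input("expected a strobe_frame")
  }
  img <- round(pmin(pmax(frame$image, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)), "255"), con)
  apply(img, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
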