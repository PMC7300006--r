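#' Waveform objects
#'
#' A waveform is a light container for a mono audio signal: a numeric vector
#' of amplitudes in \[-1, 1\] plus a sampling rate in Hz.
#'
#' @param samples numeric vector of amplitudes.
#' @param rate sampling rate in Hz (positive scalar).
#' @return An object of class `"waveform"` with elements `samples` and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1/8000)), 8000)
#' duration_ms(w)
#' @export
waveform <- function(samples, rate) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number", call. = FALSE)
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.1f ms)>\n",
              length(x$samples), x$rate, duration_ms(x)))
  invisible(x)
}

#' Duration of a waveform in milliseconds
#' @param w a `waveform`.
#' @return duration in ms (`1000 * n / rate`).
#' @export
duration_ms <- function(w) 1000 * length(w$samples) / w$rate

.read_chunk_header <- function(con) {
  id <- readChar(con, 4L, useBytes = TRUE)
  if (length(id) == 0L || nchar(id, type = "bytes") < 4L) return(NULL)
  size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  list(id = id, size = size)
}

#' Read a RIFF WAV file
#'
#' Reads PCM (8/16/24-bit integer) and IEEE-float (32-bit) RIFF WAV files.
#' Samples are rescaled to \[-1, 1\]; multi-channel input is collapsed to
#' mono by averaging the channels.
#'
#' @param path path to a `.wav` file.
#' @return a [waveform()].
#' @export
load_wav <- function(path) {
  if (!file.exists(path))
    stop(sprintf("WAV file not found: '%s'", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop(sprintf("'%s' is not a RIFF/WAVE file", path), call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    h <- .read_chunk_header(con)
    if (is.null(h)) break
    if (identical(h$id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1L, size = 2L, endian = "little",
                               signed = FALSE),
        n_channels   = readBin(con, "integer", 1L, size = 2L, endian = "little",
                               signed = FALSE),
        rate         = readBin(con, "integer", 1L, size = 4L, endian = "little"),
        byte_rate    = readBin(con, "integer", 1L, size = 4L, endian = "little"),
        block_align  = readBin(con, "integer", 1L, size = 2L, endian = "little",
                               signed = FALSE),
        bits         = readBin(con, "integer", 1L, size = 2L, endian = "little",
                               signed = FALSE))
      extra <- h$size - 16L
      if (extra > 0L) readBin(con, "raw", extra)
    } else if (identical(h$id, "data")) {
      data_raw <- readBin(con, "raw", h$size)
      if (h$size %% 2L == 1L) readBin(con, "raw", 1L)  # pad byte
    } else {
      skip <- h$size + h$size %% 2L
      readBin(con, "raw", skip)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop(sprintf("'%s': missing fmt or data chunk", path), call. = FALSE)

  bits <- fmt$bits
  n_total <- length(data_raw)
  x <- switch(
    as.character(fmt$audio_format),
    "1" = {
      if (bits == 8L) {
        (as.numeric(readBin(data_raw, "integer", n_total, size = 1L,
                            signed = FALSE)) - 128) / 128
      } else if (bits == 16L) {
        as.numeric(readBin(data_raw, "integer", n_total %/% 2L, size = 2L,
                           endian = "little")) / 32768
      } else if (bits == 24L) {
        n <- n_total %/% 3L
        b <- as.integer(data_raw)
        i <- 3L * seq_len(n)
        v <- b[i - 2L] + 256 * b[i - 1L] + 65536 * b[i]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else {
        stop(sprintf("'%s': unsupported PCM bit depth %d", path, bits),
             call. = FALSE)
      }
    },
    "3" = readBin(data_raw, "double", n_total %/% 4L, size = 4L,
                  endian = "little"),
    stop(sprintf("'%s': unsupported WAV format code %d", path,
                 fmt$audio_format), call. = FALSE))

  if (fmt$n_channels > 1L) {
    n_frames <- length(x) %/% fmt$n_channels
    x <- rowMeans(matrix(x[seq_len(n_frames * fmt$n_channels)],
                         ncol = fmt$n_channels, byrow = TRUE))
  }
  waveform(x, fmt$rate)
}

#' Write a waveform as 16-bit PCM WAV
#'
#' @param w a [waveform()]; samples outside \[-1, 1\] are clipped.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmin(1, pmax(-1, w$samples))
  pcm <- as.integer(round(x * 32767))
  data_size <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")   # PCM
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(as.integer(w$rate), con, size = 4L, endian = "little")
  writeBin(as.integer(w$rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
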