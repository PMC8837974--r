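#' Read a mono RIFF/PCM WAV file
#'
#' Minimal reader for the RIFF `WAVE` container: integer PCM at 16, 24 or
#' 32 bits and IEEE float at 32 or 64 bits are supported. Integer samples are
#' rescaled to `[-1, 1)` by `2^(bits-1)`; float samples are returned as stored.
#'
#' @param path Path to a `.wav` file.
#' @param mixdown If `TRUE`, average the channels of a multi-channel file down
#'   to mono instead of raising an error.
#' @return A list with `samples` (numeric vector), `rate` (Hz), `bits` and
#'   `format` (`"pcm"` or `"float"`).
#' @export
read_wav <- function(path, mixdown = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], integer(), 1, size = 2,
                               signed = FALSE, endian = "little"),
        n_channels   = readBin(raw[3:4], integer(), 1, size = 2,
                               signed = FALSE, endian = "little"),
        rate         = readBin(raw[5:8], integer(), 1, size = 4,
                               endian = "little"),
        bits         = readBin(raw[15:16], integer(), 1, size = 2,
                               signed = FALSE, endian = "little"))
      # WAVE_FORMAT_EXTENSIBLE: actual format sits in the SubFormat GUID
      if (fmt$audio_format == 65534L && sz >= 40)
        fmt$audio_format <- readBin(raw[25:26], integer(), 1, size = 2,
                                    signed = FALSE, endian = "little")
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))  # skip, chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)

  n_bytes <- fmt$bits %/% 8
  n <- length(data_raw) %/% n_bytes
  x <- switch(
    as.character(fmt$audio_format),
    "1" = {  # integer PCM
      if (fmt$bits == 16) {
        readBin(data_raw, integer(), n, size = 2, signed = TRUE,
                endian = "little") / 2^15
      } else if (fmt$bits == 24) {
        b <- as.integer(data_raw)
        dim(b) <- c(3, n)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 2^23, v - 2^24, v)
        v / 2^23
      } else if (fmt$bits == 32) {
        readBin(data_raw, integer(), n, size = 4, endian = "little") / 2^31
      } else stop("unsupported PCM bit depth: ", fmt$bits)
    },
    "3" = {  # IEEE float
      readBin(data_raw, numeric(), n, size = n_bytes, endian = "little")
    },
    stop("unsupported WAV audio format code: ", fmt$audio_format))

  if (fmt$n_channels > 1L) {
    if (!mixdown)
      stop("multi-channel WAV; pass mixdown = TRUE to average channels")
    dim(x) <- c(fmt$n_channels, length(x) %/% fmt$n_channels)
    x <- colMeans(x)
  }
  list(samples = x, rate = fmt$rate, bits = fmt$bits,
       format = if (fmt$audio_format == 3) "float" else "pcm")
}

#' Write a mono WAV file
#'
#' @param samples Numeric vector of samples (nominally in `[-1, 1]`).
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @param format `"float32"` (default, lossless to single precision),
#'   `"pcm16"` or `"pcm24"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, format = c("float32", "pcm16", "pcm24")) {
  format <- match.arg(format)
  bits <- switch(format, float32 = 32L, pcm16 = 16L, pcm24 = 24L)
  code <- if (format == "float32") 3L else 1L
  n_bytes <- bits %/% 8L
  data_size <- length(samples) * n_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * n_bytes), con, size = 4, endian = "little")
  writeBin(as.integer(n_bytes), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(samples, con, size = 4, endian = "little")
  } else if (format == "pcm16") {
    v <- as.integer(pmax(pmin(round(samples * 2^15), 2^15 - 1), -2^15))
    writeBin(v, con, size = 2, endian = "little")
  } else {
    v <- pmax(pmin(round(samples * 2^23), 2^23 - 1), -2^23)
    v <- ifelse(v < 0, v + 2^24, v)
    b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}
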