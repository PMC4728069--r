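#' @name wav-io
#' @title WAV file input and output
#' @description
#' A minimal RIFF/WAVE codec supporting 16/24/32-bit integer PCM and
#' 32-bit IEEE float, mono or multichannel. Samples are normalized to
#' floats in \eqn{[-1, 1]} on read; multichannel files are reduced to
#' channel 1 with a warning (the denoiser is defined for mono signals).
NULL

#' Read a WAV file
#'
#' @param path Path to a PCM (16/24/32-bit) or float32 WAV file.
#' @return An [audio_signal()] with samples in \eqn{[-1, 1]}.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("format error: not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("format error: not a WAVE file: ", path)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      chunk <- readBin(con, "raw", sz + sz %% 2)
      fmt <- list(
        audio_format = readBin(chunk[1:2], "integer", 1, 2, endian = "little",
                               signed = FALSE),
        channels = readBin(chunk[3:4], "integer", 1, 2, endian = "little",
                           signed = FALSE),
        sample_rate = readBin(chunk[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(chunk[15:16], "integer", 1, 2, endian = "little",
                       signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (length(data_raw) < sz) {
        stop("format error: truncated data chunk in ", path)
      }
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("format error: missing fmt/data chunk in ", path)
  }
  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes
  samples <- if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", n_total, 4, endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", n_total, 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 32L) {
    readBin(data_raw, "integer", n_total, 4, endian = "little") / 2147483648
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3)
    v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else {
    stop("format error: unsupported WAV encoding (format ", fmt$audio_format,
         ", ", fmt$bits, " bits)")
  }
  if (fmt$channels > 1L) {
    warning("multichannel WAV (", fmt$channels, " channels): using channel 1")
    samples <- samples[seq(1, length(samples), by = fmt$channels)]
  }
  if (length(samples) == 0L) stop("format error: empty data chunk in ", path)
  audio_signal(samples, fmt$sample_rate)
}

#' Write a WAV file
#'
#' Samples outside \eqn{[-1, 1]} are clipped with a warning before
#' integer encodings.
#'
#' @param path Output path.
#' @param signal An [audio_signal()].
#' @param encoding `"pcm16"`, `"pcm24"`, `"pcm32"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(path, signal, encoding = c("pcm16", "float32",
                                                 "pcm24", "pcm32")) {
  stopifnot(inherits(signal, "audio_signal"))
  encoding <- match.arg(encoding)
  x <- signal$samples
  if (encoding != "float32" && any(abs(x) > 1)) {
    warning(sum(abs(x) > 1), " sample(s) outside [-1, 1] clipped")
    x <- pmin(pmax(x, -1), 1)
  }
  fs <- as.integer(round(signal$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  bits <- switch(encoding, pcm16 = 16L, pcm24 = 24L, pcm32 = 32L,
                 float32 = 32L)
  fmt_code <- if (encoding == "float32") 3L else 1L
  bytes <- bits %/% 8L
  data_size <- length(x) * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                   # mono
  writeBin(fs, con, 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, 4, endian = "little")
  writeBin(as.integer(bytes), con, 2, endian = "little")
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (encoding == "float32") {
    writeBin(x, con, 4, endian = "little")
  } else if (encoding == "pcm16") {
    v <- as.integer(pmin(round(x * 32768), 32767))
    writeBin(v, con, 2, endian = "little")
  } else if (encoding == "pcm32") {
    v <- as.integer(pmin(pmax(round(x * 2147483648), -2147483647), 2147483647))
    writeBin(v, con, 4, endian = "little")
  } else {                                                  # pcm24
    v <- pmin(round(x * 8388608), 8388607)
    v <- ifelse(v < 0, v + 16777216, v)
    b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(as.integer(b)), con)
  }
  invisible(path)
}
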