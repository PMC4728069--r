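#' Read an interval label file
#'
#' Parses tab-separated label tracks in the Audacity dialect:
#' `start_s<TAB>end_s<TAB>label` per line, with labels `noise` or
#' `song`. Intervals are validated (end after start, no same-kind
#' overlap) and returned sorted by start time.
#'
#' @param path Path to a TSV label file.
#' @return A data frame with columns `start_s`, `end_s`, `kind`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("annotation error: empty label file (need >= 1 noise and song interval)")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    stop("annotation error: each line must be start<TAB>end<TAB>label")
  }
  labels <- data.frame(
    start_s = as.numeric(vapply(parts, `[[`, "", 1L)),
    end_s = as.numeric(vapply(parts, `[[`, "", 2L)),
    kind = trimws(vapply(parts, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(labels$start_s)) || any(is.na(labels$end_s))) {
    stop("annotation error: non-numeric interval boundary")
  }
  validate_labels(labels)
}

#' Write an interval label file
#'
#' @param path Output path.
#' @param labels Data frame with columns `start_s`, `end_s`, `kind`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(path, labels) {
  labels <- validate_labels(labels)
  writeLines(sprintf("%.6f\t%.6f\t%s", labels$start_s, labels$end_s,
                     labels$kind), path)
  invisible(path)
}

#' Down-sample a signal
#'
#' Anti-alias low-pass filtering (zero-phase FIR with cutoff just below
#' the new Nyquist frequency) followed by rate conversion at arbitrary
#' target rates by interpolation of the band-limited signal. Restricting
#' the frequency range this way also discards all noise above the new
#' Nyquist, which on its own can rescue a recording swamped by
#' high-frequency noise.
#'
#' @param signal An [audio_signal()].
#' @param target_rate New sample rate in Hz (below the current rate).
#' @return An [audio_signal()] at `target_rate`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 500 * (0:44099) / 44100), 44100)
#' y <- downsample(x, 22000)
#' @export
downsample <- function(signal, target_rate) {
  stopifnot(inherits(signal, "audio_signal"))
  if (target_rate >= signal$sample_rate) {
    stop("target rate must be below the current sample rate (",
         signal$sample_rate, " Hz)")
  }
  if (target_rate <= 0) stop("target rate must be positive")
  new_nyq <- target_rate / 2
  aa <- filter_spec("low-pass", 0, high_hz = 0.9 * new_nyq,
                    transition_frac = 0.2)
  filtered <- apply_filter(signal, aa)
  n <- length(signal$samples)
  t_old <- (seq_len(n) - 1) / signal$sample_rate
  n_new <- floor((n - 1) * target_rate / signal$sample_rate) + 1
  t_new <- (seq_len(n_new) - 1) / target_rate
  y <- stats::spline(t_old, filtered$samples, xout = t_new,
                     method = "fmm")$y
  audio_signal(y, target_rate)
}

#' Short-time Fourier magnitude grid
#'
#' Computes the magnitude spectrogram: the signal is cut into
#' Hann-windowed frames of `window_len` samples advancing by
#' `window_len - overlap`, each frame's spectrum is taken, and the
#' one-sided magnitudes are stacked. There are
#' `floor((n - overlap) / (window_len - overlap))` frames and
#' `window_len / 2 + 1` frequency bins.
#'
#' @param signal An [audio_signal()].
#' @param window_len Frame length in samples (even; default 512).
#' @param overlap Samples shared by consecutive frames (default 50%).
#' @return A matrix (frames in columns, frequency bins in rows) of class
#'   `spectrogram`, with attributes `freq_hz`, `time_s`, `window_len`,
#'   `overlap`.
#' @export
spectrogram <- function(signal, window_len = 512, overlap = window_len / 2) {
  stopifnot(inherits(signal, "audio_signal"))
  n <- length(signal$samples)
  window_len <- as.integer(window_len)
  overlap <- as.integer(overlap)
  if (window_len < 2L || window_len %% 2L != 0L || window_len > n) {
    stop("window_len must be even, >= 2 and <= signal length")
  }
  if (overlap < 0L || overlap >= window_len) {
    stop("overlap must satisfy 0 <= overlap < window_len")
  }
  hop <- window_len - overlap
  n_frames <- (n - overlap) %/% hop
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, window_len - 1) / window_len)
  frames <- vapply(seq_len(n_frames), function(j) {
    signal$samples[seq((j - 1) * hop + 1, length.out = window_len)] * win
  }, numeric(window_len))
  spec <- stats::mvfft(frames)[seq_len(window_len / 2 + 1), , drop = FALSE]
  mag <- Mod(spec)
  structure(mag,
            freq_hz = seq(0, window_len / 2) * signal$sample_rate / window_len,
            time_s = (seq_len(n_frames) - 1) * hop / signal$sample_rate +
              window_len / 2 / signal$sample_rate,
            window_len = window_len, overlap = overlap,
            class = c("spectrogram", "matrix", "array"))
}

#' Render a spectrogram to the active graphics device
#'
#' dB-scaled grayscale image, time on the horizontal axis.
#'
#' @param x A `spectrogram`.
#' @param dynamic_range_db Range below the peak to display (default 60).
#' @param ... Passed to [graphics::image()].
#' @export
plot.spectrogram <- function(x, dynamic_range_db = 60, ...) {
  db <- 20 * log10(pmax(unclass(x), .Machine$double.eps))
  top <- max(db)
  db <- pmax(db, top - dynamic_range_db)
  graphics::image(attr(x, "time_s"), attr(x, "freq_hz"), t(db),
                  col = grDevices::grey.colors(256, start = 1, end = 0,
                                               rev = TRUE),
                  xlab = "Time (s)", ylab = "Frequency (Hz)", ...)
  invisible(x)
}
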