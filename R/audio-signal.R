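#' Construct an audio signal
#'
#' The basic currency of the package: a sampled mono waveform together with
#' its sample rate. Samples are dimensionless amplitudes, nominally in
#' \eqn{[-1, 1]}. Multichannel input (a matrix with one column per channel)
#' is reduced to the first channel with a warning; the denoising algorithm
#' is defined for mono signals.
#'
#' @param samples Numeric vector (or matrix, channels in columns) of finite
#'   amplitude values.
#' @param sample_rate Sampling frequency in Hz (positive).
#' @return An object of class `audio_signal`: a list with elements
#'   `samples` and `sample_rate`.
#' @examples
#' s <- audio_signal(sin(2 * pi * 440 * (0:999) / 8000), 8000)
#' duration(s)
#' @export
audio_signal <- function(samples, sample_rate) {
  if (is.matrix(samples)) {
    if (ncol(samples) > 1) {
      warning("multichannel input: using channel 1 of ", ncol(samples))
    }
    samples <- samples[, 1]
  }
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("audio signal must contain at least one sample")
  }
  if (!all(is.finite(samples))) {
    stop("audio signal contains non-finite samples")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a single positive number")
  }
  sample_rate <- as.numeric(sample_rate)
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sample_rate, duration(x)))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Duration of an audio signal in seconds
#' @param x An `audio_signal`.
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  length(x$samples) / x$sample_rate
}

# Coerce an audio_signal or bare numeric vector to samples; internal.
as_samples <- function(x) {
  if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
}
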