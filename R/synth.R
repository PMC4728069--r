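#' @name synth
#' @title Synthetic test signals and coloured noise
#' @description
#' Parametric generators for the signals used to characterise the
#' denoiser without field data: stepped multi-frequency tones, impulse
#' clicks, and white/pink/brown Gaussian noise added at a stated
#' percentage of the signal's RMS strength. All generators are
#' deterministic given their seed, and fixtures carry their ground-truth
#' noise track so the true SNR can be computed alongside the
#' segment-based SnNR.
NULL

#' Stepped multi-frequency tone
#'
#' A concatenation of constant-frequency sinusoid segments, phase
#' continuous at the joins. The default reproduces the classic
#' non-stationarity demonstration: 20, 40 and 80 Hz segments of 100 ms
#' each.
#'
#' @param segment_freqs Frequencies in Hz, one per segment (all below
#'   Nyquist).
#' @param segment_dur_s Duration of each segment in seconds (recycled).
#' @param amplitude Peak amplitude.
#' @param sample_rate Sample rate in Hz.
#' @return An [audio_signal()].
#' @examples
#' stepped_tone()  # 20/40/80 Hz, 100 ms each
#' @export
stepped_tone <- function(segment_freqs = c(20, 40, 80),
                         segment_dur_s = 0.1,
                         amplitude = 1,
                         sample_rate = 8000) {
  if (length(segment_freqs) == 0L) stop("need at least one segment")
  if (any(segment_freqs >= sample_rate / 2)) {
    stop("segment frequency at or above Nyquist (", sample_rate / 2, " Hz)")
  }
  if (any(segment_freqs < 0)) stop("frequencies must be non-negative")
  durs <- rep_len(segment_dur_s, length(segment_freqs))
  if (any(durs <= 0)) stop("segment durations must be positive")
  ns <- round(durs * sample_rate)
  # per-sample instantaneous frequency, then cumulative phase
  freq_per_sample <- rep(segment_freqs, times = ns)
  phase <- 2 * pi * cumsum(freq_per_sample) / sample_rate
  audio_signal(amplitude * sin(phase), sample_rate)
}

#' Impulse click
#'
#' A single-sample impulse in silence: the canonical broadband test
#' signal, containing all frequencies at equal magnitude.
#'
#' @param dur_s Total duration in seconds.
#' @param position_s Time of the impulse (within the duration).
#' @param amplitude Impulse amplitude.
#' @param sample_rate Sample rate in Hz.
#' @return An [audio_signal()].
#' @export
click <- function(dur_s = 1, position_s = dur_s / 2, amplitude = 1,
                  sample_rate = 8000) {
  n <- round(dur_s * sample_rate)
  if (n < 1L) stop("duration too short")
  pos <- floor(position_s * sample_rate) + 1L
  if (position_s < 0 || pos > n) {
    stop("impulse position outside the signal duration")
  }
  x <- numeric(n)
  x[pos] <- amplitude
  audio_signal(x, sample_rate)
}

#' Coloured Gaussian noise
#'
#' White noise is i.i.d. Gaussian (flat power spectrum). Pink
#' (power \eqn{\propto 1/f}) and brown (power \eqn{\propto 1/f^2}) noise
#' are produced by shaping the spectrum of white Gaussian noise by
#' \eqn{f^{-\beta/2}} with \eqn{\beta = 1, 2}, zeroing the DC bin, and
#' renormalizing to unit variance so that the colour changes only the
#' spectral tilt, not the strength.
#'
#' @param n Number of samples (>= 2).
#' @param color `"white"`, `"pink"` or `"brown"`.
#' @param seed Optional integer seed; same seed, same noise.
#' @param sample_rate Sample rate attached to the result (Hz).
#' @return An [audio_signal()] with (population) unit variance for
#'   pink/brown; white noise has unit variance in expectation.
#' @export
colored_noise <- function(n, color = c("white", "pink", "brown"),
                          seed = NULL, sample_rate = 8000) {
  color <- match.arg(color)
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 samples")
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n)
  if (color != "white") {
    beta <- if (color == "pink") 1 else 2
    X <- stats::fft(x)
    # two-sided frequency index; DC weight 0 to avoid the 1/f singularity
    k <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1)))
    w <- c(0, k[-1]^(-beta / 2))
    x <- Re(stats::fft(X * w, inverse = TRUE)) / n
    x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  }
  audio_signal(x, sample_rate)
}

#' Root-mean-square amplitude
#' @param x An [audio_signal()] or numeric vector.
#' @return RMS value.
#' @export
rms <- function(x) {
  s <- as_samples(x)
  sqrt(mean(s^2))
}

#' Add noise at a percentage of signal strength
#'
#' Scales the noise so that its RMS equals `strength_pct` percent of the
#' signal's RMS, then adds it. 100% strength therefore corresponds to a
#' true SNR of 0 dB, and 50% to \eqn{10\log_{10} 4 \approx 6.02} dB.
#'
#' @param signal,noise [audio_signal()]s (or numeric vectors) of equal
#'   length and sample rate.
#' @param strength_pct Noise strength as a percentage of signal RMS
#'   (>= 0).
#' @return A list with `mixed` (the noisy [audio_signal()]), `noise`
#'   (the scaled ground-truth noise track) and `gain` (the scale factor
#'   applied to the noise).
#' @export
mix_at_strength <- function(signal, noise, strength_pct) {
  s <- as_samples(signal)
  v <- as_samples(noise)
  if (length(s) != length(v)) stop("signal and noise must have equal length")
  if (inherits(signal, "audio_signal") && inherits(noise, "audio_signal") &&
      signal$sample_rate != noise$sample_rate) {
    stop("signal and noise must share a sample rate")
  }
  if (strength_pct < 0) stop("strength_pct must be >= 0")
  fs <- if (inherits(signal, "audio_signal")) signal$sample_rate else NA_real_
  if (strength_pct == 0) {
    z <- numeric(length(s))
    mixed <- if (is.na(fs)) s else audio_signal(s, fs)
    return(list(mixed = mixed, noise = z, gain = 0))
  }
  rs <- rms(s)
  rv <- rms(v)
  if (rs == 0) stop("degenerate input: zero-RMS signal cannot set a noise strength")
  if (rv == 0) stop("degenerate input: zero-RMS noise track")
  g <- (strength_pct / 100) * rs / rv
  scaled <- g * v
  mixed <- if (is.na(fs)) s + scaled else audio_signal(s + scaled, fs)
  list(mixed = mixed, noise = scaled, gain = g)
}

#' Annotated noisy stepped-tone fixture
#'
#' Builds the standard synthetic benchmark: a stepped tone padded with
#' pure-noise margins on both sides, polluted with coloured noise at a
#' given percentage of the tone's RMS. The margins play the role of the
#' manually labelled "silence" intervals of a field recording, so SnNR
#' and the success ratio can be computed exactly as for real data, while
#' the returned ground-truth tracks also allow the true SNR.
#'
#' @param strength_pct Noise strength (% of tone RMS) over the whole
#'   recording.
#' @param color Noise colour (see [colored_noise()]).
#' @param seed Integer seed.
#' @param segment_freqs,segment_dur_s,sample_rate Passed to
#'   [stepped_tone()].
#' @param margin_s Duration of each pure-noise margin in seconds.
#' @return A list with `rec` (an [annotated_recording()] of the noisy
#'   signal), `clean` (tone with silent margins), `noise` (the scaled
#'   noise track), and `labels`.
#' @export
noisy_tone_fixture <- function(strength_pct = 100,
                               color = "white",
                               seed = 1,
                               segment_freqs = c(20, 40, 80),
                               segment_dur_s = 0.1,
                               sample_rate = 8000,
                               margin_s = 0.5) {
  tone <- stepped_tone(segment_freqs, segment_dur_s, amplitude = 1,
                       sample_rate = sample_rate)
  n_margin <- round(margin_s * sample_rate)
  clean <- c(numeric(n_margin), tone$samples, numeric(n_margin))
  noise <- colored_noise(length(clean), color, seed, sample_rate)
  # strength is relative to the tone itself, not the zero-padded track
  g <- (strength_pct / 100) * rms(tone$samples) / rms(noise$samples)
  scaled <- g * noise$samples
  mixed <- clean + scaled
  # a recorder's gain keeps the waveform inside [-1, 1]; normalize the
  # whole fixture by its peak (one common factor, so SNR, SnNR and the
  # success ratio are unchanged and the ground-truth tracks stay aligned)
  peak <- max(abs(mixed))
  if (peak > 1) {
    mixed <- mixed / peak
    clean <- clean / peak
    scaled <- scaled / peak
  }
  noisy <- audio_signal(mixed, sample_rate)
  t_tone <- length(tone$samples) / sample_rate
  labels <- rbind(
    data.frame(start_s = 0, end_s = margin_s, kind = "noise"),
    data.frame(start_s = margin_s, end_s = margin_s + t_tone, kind = "song"),
    data.frame(start_s = margin_s + t_tone,
               end_s = margin_s + t_tone + margin_s, kind = "noise")
  )
  list(rec = annotated_recording(noisy, labels),
       clean = audio_signal(clean, sample_rate),
       noise = scaled,
       labels = labels)
}
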