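# Shared helpers for the test suite. All fixtures are generated in code.

pure_sine <- function(freq_hz, dur_s = 1, fs = 8000, amplitude = 1) {
  audio_signal(amplitude * sin(2 * pi * freq_hz * (seq_len(dur_s * fs) - 1) / fs),
               fs)
}

# log-log periodogram slope of a noise realization (DC excluded)
periodogram_slope <- function(x) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  k <- 2:(n %/% 2)                 # positive frequencies, DC/Nyquist excluded
  f <- (k - 1) / n
  stats::coef(stats::lm(log10(p[k]) ~ log10(f)))[[2]]
}

# independent exhaustive-scan oracle for the entropy depth rule:
# decompose fully to `cap`, then scan the per-level maxima from the top.
best_level_oracle <- function(x, wavelet, cap) {
  tr <- wp_decompose(x, wavelet, cap, "symmetric")
  maxent <- vapply(seq_len(cap), function(l) {
    max(vapply(wp_level(tr, l), node_entropy, numeric(1)))
  }, numeric(1))
  for (l in seq_len(cap - 1)) {
    if (maxent[l] < maxent[l + 1]) return(l)
  }
  as.integer(cap)
}
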