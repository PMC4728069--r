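Package: wpdenoise
Title: Wavelet Packet Denoising for Birdsong Field Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Removes stationary background noise from bioacoustic field
    recordings using a wavelet packet decomposition with an
    entropy-selected decomposition depth and soft thresholding at 4.5
    standard deviations of the finest-scale detail coefficients,
    optionally followed by a species-specific band-pass or low-pass
    finite-impulse-response post-filter. Includes segment-based
    evaluation metrics (signal-plus-noise to noise ratio, success
    ratio, peak signal-to-noise ratio) computed from labelled
    noise-only and song intervals, a synthetic generator for stepped
    multi-frequency tones, impulse clicks and white/pink/brown noise
    at a stated percentage of signal strength, WAV input/output,
    down-sampling, spectrogram computation, and a command-line
    interface for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
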