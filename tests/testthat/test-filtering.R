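test_that("band-pass designs meet the stopband and passband specs", {
  filt <- design_filter(filter_spec("band-pass", 500, 2000), 16000)
  dc <- 20 * log10(Mod(filter_response(filt, 0)))
  expect_lt(dc, -40)
  mid <- 20 * log10(Mod(filter_response(filt, c(800, 1000, 1500))))
  expect_true(all(abs(mid) < 0.5))
  # linear phase: symmetric taps
  expect_equal(filt$coef, rev(filt$coef), tolerance = 1e-12)
})

test_that("designs reject cutoffs at or above Nyquist", {
  expect_error(design_filter(filter_spec("low-pass", 0, 9000), 16000),
               "Nyquist")
  expect_error(filter_spec("band-pass", 0, 2000), "low_hz > 0")
  expect_error(filter_spec("low-pass", 100, 2000), "low-pass")
  expect_error(filter_spec("band-pass", 2000, 500), "low_hz < high_hz")
})

test_that("filtering is zero-phase, linear, and maps silence to silence", {
  fs <- 16000
  spec <- filter_spec("band-pass", 500, 2000)
  z <- apply_filter(audio_signal(rep(0, fs), fs), spec)
  expect_equal(z$samples, rep(0, fs))
  set.seed(23)
  x <- audio_signal(rnorm(fs, sd = 0.2), fs)
  y <- audio_signal(rnorm(fs, sd = 0.2), fs)
  fx <- apply_filter(x, spec)$samples
  fy <- apply_filter(y, spec)$samples
  combo <- audio_signal(2 * x$samples - 3 * y$samples, fs)
  expect_equal(apply_filter(combo, spec)$samples, 2 * fx - 3 * fy,
               tolerance = 1e-9)
  # zero phase: a passband tone comes out aligned with the input
  tone <- pure_sine(1000, 1, fs, amplitude = 0.5)
  ft <- apply_filter(tone, spec)
  mid <- 2000:14000
  expect_gt(cor(tone$samples[mid], ft$samples[mid]), 0.99999)
})

test_that("stopband tones are attenuated by at least 40 dB", {
  fs <- 16000
  spec <- filter_spec("band-pass", 500, 2000)
  tone <- pure_sine(50, 1, fs)
  out <- apply_filter(tone, spec)
  expect_lt(20 * log10(rms(out) / rms(tone)), -40)
})

test_that("filtering is idempotent to within ripple", {
  fs <- 16000
  spec <- filter_spec("band-pass", 500, 2000)
  x <- pure_sine(1200, 1, fs, amplitude = 0.5)
  once <- apply_filter(x, spec)
  twice <- apply_filter(once, spec)
  mid <- 2000:14000
  db_change <- 20 * log10(rms(twice$samples[mid]) / rms(once$samples[mid]))
  expect_lt(abs(db_change), 1)
})

test_that("species bands resolve to the expected filters", {
  tab <- species_bands()
  expect_true(all(c("key", "low_hz", "high_hz") %in% names(tab)))
  boom <- tab[tab$key == "kakapo.booming", ]
  expect_equal(c(boom$low_hz, boom$high_hz), c(0, 800))
  spec <- resolve_band("kakapo.booming", 44100)
  expect_identical(spec$kind, "low-pass")
  expect_equal(spec$high_hz, 800)
  spec2 <- resolve_band("brown_kiwi.male", 44100)
  expect_identical(spec2$kind, "band-pass")
  expect_error(resolve_band("moa.call", 44100), "unknown species")
  # a band above a low Nyquist is clipped with a warning
  expect_warning(resolve_band("ni_saddleback.song", 16000), "clipped")
})

test_that("denoise_and_filter composes the two stages", {
  fs <- 8000
  fx <- noisy_tone_fixture(strength_pct = 50, seed = 6, sample_rate = fs)
  x <- fx$rec$audio
  cfg <- denoise_config()
  den <- denoise(x, cfg)
  # full-band limit equals denoising alone
  expect_equal(denoise_and_filter(x, cfg, band = c(0, fs / 2))$samples,
               den$samples, tolerance = 1e-6)
  # out-of-band interference is attenuated >= 40 dB by the post-filter
  interf <- pure_sine(3000, duration(x), fs, amplitude = 0.3)
  noisy2 <- audio_signal(x$samples + interf$samples, fs)
  df <- denoise_and_filter(noisy2, cfg, band = c(0, 500))
  p_interf <- function(s) {
    X <- Mod(stats::fft(s))^2
    bin <- round(3000 * length(s) / fs) + 1
    sum(X[(bin - 3):(bin + 3)])
  }
  expect_lt(10 * log10(p_interf(df$samples) / p_interf(noisy2$samples)), -40)
  expect_error(denoise_and_filter(x, cfg, band = "unknown.species"),
               "unknown species")
})

test_that("post-filtering residual broadband noise improves SnNR", {
  # pink noise leaves residual energy after wavelet denoising, so the
  # band-limited post-filter has something left to remove
  fx <- noisy_tone_fixture(strength_pct = 150, color = "pink", seed = 8,
                           sample_rate = 8000)
  cfg <- denoise_config()
  d <- denoise(fx$rec$audio, cfg)
  df <- denoise_and_filter(fx$rec$audio, cfg, band = c(0, 500))
  rec_d <- annotated_recording(d, fx$labels)
  rec_df <- annotated_recording(df, fx$labels)
  expect_gte(snnr(rec_df), snnr(rec_d))
})
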