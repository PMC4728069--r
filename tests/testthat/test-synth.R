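test_that("stepped tones have the right length, peaks and bound", {
  tone <- stepped_tone(c(20, 40, 80), 0.1, amplitude = 1, sample_rate = 1000)
  expect_length(tone$samples, 300L)
  expect_lte(max(abs(tone$samples)), 1)
  # periodogram peaks at the three segment frequencies
  long <- stepped_tone(c(20, 40, 80), 1, sample_rate = 1000)
  for (f0 in c(20, 40, 80)) {
    seg <- long$samples[seq((which(c(20, 40, 80) == f0) - 1) * 1000 + 1,
                            length.out = 1000)]
    p <- Mod(stats::fft(seg))^2
    peak_hz <- which.max(p[2:500])   # 1 Hz resolution over 1 s
    expect_equal(peak_hz, f0)
  }
  expect_error(stepped_tone(600, sample_rate = 1000), "Nyquist")
})

test_that("stepped tones are phase continuous at segment joins", {
  tone <- stepped_tone(c(100, 200), 0.1, sample_rate = 8000)
  d <- diff(tone$samples)
  # a phase jump would produce a first-difference outlier at the join;
  # bound by the maximum slope of the faster sinusoid
  expect_lte(max(abs(d)), 2 * pi * 200 / 8000 + 1e-9)
})

test_that("clicks are single-sample impulses with flat spectra", {
  c1 <- click(1, 0.5, amplitude = 1, sample_rate = 8000)
  expect_identical(sum(c1$samples != 0), 1L)
  expect_equal(sum(c1$samples^2), 1)
  mag <- Mod(stats::fft(c1$samples))
  expect_lt(max(mag) - min(mag), 1e-9)
  expect_error(click(1, 2), "position")
})

test_that("noise colours are reproducible and decorrelated across seeds", {
  a <- colored_noise(4096, "pink", seed = 7)
  b <- colored_noise(4096, "pink", seed = 7)
  expect_identical(a$samples, b$samples)
  c <- colored_noise(65536, "white", seed = 1)
  d <- colored_noise(65536, "white", seed = 2)
  expect_lt(abs(cor(c$samples, d$samples)), 0.05)
  expect_error(colored_noise(4096, "mauve"), "arg")
})

test_that("spectral slopes match the noise colour definitions", {
  set.seed(1)
  slopes <- sapply(c("white", "pink", "brown"), function(cl) {
    mean(sapply(1:4, function(s) {
      periodogram_slope(colored_noise(2^15, cl, seed = s)$samples)
    }))
  })
  expect_lt(abs(slopes[["white"]] - 0), 0.2)
  expect_lt(abs(slopes[["pink"]] - -1), 0.25)
  expect_lt(abs(slopes[["brown"]] - -2), 0.25)
})

test_that("pink and brown noise are unit variance with zero DC", {
  for (cl in c("pink", "brown")) {
    x <- colored_noise(8192, cl, seed = 3)$samples
    expect_equal(mean((x - mean(x))^2), 1, tolerance = 1e-9)
    expect_equal(mean(x), 0, tolerance = 1e-9)
  }
})

test_that("mixing at strength sets the exact RMS ratio", {
  fs <- 8000
  sig <- pure_sine(100, 1, fs)
  noise <- colored_noise(fs, "white", seed = 9, sample_rate = fs)
  m0 <- mix_at_strength(sig, noise, 0)
  expect_identical(m0$mixed$samples, sig$samples)
  m100 <- mix_at_strength(sig, noise, 100)
  expect_equal(snr(mean(sig$samples^2), mean(m100$noise^2)), 0,
               tolerance = 1e-12)
  m50 <- mix_at_strength(sig, noise, 50)
  expect_equal(snr(mean(sig$samples^2), mean(m50$noise^2)), 10 * log10(4),
               tolerance = 1e-12)
  # subtracting the returned noise track recovers the signal exactly
  expect_equal(m50$mixed$samples - m50$noise, sig$samples, tolerance = 1e-12)
  expect_error(mix_at_strength(audio_signal(rep(0, fs), fs), noise, 50),
               "degenerate")
})

test_that("the annotated fixture is internally consistent", {
  fx <- noisy_tone_fixture(strength_pct = 100, seed = 4)
  expect_s3_class(fx$rec, "annotated_recording")
  n <- length(fx$rec$audio$samples)
  expect_equal(fx$clean$samples + fx$noise, fx$rec$audio$samples,
               tolerance = 1e-12)
  expect_lte(max(abs(fx$rec$audio$samples)), 1)
  # margins of the clean track are silent
  margin_n <- round(0.5 * fx$rec$audio$sample_rate)
  expect_equal(fx$clean$samples[seq_len(margin_n)], rep(0, margin_n))
  # 100% strength means equal tone/noise RMS (measured over the tone span)
  tone_idx <- (margin_n + 1):(n - margin_n)
  expect_equal(mean(fx$clean$samples[tone_idx]^2), mean(fx$noise^2),
               tolerance = 1e-9)
})
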