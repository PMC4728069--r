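test_that("segment power is mean squared amplitude over the union", {
  fs <- 1000
  lab <- data.frame(start_s = 0.1, end_s = 0.4, kind = "song")
  expect_equal(segment_power(audio_signal(rep(2, fs), fs), lab), 4)
  expect_equal(segment_power(audio_signal(rep(0, fs), fs), lab), 0)
  expect_equal(segment_power(audio_signal(rep(c(1, -1), fs / 2), fs), lab), 1)
})

test_that("snr follows 10 log10(S/N)", {
  expect_equal(snr(1, 1), 0)
  expect_equal(snr(100, 1), 20)
  expect_error(snr(1, 0), "degenerate")
})

test_that("snnr compares song-region to noise-region power", {
  fs <- 1000
  # piecewise-constant recording: noise margin amplitude a, song sqrt(10)*a
  x <- c(rep(0.1, 200), rep(0.1 * sqrt(10), 600), rep(0.1, 200))
  labels <- data.frame(start_s = c(0, 0.2, 0.8), end_s = c(0.2, 0.8, 1),
                       kind = c("noise", "song", "noise"))
  rec <- annotated_recording(audio_signal(x, fs), labels)
  expect_equal(snnr(rec), 10, tolerance = 1e-9)
  # equal powers give 0 dB
  y <- rep(0.3, fs)
  rec0 <- annotated_recording(audio_signal(y, fs), labels)
  expect_equal(snnr(rec0), 0, tolerance = 1e-12)
})

test_that("snnr is invariant under rescaling the whole recording", {
  fx <- noisy_tone_fixture(strength_pct = 80, seed = 3)
  base <- snnr(fx$rec)
  for (c in c(0.1, -2, 7)) {
    scaled <- annotated_recording(
      audio_signal(c * fx$rec$audio$samples, fx$rec$audio$sample_rate),
      fx$labels)
    expect_equal(snnr(scaled), base, tolerance = 1e-12)
  }
})

test_that("snnr equals 10 log10(1 + 10^(SNR/10)) on constructed fixtures", {
  # noise orthogonal to the signal in the song region with exactly equal
  # power in both regions, so the decomposition P_song = S + N is exact
  fs <- 2000
  set.seed(13)
  n_margin <- 500
  n_song <- 1000
  sig <- 0.6 * sin(2 * pi * 40 * (1:n_song) / fs)
  for (target_snr_db in c(-6, 0, 10)) {
    noise_song <- rnorm(n_song)
    noise_song <- noise_song - sig * sum(noise_song * sig) / sum(sig^2)
    N <- mean(sig^2) / 10^(target_snr_db / 10)
    noise_song <- noise_song * sqrt(N / mean(noise_song^2))
    margin <- rnorm(n_margin)
    margin <- margin * sqrt(N / mean(margin^2))
    x <- c(margin, sig + noise_song, rep(0, n_margin))
    labels <- data.frame(
      start_s = c(0, n_margin / fs),
      end_s = c(n_margin / fs, (n_margin + n_song) / fs),
      kind = c("noise", "song"))
    rec <- annotated_recording(audio_signal(x, fs), labels)
    expect_equal(snnr(rec), 10 * log10(1 + 10^(target_snr_db / 10)),
                 tolerance = 1e-9)
  }
})

test_that("success ratio is the log10 variance ratio", {
  set.seed(17)
  nb <- rnorm(5000)
  pv <- function(x) mean((x - mean(x))^2)
  after <- mean(nb) + (nb - mean(nb)) / sqrt(10)   # variance ratio 10
  expect_equal(success_ratio(nb, after), 1, tolerance = 1e-9)
  expect_equal(success_ratio(nb, nb), 0)
  expect_equal(success_ratio(nb, nb / 10), 2, tolerance = 1e-12)
  # antisymmetry
  nc <- rnorm(5000, sd = 0.3)
  expect_equal(success_ratio(nb, nc), -success_ratio(nc, nb),
               tolerance = 1e-12)
  expect_error(success_ratio(nb, rep(0, 100)), "degenerate")
})

test_that("psnr follows 20 log10(max / rmse)", {
  ref <- c(1, -0.5, 0.25, 0)
  expect_equal(psnr(ref, ref - 0.1), 20, tolerance = 1e-12)
  ref2 <- c(2, 0, 0, 0)
  expect_equal(psnr(ref2, ref2 - 1), 20 * log10(2), tolerance = 1e-9)
  expect_equal(20 * log10(2), 6.0206, tolerance = 1e-4)
  expect_error(psnr(ref, ref), "degenerate")
  expect_error(psnr(ref, ref[-1]), "equal length")
})

test_that("annotation validation catches malformed label sets", {
  fs <- 1000
  x <- audio_signal(rnorm(fs), fs)
  good <- data.frame(start_s = c(0, 0.3), end_s = c(0.3, 0.9),
                     kind = c("noise", "song"))
  expect_s3_class(annotated_recording(x, good), "annotated_recording")
  expect_error(annotated_recording(x, good[1, ]), "at least one")
  bad_overlap <- data.frame(start_s = c(0, 0.2, 0.5), end_s = c(0.3, 0.4, 0.9),
                            kind = c("noise", "noise", "song"))
  expect_error(annotated_recording(x, bad_overlap), "overlap")
  beyond <- data.frame(start_s = c(0, 0.5), end_s = c(0.3, 1.5),
                       kind = c("noise", "song"))
  expect_error(annotated_recording(x, beyond), "beyond")
})
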