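test_that("soft thresholding shrinks towards zero", {
  expect_equal(soft_threshold(5, 2), 3)
  expect_equal(soft_threshold(-1, 2), 0)
  expect_equal(soft_threshold(-5, 2), -3)
  expect_equal(hard_threshold(c(5, -1, -5), 2), c(5, 0, -5))
  expect_error(soft_threshold(1, -0.1), "non-negative")
})

test_that("soft thresholding is non-expansive", {
  set.seed(61)
  x <- rnorm(500, sd = 2)
  y <- rnorm(500, sd = 2)
  for (thr in c(0, 0.3, 1, 4)) {
    sx <- soft_threshold(x, thr)
    expect_true(all(abs(sx) <= abs(x) + 1e-15))
    expect_true(all(abs(sx - soft_threshold(y, thr)) <= abs(x - y) + 1e-12))
  }
})

test_that("tree thresholding equals the elementwise oracle on every leaf", {
  set.seed(71)
  x <- rnorm(900)
  tr <- wp_decompose(x, "db3", 3)
  cfg <- denoise_config()
  out <- threshold_tree(tr, 1, cfg)
  for (i in 0:7) {
    leaf <- wp_node(tr, 3, i)
    oracle <- vapply(leaf, function(v) sign(v) * max(abs(v) - 1, 0), numeric(1))
    expect_equal(wp_node(out, 3, i), oracle)
  }
  # thr = 0 leaves the tree unchanged
  expect_equal(threshold_tree(tr, 0, cfg)$levels, tr$levels)
  # thr above every |coefficient| zeroes the reconstruction
  big <- max(abs(unlist(wp_level(tr, 3)))) + 1
  expect_equal(wp_reconstruct(threshold_tree(tr, big, cfg)), rep(0, 900))
  # approximation exemption leaves leaf 0 untouched
  cfg_ex <- denoise_config(exempt_approximation = TRUE)
  out_ex <- threshold_tree(tr, 1, cfg_ex)
  expect_equal(wp_node(out_ex, 3, 0), wp_node(tr, 3, 0))
  expect_equal(wp_node(out_ex, 3, 1), soft_threshold(wp_node(tr, 3, 1), 1))
})

test_that("noise sigma estimation is linear and zero for silence", {
  z <- wp_decompose(rep(0, 512), "db2", 1)
  expect_identical(estimate_noise_sigma(z), 0)
  set.seed(81)
  x <- rnorm(2048)
  s1 <- estimate_noise_sigma(wp_decompose(x, "db4", 2))
  s2 <- estimate_noise_sigma(wp_decompose(2 * x, "db4", 2))
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
})

test_that("sigma estimation recovers the true noise level", {
  set.seed(91)
  est <- replicate(5, {
    x <- audio_signal(rnorm(16384), 16000)
    estimate_noise_sigma(wp_decompose(x, "dmey", 1))
  })
  expect_equal(mean(est), 1, tolerance = 0.05)
})

test_that("denoising silence returns silence and reduces pure noise", {
  z <- denoise(audio_signal(rep(0, 4096), 8000))
  expect_equal(z$samples, rep(0, 4096))
  set.seed(101)
  for (k in 1:3) {
    x <- audio_signal(rnorm(8192, sd = 0.3), 8000)
    y <- denoise(x)
    expect_lt(var(y$samples), var(x$samples))
    expect_length(y$samples, 8192L)
    expect_identical(y$sample_rate, 8000)
  }
})

test_that("a clean smooth tone passes through almost unchanged", {
  tone <- pure_sine(440, dur_s = 1, fs = 8000)
  y <- denoise(tone)
  expect_gte(cor(tone$samples, y$samples), 0.99)
})

test_that("denoising a noisy tone raises SnNR and the success ratio", {
  fx <- noisy_tone_fixture(strength_pct = 100, color = "white", seed = 12)
  rep <- metrics_report(fx$rec, denoise(fx$rec$audio))
  expect_gt(rep$success_ratio, 0)
  expect_gt(rep$snnr_after_db, rep$snnr_before_db)
})

test_that("wavelet selection maximises input-output correlation", {
  expect_identical(select_wavelet(rnorm(2048), "db2")$best, "db2")
  fx <- noisy_tone_fixture(strength_pct = 50, color = "white", seed = 5)
  cands <- c("db2", "db6", "db10", "dmey")
  sel <- select_wavelet(fx$rec$audio, cands)
  expect_true(all(sel$scores >= -1 & sel$scores <= 1))
  # brute-force re-loop oracle
  x <- fx$rec$audio
  oracle <- vapply(cands, function(nm) {
    y <- denoise(x, denoise_config(wavelet_name = nm))
    cor(x$samples, y$samples)
  }, numeric(1))
  expect_identical(sel$best, cands[[which.max(oracle)]])
  expect_equal(unname(sel$scores), unname(oracle), tolerance = 1e-12)
  expect_error(select_wavelet(rep(1, 1000)), "degenerate")
})
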