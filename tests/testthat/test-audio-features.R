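# The handcrafted audio feature bank and WAV round-tripping.

test_that("block dimensions are 11 / 128 / 224 and concatenate to 363 (or 352)", {
  set.seed(1)
  clip <- audio_clip(rnorm(8000, sd = 0.1), 16000)
  f <- extract_all(clip)
  expect_equal(unname(attr(f, "block_dims")), c(11L, 128L, 224L))
  expect_length(f, 363)
  expect_true(all(is.finite(f)))
  f2 <- extract_all(clip, blocks = c("mfcc", "spectral"))
  expect_length(f2, 352)
  # order is canonical even if blocks are given shuffled
  f3 <- extract_all(clip, blocks = c("spectral", "mfcc"))
  expect_identical(f2, f3)
  expect_error(extract_all(audio_clip(0, 16000)), "data error")
})

test_that("statistical features match a direct DFT oracle", {
  # constant clip: spectrum concentrated in the DC bin
  const <- audio_clip(rep(0.5, 64), 8000)
  f <- statistical_features(const)
  mag <- dft_mag_oracle(rep(0.5, 64))
  expect_equal(unname(f["energy"]), sum(mag^2), tolerance = 1e-9)
  expect_equal(unname(f["max"]), mag[1], tolerance = 1e-9)  # DC bin
  expect_equal(sum(mag[-1] > 1e-9), 0)
  # random clip: every statistic agrees with the oracle spectrum
  set.seed(7)
  x <- rnorm(128)
  fx <- statistical_features(audio_clip(x, 8000))
  magx <- dft_mag_oracle(x)
  expect_equal(unname(fx["mean"]), mean(magx), tolerance = 1e-9)
  expect_equal(unname(fx["median"]), median(magx), tolerance = 1e-9)
  expect_equal(unname(fx["sd"]), sd(magx), tolerance = 1e-9)
  expect_equal(unname(fx["energy"]), sum(magx^2), tolerance = 1e-8)
  expect_equal(unname(fx["rms_energy"]), sqrt(mean(magx^2)), tolerance = 1e-9)
  # all-zero clip: zero energy
  f0 <- statistical_features(audio_clip(numeric(32), 8000))
  expect_equal(unname(f0[["energy"]]), 0)
  expect_equal(unname(f0[["rms_energy"]]), 0)
})

test_that("a pure sine peaks at its own frequency bin", {
  sr <- 16000
  t <- (0:(sr - 1)) / sr
  x <- sin(2 * pi * 440 * t)
  mag <- Mod(fft(x))[1:(sr / 2 + 1)]
  expect_equal(which.max(mag) - 1L, 440L)   # bin resolution is 1 Hz at n = sr
  f <- statistical_features(audio_clip(x, sr))
  expect_gt(f[["max"]], 100 * f[["median"]])
})

test_that("spectral centroid and bandwidth behave analytically", {
  sr <- 16000
  t <- (0:(sr - 1)) / sr
  sine <- audio_clip(sin(2 * pi * 1000 * t), sr)
  f <- spectral_features(sine)
  bin_hz <- sr / 2048
  expect_lt(abs(f[["centroid_mean"]] - 1000), bin_hz)   # within one bin
  expect_lt(f[["bandwidth_mean"]], 5 * bin_hz)          # near-zero spread
  set.seed(2)
  noise <- audio_clip(rnorm(sr), sr)
  fn <- spectral_features(noise)
  expect_lt(abs(fn[["centroid_mean"]] - sr / 4) / (sr / 4), 0.1)
  expect_length(f, 224)
})

test_that("MFCCs are finite on silence and stable under a one-hop shift", {
  silent <- audio_clip(numeric(4096), 16000)
  f <- mfcc_features(silent)
  expect_length(f, 128)
  expect_true(all(is.finite(f)))   # log floor prevents -Inf
  set.seed(5)
  x <- rnorm(16000 * 2)
  a <- mfcc_features(audio_clip(x[1:24000], 16000))
  b <- mfcc_features(audio_clip(x[513:24512], 16000))  # shift by one hop
  expect_lt(sqrt(sum((a - b)^2)) / sqrt(sum(a^2)), 0.01)
})

test_that("amplitude scaling and sign flips act as theory says", {
  set.seed(9)
  x <- rnorm(4096, sd = 0.05)
  clip <- audio_clip(x, 16000)
  f1 <- statistical_features(clip)
  f3 <- statistical_features(audio_clip(3 * x, 16000))
  expect_equal(unname(f3[["energy"]]), unname(9 * f1[["energy"]]),
               tolerance = 1e-9)
  s1 <- spectral_features(clip)
  s3 <- spectral_features(audio_clip(3 * x, 16000))
  expect_equal(s3[["centroid_mean"]], s1[["centroid_mean"]], tolerance = 1e-9)
  # global sign flip leaves every magnitude-based feature unchanged
  expect_equal(statistical_features(audio_clip(-x, 16000)), f1,
               tolerance = 1e-9)
  expect_equal(spectral_features(audio_clip(-x, 16000)), s1, tolerance = 1e-9)
  expect_equal(mfcc_features(audio_clip(-x, 16000)),
               mfcc_features(clip), tolerance = 1e-9)
})

test_that("features survive a 16-bit WAV round trip within quantization tolerance", {
  set.seed(4)
  cfg <- tiny_cfg(L = 2L, seed = 4)
  clip <- gen_audio(cfg)$clips[[1]]
  path <- withr::local_tempfile(fileext = ".wav")
  wav_write(clip, path)
  back <- wav_read(path)
  expect_equal(back$sample_rate, clip$sample_rate)
  expect_equal(back$samples, clip$samples, tolerance = 1e-3)
  fa <- extract_all(clip); fb <- extract_all(back)
  expect_lt(max(abs(fa - fb) / pmax(abs(fa), 1)), 0.05)
})

test_that("preprocessing removes DC, normalizes peaks and improves SNR", {
  set.seed(6)
  x <- 0.3 * sin(2 * pi * 300 * (0:15999) / 16000) + 0.1
  clip <- audio_clip(x, 16000)
  out <- preprocess_audio(clip, dc_remove = TRUE, normalize = TRUE)
  expect_lt(abs(mean(out$samples)), 1e-9)
  expect_equal(max(abs(out$samples)), 1, tolerance = 1e-12)
  # all options off: identity
  same <- preprocess_audio(clip, dc_remove = FALSE, normalize = FALSE)
  expect_identical(same$samples, clip$samples)
  # all-zero clip: unchanged, flagged
  z <- preprocess_audio(audio_clip(numeric(100), 16000), dc_remove = FALSE,
                        normalize = TRUE)
  expect_equal(z$samples, numeric(100))
  expect_equal(attr(z, "warning"), "all-zero clip")
  # spectral subtraction raises the SNR of sine + white noise at 0 dB
  clean <- sin(2 * pi * 500 * (0:31999) / 16000)
  noise <- rnorm(32000, sd = sqrt(mean(clean^2)))   # SNR = 0 dB
  noisy <- audio_clip((clean + noise) / 2, 16000)
  den <- preprocess_audio(noisy, dc_remove = FALSE, normalize = FALSE,
                          denoise = TRUE)
  snr <- function(sig) {
    a <- sum(sig * clean) / sum(clean^2)   # project onto the known clean part
    res <- sig - a * clean
    10 * log10(sum((a * clean)^2) / sum(res^2))
  }
  expect_gt(snr(den$samples), snr(noisy$samples))
})

test_that("resampling preserves duration and tone frequency", {
  t <- (0:7999) / 8000
  clip <- audio_clip(sin(2 * pi * 400 * t), 8000)
  up <- resample_clip(clip, 16000)
  expect_equal(length(up$samples), 16000)
  f <- spectral_features(up)
  expect_lt(abs(f[["centroid_mean"]] - 400), 3 * 16000 / 2048)
  expect_identical(resample_clip(clip, 8000), clip)
})
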