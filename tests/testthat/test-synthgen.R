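test_that("the default fixture is 10 s of 360 Hz samples with a dominant R wave", {
  s <- gen_ecg(ecg_spec())
  expect_length(s$samples, 3600L)
  expect_equal(s$fs, 360)
  expect_equal(duration(s), 10)
  expect_error(ecg_spec(fs = 360, duration = 1 / 7),
               class = "stecg_invalid_param")
})

test_that("jitter-free beats put R peaks exactly one period apart", {
  s <- gen_ecg(ecg_spec(heart_rate = 60, duration = 10, jitter = 0))
  x <- s$samples
  peaks <- which(diff(sign(diff(x))) == -2) + 1L
  rpeaks <- peaks[x[peaks] > 0.5]
  expect_length(rpeaks, 10L)
  expect_true(all(diff(rpeaks) == 360L))
})

test_that("every generator is bit-reproducible under its seed", {
  expect_identical(gen_ecg(ecg_spec(seed = 5)), gen_ecg(ecg_spec(seed = 5)))
  for (kind in c("pli", "gaussian", "baseline_wander", "muscle_artifact",
                 "electrode_motion")) {
    a <- gen_noise(noise_spec(kind, seed = 9), 720, 360)
    b <- gen_noise(noise_spec(kind, seed = 9), 720, 360)
    expect_identical(a, b)
    expect_length(a, 720L)
    expect_true(all(is.finite(a)))
  }
})

test_that("power-line interference is a spectrally pure on-bin sinusoid", {
  v <- gen_noise(noise_spec("pli"), 3600, 360)
  X <- Mod(fft(v))
  bin60 <- 60 * 3600 / 360 + 1           # 1-based positive bin
  bin60n <- 3600 - 60 * 3600 / 360 + 1   # conjugate bin
  expect_lt(max(X[-c(bin60, bin60n)]), 1e-10 * max(X))
  expect_equal(which.max(X[1:1801]), bin60)
})

test_that("baseline wander sits at its spec'd low frequency", {
  v <- gen_noise(noise_spec("baseline_wander"), 3600, 360)
  X <- Mod(fft(v))[1:1801]
  f_dom <- (which.max(X[-1])) * 360 / 3600     # skip DC
  expect_equal(f_dom, 0.2)
  expect_gte(f_dom, 0.15); expect_lte(f_dom, 0.3)
  w <- gen_noise(noise_spec("baseline_wander", bw_mode = "walk"), 3600, 360)
  Xw <- Mod(fft(w))^2
  f <- (0:3599) * 360 / 3600
  inband <- f <= 0.3 | f >= 360 - 0.3
  expect_gt(sum(Xw[inband]) / sum(Xw), 0.99)
})

test_that("muscle artifact and electrode motion occupy their bands", {
  ma <- gen_noise(noise_spec("muscle_artifact"), 3600, 360)
  P <- Mod(fft(ma))^2
  f <- (0:3599) * 360 / 3600
  f <- pmin(f, 360 - f)
  expect_gt(sum(P[f >= 20 & f <= 100]) / sum(P), 0.95)

  em <- gen_noise(noise_spec("electrode_motion", seed = 3), 3600, 360)
  Pe <- Mod(fft(em))^2
  expect_gt(sum(Pe[f < 5]) / sum(Pe), 0.95)
})

test_that("noise mixing hits the target input SNR exactly", {
  clean <- gen_ecg(ecg_spec(seed = 2))
  for (kind in c("pli", "gaussian", "baseline_wander", "muscle_artifact",
                 "electrode_motion")) {
    nz <- gen_noise(noise_spec(kind, seed = 4), 3600, 360)
    for (level in c(0, 5, 10)) {
      mix <- add_noise_at_snr(clean, nz, level)
      got <- 10 * log10(sum(clean$samples^2) / sum(mix$scaled_noise^2))
      expect_lt(abs(got - level), 1e-9)
      expect_equal(mix$noisy$samples, clean$samples + mix$scaled_noise)
    }
  }
  # 0 dB means equal powers, and noise amplitude is homogeneous in the signal
  nz <- gen_noise(noise_spec("gaussian", seed = 4), 3600, 360)
  m0 <- add_noise_at_snr(clean, nz, 0)
  expect_equal(sum(clean$samples^2), sum(m0$scaled_noise^2),
               tolerance = 1e-12)
  clean2 <- ecg_signal(2 * clean$samples, clean$fs)
  m2 <- add_noise_at_snr(clean2, nz, 5)
  m1 <- add_noise_at_snr(clean, nz, 5)
  expect_equal(m2$scaled_noise, 2 * m1$scaled_noise, tolerance = 1e-12)
})

test_that("degenerate mixing inputs are rejected", {
  clean <- gen_ecg(ecg_spec(fs = 120, duration = 2))
  expect_error(add_noise_at_snr(clean, numeric(240), 5),
               class = "stecg_invalid_input")
  expect_error(add_noise_at_snr(clean, rnorm(10), 5),
               class = "stecg_invalid_input")
  expect_error(gen_noise(noise_spec("pli"), 1, 360),
               class = "stecg_invalid_param")
})

test_that("fixture files round-trip through CSV", {
  fx <- make_noisy_fixture(ecg_spec(fs = 120, duration = 2),
                           noise_spec("gaussian", target_snr_db = 5))
  prefix <- file.path(tempdir(), "fx_test")
  write_fixture_csv(fx, prefix)
  df <- read.csv(paste0(prefix, ".csv"))
  expect_equal(df$clean, fx$clean$samples)
  expect_equal(df$noisy, fx$noisy$samples)
  side <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(side$fs, 120)
  unlink(paste0(prefix, c(".csv", ".json")))
})
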