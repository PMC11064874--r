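test_that("signal container validates its invariants", {
  expect_s3_class(ecg_signal(rnorm(10), 360), "ecg_signal")
  expect_error(ecg_signal(c(1, NA, 3), 360), class = "stecg_invalid_input")
  expect_error(ecg_signal(1, 360), class = "stecg_invalid_input")
  expect_error(ecg_signal(rnorm(10), -1), class = "stecg_invalid_input")
  expect_equal(duration(ecg_signal(rnorm(720), 360)), 2)
})

test_that("a constant signal has all its content in the zero-frequency row", {
  for (c0 in c(1, -3.7)) {
    tfr <- forward_st(ecg_signal(rep(c0, 64), 64))
    expect_lt(max(Mod(tfr$values[-1, ])), 1e-10)
    expect_equal(Re(tfr$values[1, ]), rep(c0, 64))
  }
})

test_that("a pure tone peaks at its own frequency bin in every column", {
  fs <- 256; n <- 256
  t <- (0:(n - 1)) / fs
  tfr <- forward_st(ecg_signal(cos(2 * pi * 32 * t), fs))
  peak_rows <- apply(Mod(tfr$values), 2, which.max)
  expect_true(all(peak_rows == 33L))   # bin 32 (1-based row 33)
  expect_equal(tfr_frequencies(tfr)[33], 32)
})

test_that("FFT-based transform agrees with direct quadrature of the defining integral", {
  # tones on a small grid, the independent oracle evaluates the windowed
  # integral per (t, f) pair with a periodised sampled Gaussian
  for (spec in list(c(n = 48, k = 6), c(n = 64, k = 11), c(n = 32, k = 5))) {
    n <- spec[["n"]]; k <- spec[["k"]]
    x <- cos(2 * pi * k * (0:(n - 1)) / n + 0.3)
    S <- forward_st(ecg_signal(x, n))$values
    O <- oracle_st(x)
    rel <- max(Mod(S - O)) / max(Mod(O))
    expect_lt(rel, 1e-6)
  }
})

test_that("inverse transform is exact on roundtrips, impulses and zero planes", {
  withr::with_seed(11, {
    x <- rnorm(128)
    rt <- inverse_st(forward_st(ecg_signal(x, 128)))
    expect_lt(max(abs(rt$samples - x)), 1e-8)
  })
  imp <- numeric(64); imp[11] <- 1
  rt <- inverse_st(forward_st(ecg_signal(imp, 64)))
  expect_lt(max(abs(rt$samples - imp)), 1e-8)

  z <- forward_st(ecg_signal(rnorm(32), 32))
  z$values[] <- 0 + 0i
  expect_equal(inverse_st(z)$samples, numeric(32))
})

test_that("an analytic single-row tone TFR reconstructs the closed-form tone", {
  n <- 64; k0 <- 7
  tfr <- forward_st(ecg_signal(rnorm(n), n))
  tfr$values[] <- 0 + 0i
  cc <- complex(real = 0.4, imaginary = 0.25)
  tfr$values[k0 + 1, ] <- cc      # constant row = marginal coefficient cc
  got <- inverse_st(tfr)$samples
  j <- 0:(n - 1)
  want <- 2 * Re(cc * exp(2i * pi * k0 * j / n))
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("the transform is linear and satisfies the marginal identity", {
  withr::with_seed(12, {
    x <- rnorm(96); y <- rnorm(96)
    a <- 1.7; b <- -0.6
    Sx <- forward_st(ecg_signal(x, 96))$values
    Sy <- forward_st(ecg_signal(y, 96))$values
    Sxy <- forward_st(ecg_signal(a * x + b * y, 96))$values
    expect_lt(max(Mod(Sxy - (a * Sx + b * Sy))), 1e-10)
    # time-average of each row = normalised FFT coefficient
    X <- fft(x) / 96
    expect_lt(max(Mod(rowMeans(Sx)[-1] - X[2:49])), 1e-10)
    expect_lt(Mod(rowMeans(Sx)[1] - mean(x)), 1e-12)
  })
})

test_that("magnitude/phase split and recombination are exact inverses", {
  withr::with_seed(13, {
    tfr <- forward_st(ecg_signal(rnorm(60), 120))
    mp <- split_mag_phase(tfr)
    expect_true(all(mp$magnitude >= 0))
    expect_true(all(mp$phase > -pi & mp$phase <= pi))
    back <- combine_mag_phase(mp$magnitude, mp$phase, tfr$fs)
    expect_lt(max(Mod(back$values - tfr$values)), 1e-12)
  })
  # polar form of a single entry and the zero convention
  z <- complex(real = 3, imaginary = 4)
  expect_equal(Mod(z), 5)
  tfr0 <- forward_st(ecg_signal(rep(0.5, 8), 8))
  mp0 <- split_mag_phase(tfr0)
  expect_equal(mp0$phase[2, 1], 0)   # zero entry -> phase 0 by convention
})

test_that("negative magnitudes are clipped before recombination", {
  mag <- matrix(1, 5, 8); ph <- matrix(0, 5, 8)
  mag[3, 4] <- -0.3
  tfr <- combine_mag_phase(mag, ph, 8)
  expect_equal(Re(tfr$values[3, 4]), 0)
  expect_error(combine_mag_phase(mag, ph, 8, clip_negative = FALSE),
               class = "stecg_invalid_input")
  expect_error(combine_mag_phase(mag, ph[, 1:4], 8),
               class = "stecg_invalid_input")
})
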