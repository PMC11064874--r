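test_that("hand-computed metric values are reproduced exactly", {
  expect_equal(snr_db(c(3, 4), c(3, 3)), 10 * log10(25), tolerance = 1e-12)
  expect_equal(prd(c(3, 4), c(3, 3)), 20.0, tolerance = 1e-12)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(prd(1:5, 1:5), 0)
})

test_that("identical signals give the infinite-SNR sentinel and SSIM 1", {
  expect_identical(snr_db(c(1, 2, 3), c(1, 2, 3)), Inf)
  expect_equal(ssim(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1.0)
})

test_that("degenerate references raise undefined-metric errors", {
  expect_error(snr_db(c(0, 0), c(1, 2)), class = "stecg_undefined_metric")
  expect_error(prd(c(0, 0), c(1, 2)), class = "stecg_undefined_metric")
  expect_error(ssim(1, 1), class = "stecg_undefined_metric")
  expect_error(rmse(1:3, 1:4), class = "stecg_invalid_input")
})

test_that("scale and translation invariances hold", {
  withr::with_seed(41, {
    y <- rnorm(50); yh <- y + rnorm(50, sd = 0.2)
    expect_equal(snr_db(3 * y, 3 * yh), snr_db(y, yh), tolerance = 1e-12)
    expect_equal(prd(-2 * y, -2 * yh), prd(y, yh), tolerance = 1e-12)
    expect_equal(rmse(y + 7, yh + 7), rmse(y, yh), tolerance = 1e-12)
  })
})

test_that("SNR and PRD satisfy their algebraic identity on random pairs", {
  withr::with_seed(42, {
    for (i in 1:10) {
      y <- rnorm(64); yh <- y + rnorm(64, sd = runif(1, 0.05, 1))
      expect_equal(snr_db(y, yh), 40 - 20 * log10(prd(y, yh)),
                   tolerance = 1e-10)
    }
  })
})

test_that("global SSIM matches a literal transcription of its formula", {
  x <- c(0, 1, 0, 1); y <- c(1, 0, 1, 0)
  K1 <- 0.01; K2 <- 0.03; L <- 1
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  want <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  expect_equal(ssim(x, y, L = 1), want, tolerance = 1e-12)

  # independent re-implementation on random pairs (population moments)
  withr::with_seed(43, {
    for (i in 1:5) {
      a <- rnorm(30); b <- a + rnorm(30, sd = 0.3)
      L <- max(a) - min(a)
      n <- length(a)
      ref <- ((2 * mean(a) * mean(b) + (0.01 * L)^2) *
                (2 * cov(a, b) * (n - 1) / n + (0.03 * L)^2)) /
        ((mean(a)^2 + mean(b)^2 + (0.01 * L)^2) *
           (var(a) * (n - 1) / n + var(b) * (n - 1) / n + (0.03 * L)^2))
      expect_equal(ssim(a, b), ref, tolerance = 1e-10)
      expect_equal(ssim(a, b, L = L), ssim(b, a, L = L), tolerance = 1e-12)
    }
  })
})

test_that("windowed SSIM averages local scores on matrices", {
  withr::with_seed(44, {
    a <- matrix(rnorm(64), 8, 8)
    b <- a + matrix(rnorm(64, sd = 0.1), 8, 8)
    w <- ssim(a, b, window = 4)
    expect_true(is.finite(w) && w <= 1)
    expect_equal(ssim(a, a, window = 4), 1.0)
  })
})

test_that("metrics_report collects all four measures", {
  withr::with_seed(45, {
    y <- rnorm(40); yh <- y + rnorm(40, sd = 0.1)
    rep <- metrics_report(y, yh)
    expect_named(rep, c("snr_db", "rmse", "prd", "ssim"))
    expect_equal(nrow(rep), 1L)
    expect_true(all(is.finite(unlist(rep))))
  })
})
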