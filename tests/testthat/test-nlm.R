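test_that("noise level estimation is robust to smooth structure", {
  expect_equal(estimate_sigma(matrix(3.2, 10, 10)), 0)
  withr::with_seed(31, {
    g <- matrix(rnorm(256 * 256), 256, 256)
    expect_lt(abs(estimate_sigma(g) - 1), 0.1)
    ramp <- outer(seq_len(128), seq_len(128), function(r, c) 0.2 * r + 0.1 * c)
    noisy <- ramp + matrix(rnorm(128 * 128, sd = 0.5), 128, 128)
    expect_lt(abs(estimate_sigma(noisy) - 0.5) / 0.5, 0.15)
  })
})

test_that("2-D filter equals the literal weight-formula transcription", {
  withr::with_seed(32, {
    plane <- matrix(rnorm(144), 12, 12)
    want <- oracle_nlm2d(plane, P = 1, Q = 3, lambda = 0.4)
    got <- nlm_denoise(plane, nlm_params(bandwidth = 0.4, patch_hw = 1,
                                         search_hw = 3))
    expect_lt(max(abs(got - want)), 1e-12)
    # second parameterisation exercises P > 1
    want2 <- oracle_nlm2d(plane, P = 2, Q = 4, lambda = 0.9)
    got2 <- nlm_denoise(plane, nlm_params(bandwidth = 0.9, patch_hw = 2,
                                          search_hw = 4))
    expect_lt(max(abs(got2 - want2)), 1e-12)
  })
})

test_that("constant planes pass through unchanged", {
  m <- matrix(2.5, 9, 9)
  out <- nlm_denoise(m, nlm_params(bandwidth = 0.3, search_hw = 3))
  expect_equal(out, m)
})

test_that("output is a convex combination: range preserved, variance reduced", {
  withr::with_seed(33, {
    m <- matrix(rnorm(400), 20, 20)
    out <- nlm_denoise(m, nlm_params(bandwidth = 0.5, search_hw = 5))
    expect_gte(min(out), min(m))
    expect_lte(max(out), max(m))
    expect_lt(var(as.vector(out)), var(as.vector(m)))
  })
})

test_that("bandwidth limits: identity as lambda -> 0, window mean as lambda -> infinity", {
  withr::with_seed(34, {
    m <- matrix(rnorm(100), 10, 10)
    tiny <- nlm_denoise(m, nlm_params(bandwidth = 1e-8, search_hw = 3))
    expect_lt(max(abs(tiny - m)), 1e-10)
    huge <- nlm_denoise(m, nlm_params(bandwidth = 1e8, search_hw = 3))
    box <- matrix(0, 10, 10)
    for (r in 1:10) for (c in 1:10)
      box[r, c] <- mean(m[max(1, r - 3):min(10, r + 3),
                          max(1, c - 3):min(10, c + 3)])
    expect_lt(max(abs(huge - box)), 1e-8)
  })
})

test_that("filtering commutes with transposition for symmetric parameters", {
  withr::with_seed(35, {
    m <- matrix(rnorm(15 * 15), 15, 15)
    p <- nlm_params(bandwidth = 0.6, patch_hw = 1, search_hw = 4)
    expect_equal(t(nlm_denoise(t(m), p)), nlm_denoise(m, p), tolerance = 1e-14)
  })
})

test_that("infeasible parameters are rejected", {
  m <- matrix(rnorm(36), 6, 6)
  expect_error(nlm_denoise(m, nlm_params(bandwidth = 1, patch_hw = 3,
                                         search_hw = 3)),
               class = "stecg_invalid_param")
  expect_error(nlm_params(bandwidth = -1), class = "stecg_invalid_param")
  expect_error(nlm_params(patch_hw = 0), class = "stecg_invalid_param")
  expect_error(nlm_params(patch_hw = 3, search_hw = 2),
               class = "stecg_invalid_param")
})
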