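test_that("extrema detection matches a brute-force scan on tie-free planes", {
  withr::with_seed(21, {
    key <- function(m) sort(m[, 1] * 1000 + m[, 2])
    for (conn in c(4L, 8L)) {
      m <- matrix(rnorm(256), 16, 16)
      got <- find_extrema(m, conn)
      want <- oracle_extrema(m, conn)
      expect_equal(key(as.matrix(got$maxima[, c("row", "col")])),
                   key(want$maxima))
      expect_equal(key(as.matrix(got$minima[, c("row", "col")])),
                   key(want$minima))
    }
  })
})

test_that("a unimodal bump yields one interior maximum and border minima only", {
  g <- outer(1:11, 1:11, function(r, c) exp(-((r - 6)^2 + (c - 6)^2) / 8))
  e <- find_extrema(g)
  expect_equal(nrow(e$maxima), 1L)
  expect_equal(c(e$maxima$row, e$maxima$col), c(6, 6))
  expect_true(all(e$minima$row %in% c(1, 11) | e$minima$col %in% c(1, 11)))
})

test_that("constant planes have no extrema and plateaus reduce to their centroid", {
  expect_equal(nrow(find_extrema(matrix(1, 8, 8))$maxima), 0L)
  expect_equal(nrow(find_extrema(matrix(1, 8, 8))$minima), 0L)
  # 2x2 flat top strictly above the surroundings -> exactly one maximum
  m <- matrix(0, 9, 9)
  m[5:6, 5:6] <- 1
  e <- find_extrema(m)
  expect_equal(nrow(e$maxima), 1L)
  expect_true(e$maxima$row %in% 5:6 && e$maxima$col %in% 5:6)
})

test_that("envelopes interpolate planes exactly and bowls within tolerance", {
  pts <- data.frame(row = c(1, 1, 12, 12, 3, 5, 7, 9, 4, 10),
                    col = c(1, 12, 1, 12, 5, 9, 2, 11, 8, 6))
  pts$value <- 2 * pts$row + 3 * pts$col + 1
  env <- build_envelope(pts, c(12, 12))
  truth <- outer(1:12, 1:12, function(r, c) 2 * r + 3 * c + 1)
  expect_lt(max(abs(env - truth)), 1e-6)

  # smooth quadratic bowl sampled on a lattice; off-node error < 5% of range
  bowl <- function(r, c) 0.05 * ((r - 6.5)^2 + (c - 6.5)^2)
  lat <- expand.grid(row = c(1, 4, 6, 9, 12), col = c(1, 4, 6, 9, 12))
  lat$value <- bowl(lat$row, lat$col)
  env2 <- build_envelope(lat, c(12, 12))
  truth2 <- outer(1:12, 1:12, bowl)
  expect_lt(max(abs(env2 - truth2)), 0.05 * diff(range(truth2)))
})

test_that("too few or degenerate points signal insufficient extrema", {
  pts <- data.frame(row = c(1, 5, 9), col = c(1, 5, 9), value = 1:3)
  expect_error(build_envelope(pts, c(10, 10)),
               class = "stecg_insufficient_extrema")
  col <- data.frame(row = 1:6, col = 1:6, value = rnorm(6))  # collinear
  expect_error(build_envelope(col, c(10, 10)),
               class = "stecg_insufficient_extrema")
})

test_that("one sifting step subtracts the mean envelope", {
  # checkerboard + constant: the mean envelope is the constant, the sift
  # recovers the oscillation
  n <- 16
  cb <- outer(1:n, 1:n, function(r, c) (-1)^(r + c))
  m <- cb + 5
  # 4-connectivity: on a checkerboard the diagonal neighbours tie, so the
  # 8-connected scan would see one big plateau instead of per-pixel extrema
  s <- sift_once(m, sift_config(envelope_method = "tps",
                                extrema_connectivity = 4L))
  interior <- s[3:(n - 2), 3:(n - 2)]
  expect_lt(max(abs(interior - cb[3:(n - 2), 3:(n - 2)])), 0.2)
  # a monotone ramp has no interior extrema
  ramp <- outer(1:12, 1:12, `+`)
  expect_error(sift_once(ramp), class = "stecg_insufficient_extrema")
})

test_that("decomposition is complete, deterministic and respects iteration caps", {
  withr::with_seed(22, {
    for (i in 1:3) {
      m <- matrix(rnorm(32 * 32), 32, 32)
      d <- bemd_decompose(m)
      recon <- Reduce(`+`, d$bimfs) + d$residue
      expect_lt(max(abs(recon - m)), 1e-10)
      expect_true(all(d$n_sifts <= sift_config()$max_sift_iters))
      expect_lte(length(d$bimfs), 4L)
      d2 <- bemd_decompose(m)
      expect_identical(d, d2)
    }
  })
})

test_that("a monotone plane decomposes to zero modes with the input as residue", {
  ramp <- outer(1:16, 1:16, function(r, c) 2 * r + c)
  d <- bemd_decompose(ramp)
  expect_length(d$bimfs, 0)
  expect_identical(d$residue, ramp)
  expect_error(bemd_decompose(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "stecg_invalid_input")
})

test_that("scale separation: the fast oscillation loads on BIMF1, the bump on the rest", {
  fx <- two_component_plane(64)
  d <- bemd_decompose(fx$plane)
  expect_gte(length(d$bimfs), 1L)
  expect_gt(cor(as.vector(d$bimfs[[1]]), as.vector(fx$sine)), 0.9)
  rest <- Reduce(`+`, c(d$bimfs[-1], list(d$residue)))
  expect_gt(cor(as.vector(rest), as.vector(fx$bump)), 0.9)
  # extrema density per unit area decreases with mode index
  dens <- vapply(c(d$bimfs, list(d$residue)), function(p)
    nrow(find_extrema(p)$maxima) / length(p), numeric(1))
  expect_true(all(diff(dens[seq_along(d$bimfs)]) <= 1e-3))
})

test_that("order-statistics envelopes also give a complete decomposition", {
  withr::with_seed(23, {
    m <- matrix(rnorm(48 * 48), 48, 48)
    d <- bemd_decompose(m, sift_config(envelope_method = "orderstat"))
    expect_lt(max(abs(Reduce(`+`, d$bimfs) + d$residue - m)), 1e-10)
    expect_gte(length(d$bimfs), 1L)
  })
})
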