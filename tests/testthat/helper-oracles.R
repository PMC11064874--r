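# Independent brute-force oracles used across the test files.  These are
# deliberately literal transcriptions of the defining formulas, sharing no
# code with the package internals.

# Direct quadrature of the S-transform: sample the continuous Gaussian
# window (std 1/f in time), periodise it over the finite record, and sum
# x(tau) g(tau - t) e^{-i 2 pi f tau} per (t, f) pair.  Signals are assumed
# zero-mean (the DC content is carried by the transform's zero-frequency
# row by convention).
oracle_st <- function(x, n_periods = 8L) {
  n <- length(x)
  K <- n %/% 2L + 1L
  S <- matrix(0 + 0i, K, n)
  S[1, ] <- mean(x)
  p <- 0:(n - 1)
  for (k in seq_len(K - 1L)) {
    for (j in 0:(n - 1)) {
      d <- p - j
      w <- 0
      for (r in -n_periods:n_periods)
        w <- w + (k / (n * sqrt(2 * pi))) * exp(-(d + r * n)^2 * k^2 / (2 * n^2))
      S[k + 1L, j + 1L] <- sum(x * w * exp(-2i * pi * k * p / n))
    }
  }
  S
}

# Literal quadruple-loop 2-D non-local means with symmetric mirror padding.
oracle_nlm2d <- function(y, P, Q, lambda) {
  R <- nrow(y); C <- ncol(y); L <- (2 * P + 1)^2
  refl <- function(i, n) {
    p <- 2 * n
    i <- ((i - 1) %% p + p) %% p + 1
    ifelse(i <= n, i, p - i + 1)
  }
  pad <- matrix(0, R + 2 * P, C + 2 * P)
  for (r in 1:(R + 2 * P)) for (c in 1:(C + 2 * P))
    pad[r, c] <- y[refl(r - P, R), refl(c - P, C)]
  out <- matrix(0, R, C)
  for (r in 1:R) for (c in 1:C) {
    num <- 0; den <- 0
    for (nr in max(1, r - Q):min(R, r + Q)) for (nc in max(1, c - Q):min(C, c + Q)) {
      d2 <- 0
      for (dr in -P:P) for (dc in -P:P)
        d2 <- d2 + (pad[r + P + dr, c + P + dc] - pad[nr + P + dr, nc + P + dc])^2
      w <- exp(-d2 / (2 * L * lambda^2))
      num <- num + w * y[nr, nc]; den <- den + w
    }
    out[r, c] <- num / den
  }
  out
}

# Literal double-loop 1-D non-local means.
oracle_nlm1d <- function(y, P, Q, lambda) {
  n <- length(y); L <- 2 * P + 1
  refl <- function(i, nn) {
    p <- 2 * nn
    i <- ((i - 1) %% p + p) %% p + 1
    ifelse(i <= nn, i, p - i + 1)
  }
  pad <- y[refl(1:(n + 2 * P) - P, n)]
  out <- numeric(n)
  for (m in 1:n) {
    num <- 0; den <- 0
    for (k in max(1, m - Q):min(n, m + Q)) {
      d2 <- sum((pad[m + P + (-P:P)] - pad[k + P + (-P:P)])^2)
      w <- exp(-d2 / (2 * L * lambda^2))
      num <- num + w * y[k]; den <- den + w
    }
    out[m] <- num / den
  }
  out
}

# Brute-force strict extrema scan (no plateau logic; use on tie-free planes).
oracle_extrema <- function(m, connectivity = 8) {
  R <- nrow(m); C <- ncol(m)
  offs <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  maxima <- NULL; minima <- NULL
  for (r in 1:R) for (c in 1:C) {
    nb <- c()
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
      if (rr >= 1 && rr <= R && cc >= 1 && cc <= C) nb <- c(nb, m[rr, cc])
    }
    if (all(m[r, c] > nb)) maxima <- rbind(maxima, c(r, c))
    if (all(m[r, c] < nb)) minima <- rbind(minima, c(r, c))
  }
  list(maxima = maxima, minima = minima)
}

# Two-component BEMD fixture: fast sinusoidal grid plus a smooth bump.
two_component_plane <- function(n = 64) {
  sine <- outer(1:n, 1:n, function(r, c) sin(2 * pi * 6 * r / n) * sin(2 * pi * 6 * c / n))
  bump <- outer(1:n, 1:n, function(r, c)
    2 * exp(-((r - n / 2)^2 + (c - n / 2)^2) / (2 * (n / 4.5)^2)))
  list(plane = sine + bump, sine = sine, bump = bump)
}
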