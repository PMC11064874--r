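#' Forward Stockwell transform
#'
#' Maps a time-domain signal to its complex time-frequency representation
#' (TFR).  The S-transform windows the signal with a Gaussian whose width
#' scales inversely with frequency, so low frequencies are seen with wide
#' windows (fine frequency resolution) and high frequencies with narrow ones
#' (fine time resolution), while the absolutely-referenced phase of the
#' Fourier transform is retained.
#'
#' The discrete transform is computed row-by-row in the frequency domain:
#' the voice at frequency bin \eqn{k} is the inverse DFT over \eqn{\alpha}
#' of \eqn{X(\alpha + k)\,e^{-2\pi^2\alpha^2/k^2}}, where \eqn{X} is the
#' normalised DFT of the signal and \eqn{\alpha} is indexed symmetrically
#' around zero.  This is the standard FFT formulation; it equals the direct
#' discretisation of the continuous transform with a periodised sampled
#' Gaussian window.  The zero-frequency voice, where the Gaussian window is
#' undefined, holds the signal mean replicated across time (the convention
#' that preserves invertibility).  Only the non-negative frequency rows are
#' stored; the input is real so the negative half is redundant.
#'
#' @param signal An [ecg_signal].
#' @return An object of class `ecg_tfr`: list with `values` (complex matrix,
#'   `floor(N/2)+1` frequency rows by `N` time columns, row 1 = DC), `fs`,
#'   and `n_samples`.
#' @seealso [inverse_st()], [split_mag_phase()]
#' @examples
#' s <- ecg_signal(cos(2 * pi * 8 * seq(0, 1 - 1/64, by = 1/64)), fs = 64)
#' tfr <- forward_st(s)
#' dim(tfr$values)
#' @export
forward_st <- function(signal) {
  if (!inherits(signal, "ecg_signal"))
    stop_invalid_input("`signal` must be an ecg_signal")
  x <- signal$samples
  n <- length(x)
  K <- n %/% 2L + 1L          # rows: k = 0 .. floor(N/2)
  X <- fft(x) / n
  # The DC content lives entirely in row 0; zeroing the DC bin here keeps
  # the k >= 1 voices zero for a constant input without touching their time
  # marginal (the shifted DC term averages to zero over time), so
  # invertibility is unaffected.
  X[1] <- 0 + 0i
  idx <- 0:(n - 1)
  alpha2 <- (ifelse(idx <= n / 2, idx, idx - n))^2

  M <- matrix(0 + 0i, nrow = n, ncol = K - 1L)
  for (k in seq_len(K - 1L)) {
    M[, k] <- X[((idx + k) %% n) + 1L] * exp(-2 * pi^2 * alpha2 / k^2)
  }
  # unnormalised inverse DFT of each column = sum over alpha
  S <- t(stats::mvfft(M, inverse = TRUE))
  values <- rbind(matrix(complex(real = mean(x)), nrow = 1, ncol = n), S)
  structure(list(values = values, fs = signal$fs, n_samples = n),
            class = "ecg_tfr")
}

#' @export
print.ecg_tfr <- function(x, ...) {
  cat(sprintf("<ecg_tfr> %d frequency rows x %d time columns @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$fs))
  invisible(x)
}

validate_tfr <- function(tfr) {
  if (!inherits(tfr, "ecg_tfr"))
    stop_invalid_input("`tfr` must be an ecg_tfr")
  v <- tfr$values
  n <- tfr$n_samples
  if (!is.matrix(v) || ncol(v) != n || nrow(v) != n %/% 2L + 1L)
    stop_invalid_input("TFR shape is inconsistent with n_samples")
  if (!all(is.finite(Re(v))) || !all(is.finite(Im(v))))
    stop_invalid_input("TFR contains non-finite entries")
  invisible(tfr)
}

#' Inverse Stockwell transform
#'
#' Reconstructs the time-domain signal from a (possibly modified) TFR via
#' the time-marginal identity: averaging each frequency voice over time
#' yields the Fourier coefficient at that frequency, so the signal is
#' recovered by an inverse FFT of the marginal spectrum.  Hermitian symmetry
#' is enforced on the reassembled spectrum (the stored rows cover only
#' non-negative frequencies), so the output is exactly real.
#'
#' For an unmodified transform this is the exact inverse of [forward_st()]
#' to machine precision.
#'
#' @param tfr An `ecg_tfr`.
#' @return An [ecg_signal] of length `tfr$n_samples`.
#' @export
inverse_st <- function(tfr) {
  validate_tfr(tfr)
  v <- tfr$values
  n <- tfr$n_samples
  K <- nrow(v)
  Xhat <- rowMeans(v)                      # marginal spectrum, bins 0..K-1
  full <- complex(length.out = n)
  full[1] <- complex(real = Re(Xhat[1]))   # DC of a real signal is real
  if (n %% 2L == 0L) {
    # Nyquist bin must be real for a real signal
    full[n / 2 + 1] <- complex(real = Re(Xhat[K]))
    if (K > 2) {
      pos <- Xhat[2:(K - 1L)]
      full[2:(K - 1L)] <- pos
      full[n:(K + 1L)] <- Conj(pos)
    }
  } else {
    if (K > 1) {
      pos <- Xhat[2:K]
      full[2:K] <- pos
      full[n:(K + 1L)] <- Conj(pos)
    }
  }
  x <- Re(fft(full, inverse = TRUE))       # sum_k Xhat(k) e^{+2pi i kj/N}
  ecg_signal_unchecked(x, tfr$fs)
}

# internal constructor skipping finiteness re-checks (values already vetted)
ecg_signal_unchecked <- function(samples, fs) {
  structure(list(samples = as.numeric(samples), fs = fs),
            class = "ecg_signal")
}

#' Split a TFR into magnitude and phase planes
#'
#' @param tfr An `ecg_tfr`.
#' @return List with `magnitude` (non-negative real matrix) and `phase`
#'   (matrix in \eqn{(-\pi, \pi]}; zero entries get phase 0 by convention).
#'   `magnitude * exp(1i * phase)` reproduces the complex TFR exactly.
#' @export
split_mag_phase <- function(tfr) {
  validate_tfr(tfr)
  ph <- Arg(tfr$values)
  ph[ph == -pi] <- pi        # canonicalise the branch cut to (-pi, pi]
  list(magnitude = Mod(tfr$values), phase = ph)
}

#' Recombine magnitude and phase planes into a TFR
#'
#' Inverse of [split_mag_phase()].  Magnitude entries driven negative by
#' upstream filtering/summation are clipped to zero (a magnitude plane is
#' non-negative by definition; clipping is the minimal correction).
#'
#' @param magnitude Real matrix of magnitudes.
#' @param phase Real matrix of phases, same shape.
#' @param fs Sampling rate of the underlying signal (Hz).
#' @param clip_negative Clip negative magnitude entries to zero before
#'   combining (default `TRUE`).  With `FALSE`, negative entries raise an
#'   invalid-input error.
#' @return An `ecg_tfr`.
#' @export
combine_mag_phase <- function(magnitude, phase, fs, clip_negative = TRUE) {
  if (!is.matrix(magnitude) || !is.matrix(phase) ||
      !identical(dim(magnitude), dim(phase)))
    stop_invalid_input("`magnitude` and `phase` must be matrices of equal shape")
  if (any(magnitude < 0)) {
    if (clip_negative) magnitude[magnitude < 0] <- 0
    else stop_invalid_input("`magnitude` has negative entries")
  }
  K <- nrow(magnitude)
  n <- ncol(magnitude)
  if (K != n %/% 2L + 1L)
    stop_invalid_input("plane shape is not a valid TFR shape (floor(N/2)+1 x N)")
  structure(list(values = magnitude * exp(1i * phase), fs = fs,
                 n_samples = n),
            class = "ecg_tfr")
}

#' Frequency axis of a TFR
#' @param tfr An `ecg_tfr`.
#' @return Vector of row frequencies in Hz, `k * fs / N` for `k = 0..floor(N/2)`.
#' @export
tfr_frequencies <- function(tfr) {
  validate_tfr(tfr)
  (seq_len(nrow(tfr$values)) - 1) * tfr$fs / tfr$n_samples
}
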