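#' Specification of a synthetic ECG fixture
#'
#' Describes a quasi-periodic P-QRS-T waveform built as a sum of Gaussian
#' components per beat.  Defaults emulate the standard ambulatory-ECG
#' study conditions: 360 Hz sampling, 10 s segments, 60 bpm, R wave
#' dominant at 1 mV.
#'
#' @param fs Sampling rate in Hz (default 360).  `fs * duration` must be an
#'   integer.
#' @param duration Segment length in seconds (default 10).
#' @param heart_rate Beats per minute (default 60).
#' @param morphology Data frame with columns `wave`, `amplitude` (mV),
#'   `center` (s, offset from the R peak) and `width` (s, Gaussian standard
#'   deviation); defaults to a typical adult P-QRS-T morphology.  The R
#'   amplitude must be the largest in magnitude.
#' @param jitter Beat-to-beat timing jitter as a fraction of the beat
#'   period (default 0.02; set 0 for strictly periodic beats).
#' @param seed Integer seed controlling the jitter (default 1).
#' @return An `ecg_spec` list.
#' @export
ecg_spec <- function(fs = 360, duration = 10, heart_rate = 60,
                     morphology = default_morphology(),
                     jitter = 0.02, seed = 1L) {
  n <- fs * duration
  if (abs(n - round(n)) > 1e-9)
    stop_invalid_param("`fs * duration` must be an integer number of samples")
  if (!is_scalar_num(heart_rate) || heart_rate <= 0)
    stop_invalid_param("`heart_rate` must be > 0")
  req <- c("wave", "amplitude", "center", "width")
  if (!is.data.frame(morphology) || !all(req %in% names(morphology)))
    stop_invalid_param("`morphology` must have columns wave, amplitude, center, width")
  r_amp <- morphology$amplitude[morphology$wave == "R"]
  if (length(r_amp) != 1L || abs(r_amp) < max(abs(morphology$amplitude)))
    stop_invalid_param("the R wave must be the dominant morphology component")
  if (!is_scalar_num(jitter) || jitter < 0)
    stop_invalid_param("`jitter` must be >= 0")
  structure(list(fs = fs, duration = duration, heart_rate = heart_rate,
                 morphology = morphology, jitter = jitter,
                 seed = as.integer(seed)),
            class = "ecg_spec")
}

#' Default P-QRS-T morphology (amplitudes in mV, times in seconds)
#' @return Data frame with one row per wave component.
#' @export
default_morphology <- function() {
  data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.12, -0.10, 1.00, -0.15, 0.30),
    center = c(-0.200, -0.025, 0.000, 0.025, 0.220),
    width = c(0.045, 0.008, 0.011, 0.008, 0.060)
  )
}

#' Generate a synthetic ECG signal
#'
#' Places one sum-of-Gaussians P-QRS-T beat per cardiac cycle, with
#' optional Gaussian timing jitter per beat.  Deterministic given the seed.
#'
#' @param spec An [ecg_spec].
#' @return An [ecg_signal] of `fs * duration` samples.
#' @export
gen_ecg <- function(spec = ecg_spec()) {
  stopifnot(inherits(spec, "ecg_spec"))
  n <- as.integer(round(spec$fs * spec$duration))
  t <- (0:(n - 1)) / spec$fs
  period <- 60 / spec$heart_rate
  n_beats <- floor(spec$duration / period + 1e-9)
  centers <- (seq_len(n_beats) - 0.5) * period
  if (spec$jitter > 0) {
    centers <- withr::with_seed(spec$seed, {
      centers + rnorm(n_beats, sd = spec$jitter * period)
    })
  }
  x <- numeric(n)
  m <- spec$morphology
  for (b in centers) {
    for (w in seq_len(nrow(m))) {
      mu <- b + m$center[w]
      x <- x + m$amplitude[w] * exp(-(t - mu)^2 / (2 * m$width[w]^2))
    }
  }
  ecg_signal(x, spec$fs)
}

#' Specification of an additive noise realisation
#'
#' @param kind One of `"pli"` (power-line interference), `"gaussian"`,
#'   `"baseline_wander"`, `"muscle_artifact"`, `"electrode_motion"`.
#' @param target_snr_db Target input SNR in dB used by
#'   [add_noise_at_snr()] (default 5; the standard levels are 0, 5, 10).
#' @param seed Integer seed (default 1).
#' @param pli_freq Power-line frequency in Hz (default 60).
#' @param bw_freq Baseline-wander frequency in Hz (default 0.2; baseline
#'   wander occupies 0.15-0.3 Hz).
#' @param bw_mode `"sine"` (default) or `"walk"` (band-limited random
#'   walk).
#' @param ma_band Muscle-artifact band edges in Hz (default `c(20, 100)`).
#' @param em_cutoff Electrode-motion low-pass cutoff in Hz (default 5).
#' @param em_rate Mean electrode-motion event rate per second (default 1).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(kind = c("pli", "gaussian", "baseline_wander",
                                "muscle_artifact", "electrode_motion"),
                       target_snr_db = 5, seed = 1L, pli_freq = 60,
                       bw_freq = 0.2, bw_mode = c("sine", "walk"),
                       ma_band = c(20, 100), em_cutoff = 5, em_rate = 1) {
  kind <- match.arg(kind)
  bw_mode <- match.arg(bw_mode)
  if (!is_scalar_num(target_snr_db))
    stop_invalid_param("`target_snr_db` must be a finite scalar (dB)")
  if (!is_scalar_num(pli_freq) || pli_freq <= 0)
    stop_invalid_param("`pli_freq` must be > 0")
  if (!is_scalar_num(bw_freq) || bw_freq <= 0)
    stop_invalid_param("`bw_freq` must be > 0")
  if (length(ma_band) != 2L || ma_band[1] <= 0 || ma_band[2] <= ma_band[1])
    stop_invalid_param("`ma_band` must be increasing positive band edges")
  structure(list(kind = kind, target_snr_db = target_snr_db,
                 seed = as.integer(seed), pli_freq = pli_freq,
                 bw_freq = bw_freq, bw_mode = bw_mode, ma_band = ma_band,
                 em_cutoff = em_cutoff, em_rate = em_rate),
            class = "noise_spec")
}

# Keep only FFT bins whose |frequency| lies in [lo, hi]; exact band
# limiting, deterministic, returns a real vector.
fft_bandlimit <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- abs((0:(n - 1)) - n * ((0:(n - 1)) > n / 2)) * fs / n
  X <- fft(x)
  X[f < lo | f > hi] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

#' Generate an (unscaled) noise realisation
#'
#' Produces one of five canonical ECG contaminants.  Amplitude scaling to a
#' target input SNR is done separately by [add_noise_at_snr()].
#'
#' * `pli`: unit-amplitude sinusoid at `pli_freq`.
#' * `gaussian`: i.i.d. standard normal samples.
#' * `baseline_wander`: unit sinusoid at `bw_freq`, or a band-limited
#'   (0.05-0.3 Hz) random walk when `bw_mode = "walk"`.
#' * `muscle_artifact`: white noise spectrally confined to `ma_band`
#'   (exact FFT-domain band limiting, so out-of-band energy is zero).
#' * `electrode_motion`: sparse random step events (Poisson arrivals,
#'   Laplace-like amplitudes) low-passed below `em_cutoff`, giving the
#'   characteristic low-frequency lurches of a moving electrode.
#'
#' @param spec A [noise_spec].
#' @param n_samples Number of samples to generate.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of length `n_samples`; deterministic given
#'   `spec$seed`.
#' @export
gen_noise <- function(spec, n_samples, fs) {
  stopifnot(inherits(spec, "noise_spec"))
  if (!is_scalar_num(n_samples) || n_samples < 2)
    stop_invalid_param("`n_samples` must be >= 2")
  n <- as.integer(n_samples)
  t <- (0:(n - 1)) / fs
  withr::with_seed(spec$seed, {
    switch(spec$kind,
      pli = sin(2 * pi * spec$pli_freq * t),
      gaussian = rnorm(n),
      baseline_wander = {
        if (spec$bw_mode == "sine") sin(2 * pi * spec$bw_freq * t)
        else fft_bandlimit(cumsum(rnorm(n)), fs, 0.05, 0.3)
      },
      muscle_artifact = fft_bandlimit(rnorm(n), fs, spec$ma_band[1],
                                      spec$ma_band[2]),
      electrode_motion = {
        n_events <- max(1L, rpois(1, spec$em_rate * n / fs))
        pos <- sort(sample.int(n, min(n_events, n)))
        amp <- rnorm(length(pos)) * rexp(length(pos))
        steps <- numeric(n)
        steps[pos] <- amp
        # integrate impulses into steps, then confine below the cutoff
        fft_bandlimit(cumsum(steps), fs, fs / n, spec$em_cutoff)
      },
      stop_invalid_param(sprintf("unknown noise kind '%s'", spec$kind))
    )
  })
}

#' Add noise at an exact input SNR
#'
#' Scales the noise vector by
#' \eqn{\alpha = \sqrt{P_{clean} / (P_{noise}\,10^{T/10})}} so that the
#' realised input SNR `10*log10(P_clean / P_noise_scaled)` equals the
#' target `T` exactly, then adds it to the clean signal.
#'
#' @param clean An [ecg_signal] (not all zero).
#' @param noise Numeric vector of the same length (not all zero).
#' @param target_snr_db Target input SNR in dB.
#' @return List with `noisy` (an [ecg_signal]) and `scaled_noise` (numeric
#'   vector).
#' @export
add_noise_at_snr <- function(clean, noise, target_snr_db) {
  stopifnot(inherits(clean, "ecg_signal"))
  noise <- as.numeric(noise)
  if (length(noise) != length(clean$samples))
    stop_invalid_input("`noise` must match the clean signal length")
  p_clean <- sum(clean$samples^2)
  p_noise <- sum(noise^2)
  if (p_clean == 0) stop_invalid_input("clean signal is all zero")
  if (p_noise == 0) stop_invalid_input("noise is all zero")
  if (!is_scalar_num(target_snr_db))
    stop_invalid_input("`target_snr_db` must be a finite scalar")
  alpha <- sqrt(p_clean / (p_noise * 10^(target_snr_db / 10)))
  scaled <- alpha * noise
  list(noisy = ecg_signal(clean$samples + scaled, clean$fs),
       scaled_noise = scaled)
}

#' Build a clean/noisy fixture pair
#'
#' Convenience wrapper: generates the clean ECG, the noise realisation, and
#' the noisy mixture at the requested input SNR.
#'
#' @param ecg An [ecg_spec].
#' @param noise A [noise_spec] (its `target_snr_db` sets the mixing level).
#' @return List with `clean`, `noisy` (both [ecg_signal]s), `noise`
#'   (scaled noise vector), and the two specs.
#' @export
make_noisy_fixture <- function(ecg = ecg_spec(), noise = noise_spec()) {
  clean <- gen_ecg(ecg)
  nz <- gen_noise(noise, length(clean$samples), clean$fs)
  mix <- add_noise_at_snr(clean, nz, noise$target_snr_db)
  list(clean = clean, noisy = mix$noisy, noise = mix$scaled_noise,
       ecg_spec = ecg, noise_spec = noise)
}

#' Write a fixture to CSV with a JSON sidecar
#'
#' Writes `<prefix>.csv` with columns `clean` and `noisy` (one sample per
#' row) and `<prefix>.json` recording the generating parameters.
#'
#' @param fixture A list as returned by [make_noisy_fixture()].
#' @param prefix Output path prefix.
#' @return Invisibly, the CSV path.
#' @export
write_fixture_csv <- function(fixture, prefix) {
  csv <- paste0(prefix, ".csv")
  write.csv(data.frame(clean = fixture$clean$samples,
                       noisy = fixture$noisy$samples),
            csv, row.names = FALSE)
  side <- list(fs = fixture$clean$fs,
               ecg_spec = fixture$ecg_spec[setdiff(names(fixture$ecg_spec),
                                                   "morphology")],
               noise_spec = unclass(fixture$noise_spec))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(csv)
}
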