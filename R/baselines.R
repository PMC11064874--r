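#' Wavelet-threshold baseline configuration
#'
#' Settings for the classic wavelet shrinkage denoiser used as a
#' comparison method: Daubechies-4 decomposition, universal soft
#' thresholding of the detail coefficients.
#'
#' @param wavelet Wavelet name; only `"db4"` (8-tap Daubechies, 4 vanishing
#'   moments) is built in.
#' @param level Decomposition depth (default 5).
#' @param threshold_rule `"universal"`: \eqn{\sigma\sqrt{2\log N}} with
#'   \eqn{\sigma} the MAD estimate from the finest detail level.
#' @param mode `"soft"` (default) or `"hard"` thresholding.
#' @param threshold Optional fixed threshold overriding the rule (0 gives
#'   a pure analysis/synthesis roundtrip).
#' @return A `wt_config` list.
#' @export
wt_config <- function(wavelet = "db4", level = 5L,
                      threshold_rule = "universal",
                      mode = c("soft", "hard"), threshold = NULL) {
  mode <- match.arg(mode)
  if (!identical(wavelet, "db4"))
    stop_invalid_param("only the db4 wavelet is available")
  if (!is_scalar_num(level) || level < 1 || level != round(level))
    stop_invalid_param("`level` must be an integer >= 1")
  if (!identical(threshold_rule, "universal"))
    stop_invalid_param("only the universal threshold rule is available")
  if (!is.null(threshold) && (!is_scalar_num(threshold) || threshold < 0))
    stop_invalid_param("`threshold` must be NULL or >= 0")
  structure(list(wavelet = wavelet, level = as.integer(level),
                 threshold_rule = threshold_rule, mode = mode,
                 threshold = threshold),
            class = "wt_config")
}

# Daubechies D8 scaling (low-pass reconstruction) filter; the wavelet
# filter is its alternating-sign reverse (quadrature mirror).
db4_scaling <- c(0.2303778133088964, 0.7148465705529154, 0.6308807679298587,
                 -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
                 0.0328830116668852, -0.0105974017850690)

# Periodised analysis filters: time-reversed scaling filter and its
# quadrature mirror.  The analysis operator (even shifts of these rows) is
# orthonormal, so synthesis is its exact transpose.
db4_analysis_filters <- function() {
  g <- rev(db4_scaling)
  h <- (-1)^(0:7) * db4_scaling        # QMF: h_l = (-1)^l g_{L-1-l}
  list(g = g, h = h)
}

# One analysis step: x (even length >= 8) -> list(approx, detail), with
# a[t] = sum_l g_l x[(2t+1-l) mod n] (0-based), likewise for the detail.
dwt_step <- function(x, g, h) {
  n <- length(x)
  half <- n %/% 2L
  a <- numeric(half); d <- numeric(half)
  L <- length(g)
  for (t in seq_len(half)) {
    seg <- x[(2L * t - 1L - (0:(L - 1L))) %% n + 1L]
    a[t] <- sum(g * seg)
    d[t] <- sum(h * seg)
  }
  list(approx = a, detail = d)
}

# Adjoint (= inverse) of dwt_step.
idwt_step <- function(a, d, g, h) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  L <- length(g)
  for (t in seq_len(half)) {
    idx <- (2L * t - 1L - (0:(L - 1L))) %% n + 1L
    x[idx] <- x[idx] + g * a[t] + h * d[t]
  }
  x
}

dwt_periodic <- function(x, level) {
  f <- db4_analysis_filters()
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- dwt_step(a, f$g, f$h)
    a <- s$approx
    details[[j]] <- s$detail
  }
  list(approx = a, details = details)
}

idwt_periodic <- function(decomp) {
  f <- db4_analysis_filters()
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    a <- idwt_step(a, decomp$details[[j]], f$g, f$h)
  }
  a
}

soft_thresh <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)
hard_thresh <- function(x, thr) ifelse(abs(x) > thr, x, 0)

#' Wavelet-threshold denoising (comparison baseline)
#'
#' Periodised db4 decomposition to `config$level`, universal soft (or
#' hard) thresholding of all detail coefficients with
#' \eqn{\sigma\sqrt{2\log N}} (\eqn{\sigma} from the MAD of the finest
#' details), and reconstruction.  Signals whose length is not a multiple of
#' `2^level` are symmetrically padded on the right before analysis and
#' cropped after synthesis.
#'
#' @param signal An [ecg_signal].
#' @param config A [wt_config].
#' @return Denoised [ecg_signal] of the same length.
#' @export
wt_denoise <- function(signal, config = wt_config()) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (!inherits(config, "wt_config"))
    stop_invalid_param("`config` must be a wt_config")
  x <- signal$samples
  n <- length(x)
  block <- 2L^config$level
  if (n < 2L * block)
    stop_invalid_param(sprintf(
      "decomposition level %d infeasible for %d samples", config$level, n))
  n_pad <- block * as.integer(ceiling(n / block))
  if (n_pad > n) {
    extra <- n_pad - n
    x <- c(x, x[n - seq_len(extra) + 1L])   # symmetric right padding
  }
  dec <- dwt_periodic(x, config$level)
  thr <- config$threshold
  if (is.null(thr)) {
    sigma <- median(abs(dec$details[[1]])) / 0.6745
    thr <- sigma * sqrt(2 * log(length(x)))
  }
  f <- if (config$mode == "soft") soft_thresh else hard_thresh
  dec$details <- lapply(dec$details, f, thr = thr)
  y <- idwt_periodic(dec)[seq_len(n)]
  ecg_signal_unchecked(y, signal$fs)
}

#' Time-domain non-local means denoising (comparison baseline)
#'
#' The sample-domain analogue of [nlm_denoise()]: each output sample is a
#' weighted average over a `2Q+1` search window with patch-similarity
#' weights `exp(-d^2 / (2 (2P+1) lambda^2))`, mirror-padded borders.
#' Default parameters follow ECG practice: patches spanning roughly a QRS
#' upstroke (`P = 10` samples) and a search window on the order of the
#' R-R interval (`Q = 300` samples at 360 Hz), with the `0.5 * sigma`
#' bandwidth rule.
#'
#' @param signal An [ecg_signal].
#' @param params An [nlm_params] (1-D interpretation: patch length
#'   `2*patch_hw+1` samples).  A `NULL` bandwidth resolves to `0.5 * sigma`
#'   with `sigma` estimated from the second difference of the signal.
#' @return Denoised [ecg_signal].
#' @export
nlm1d_denoise <- function(signal,
                          params = nlm_params(patch_hw = 10L,
                                              search_hw = 300L)) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (!inherits(params, "nlm_params"))
    stop_invalid_param("`params` must be an nlm_params object")
  x <- signal$samples
  n <- length(x)
  P <- params$patch_hw
  Q <- min(params$search_hw, n - 1L)
  if (2 * P + 1 > n)
    stop_invalid_param("`patch_hw` too large for the signal")
  lambda <- params$bandwidth
  if (is.null(lambda)) {
    sigma <- params$sigma %||% estimate_sigma_1d(x)
    lambda <- 0.5 * sigma
  }
  if (lambda <= 0) return(signal)
  ecg_signal_unchecked(nlm1d_cpp(x, P, Q, lambda), signal$fs)
}
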