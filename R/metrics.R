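# Internal: common validation for (reference, estimate) pairs.
check_pair <- function(reference, estimate) {
  if (inherits(reference, "ecg_signal")) reference <- reference$samples
  if (inherits(estimate, "ecg_signal")) estimate <- estimate$samples
  reference <- as.numeric(reference); estimate <- as.numeric(estimate)
  if (length(reference) != length(estimate))
    stop_invalid_input("reference and estimate must have equal length")
  if (length(reference) < 1L)
    stop_invalid_input("empty inputs")
  if (!all(is.finite(reference)) || !all(is.finite(estimate)))
    stop_invalid_input("non-finite values in inputs")
  list(y = reference, yhat = estimate)
}

#' Output signal-to-noise ratio (dB)
#'
#' `10 * log10(sum(y^2) / sum((y - yhat)^2))` for a reference `y` and an
#' estimate `yhat`.  Returns `Inf` when the estimate equals the reference
#' (zero error power).
#'
#' @param reference,estimate Numeric vectors (or [ecg_signal]s) of equal
#'   length; the reference must not be all zero.
#' @return SNR in dB.
#' @export
snr_db <- function(reference, estimate) {
  p <- check_pair(reference, estimate)
  sig <- sum(p$y^2)
  if (sig == 0) stop_undefined_metric("SNR undefined for an all-zero reference")
  err <- sum((p$y - p$yhat)^2)
  if (err == 0) return(Inf)
  10 * log10(sig / err)
}

#' Root mean squared error
#'
#' @inheritParams snr_db
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(reference, estimate) {
  p <- check_pair(reference, estimate)
  sqrt(mean((p$y - p$yhat)^2))
}

#' Percent root-mean-square difference
#'
#' `100 * sqrt(sum((y - yhat)^2) / sum(y^2))`.  Related to [snr_db()] by
#' `SNR = 40 - 20 * log10(PRD)`.
#'
#' @inheritParams snr_db
#' @return PRD in percent.
#' @export
prd <- function(reference, estimate) {
  p <- check_pair(reference, estimate)
  sig <- sum(p$y^2)
  if (sig == 0) stop_undefined_metric("PRD undefined for an all-zero reference")
  100 * sqrt(sum((p$y - p$yhat)^2) / sig)
}

#' Structural similarity index
#'
#' Global (single-window) SSIM
#' \deqn{\mathrm{SSIM}(x,y) = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'   {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}}
#' with \eqn{C_1 = (K_1 L)^2}, \eqn{C_2 = (K_2 L)^2}, means, standard
#' deviations and covariance taken over all elements with the population
#' convention (divide by N).  `window` switches to a mean of local SSIM
#' values over square tiles of that side (stride = window), mainly useful
#' for large time-frequency planes; the default is the global form.
#'
#' @param reference,estimate Numeric vectors or matrices of equal shape
#'   (at least 2 elements).
#' @param K1,K2 Stability constants (defaults 0.01 and 0.03, the universal
#'   SSIM choices).
#' @param L Dynamic range; defaults to `max(reference) - min(reference)`
#'   (1 when the reference is constant).
#' @param window Optional tile side for the windowed variant (`NULL`,
#'   the default, computes the global form).
#' @return SSIM in \eqn{[-1, 1]} (typically \eqn{[0, 1]}).
#' @export
ssim <- function(reference, estimate, K1 = 0.01, K2 = 0.03, L = NULL,
                 window = NULL) {
  dim_ref <- dim(reference)
  p <- check_pair(reference, estimate)
  if (length(p$y) < 2L)
    stop_undefined_metric("SSIM needs at least 2 elements")
  if (is.null(L)) {
    L <- max(p$y) - min(p$y)
    if (L == 0) L <- 1
  }
  if (!is_scalar_num(L) || L <= 0) stop_invalid_param("`L` must be > 0")
  if (is.null(window)) return(ssim_global(p$y, p$yhat, K1, K2, L))
  if (is.null(dim_ref) || length(dim_ref) != 2L)
    stop_invalid_param("windowed SSIM requires matrix inputs")
  x <- matrix(p$y, dim_ref[1], dim_ref[2])
  y <- matrix(p$yhat, dim_ref[1], dim_ref[2])
  w <- as.integer(window)
  if (w < 2L || w > min(dim_ref)) stop_invalid_param("bad `window`")
  vals <- c()
  r_starts <- seq(1L, dim_ref[1] - w + 1L, by = w)
  c_starts <- seq(1L, dim_ref[2] - w + 1L, by = w)
  for (r0 in r_starts) for (c0 in c_starts) {
    ri <- r0:(r0 + w - 1L); ci <- c0:(c0 + w - 1L)
    vals <- c(vals, ssim_global(as.numeric(x[ri, ci]), as.numeric(y[ri, ci]),
                                K1, K2, L))
  }
  mean(vals)
}

ssim_global <- function(x, y, K1, K2, L) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

#' Full metrics report for a reference/estimate pair
#'
#' @inheritParams snr_db
#' @param L Dynamic range passed to [ssim()] (default: reference range).
#' @return A one-row data frame with columns `snr_db`, `rmse`, `prd`,
#'   `ssim`.
#' @export
metrics_report <- function(reference, estimate, L = NULL) {
  data.frame(snr_db = snr_db(reference, estimate),
             rmse = rmse(reference, estimate),
             prd = prd(reference, estimate),
             ssim = ssim(reference, estimate, L = L))
}
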