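#' Non-local means parameters
#'
#' @param bandwidth Smoothing bandwidth \eqn{\lambda} (> 0).  When `NULL`
#'   (default) it is set at filtering time to `0.5 * sigma`, the
#'   optimal-bandwidth rule for non-local means, with `sigma` estimated from
#'   the plane if not supplied.
#' @param patch_hw Patch half-width P (patches are `(2P+1)^2` pixels;
#'   default 1, i.e. 3 x 3 patches).
#' @param search_hw Neighbourhood (search window) half-width Q, `>= patch_hw`
#'   (default 10).  The similarity search covers `(2Q+1)^2` pixels; cost
#'   grows quadratically in Q.
#' @param sigma Noise standard deviation (>= 0) used when `bandwidth` is
#'   `NULL`; itself `NULL` to auto-estimate via [estimate_sigma()].
#' @return An `nlm_params` list.
#' @export
nlm_params <- function(bandwidth = NULL, patch_hw = 1L, search_hw = 10L,
                       sigma = NULL) {
  if (!is.null(bandwidth) && (!is_scalar_num(bandwidth) || bandwidth <= 0))
    stop_invalid_param("`bandwidth` must be NULL or a positive scalar")
  if (!is_scalar_num(patch_hw) || patch_hw < 1 || patch_hw != round(patch_hw))
    stop_invalid_param("`patch_hw` must be an integer >= 1")
  if (!is_scalar_num(search_hw) || search_hw < patch_hw ||
      search_hw != round(search_hw))
    stop_invalid_param("`search_hw` must be an integer >= patch_hw")
  if (!is.null(sigma) && (!is_scalar_num(sigma) || sigma < 0))
    stop_invalid_param("`sigma` must be NULL or >= 0")
  structure(list(bandwidth = bandwidth, patch_hw = as.integer(patch_hw),
                 search_hw = as.integer(search_hw), sigma = sigma),
            class = "nlm_params")
}

#' Robust noise-level estimate for a plane
#'
#' Estimates the standard deviation of additive noise from the
#' finest-scale detail of the plane: the response of the discrete
#' Laplacian-difference kernel
#' `[[1,-2,1],[-2,4,-2],[1,-2,1]]` (which annihilates locally planar
#' structure), scaled to noise units by the kernel norm (6) and made robust
#' with the median absolute deviation (`median(|r|) / 0.6745`).
#'
#' @param plane Real matrix, at least 3 x 3.
#' @return Non-negative scalar; exactly 0 for a constant plane.
#' @export
estimate_sigma <- function(plane) {
  check_plane(plane, min_dim = 3L)
  R <- nrow(plane); C <- ncol(plane)
  ri <- 2:(R - 1); ci <- 2:(C - 1)
  resp <- 4 * plane[ri, ci, drop = FALSE] -
    2 * (plane[ri - 1, ci, drop = FALSE] + plane[ri + 1, ci, drop = FALSE] +
         plane[ri, ci - 1, drop = FALSE] + plane[ri, ci + 1, drop = FALSE]) +
    (plane[ri - 1, ci - 1, drop = FALSE] + plane[ri - 1, ci + 1, drop = FALSE] +
     plane[ri + 1, ci - 1, drop = FALSE] + plane[ri + 1, ci + 1, drop = FALSE])
  median(abs(resp)) / (0.6745 * 6)
}

# 1-D analogue used by the time-domain baseline: second difference
# annihilates linear trend; norm sqrt(1 + 4 + 1) = sqrt(6).
estimate_sigma_1d <- function(x) {
  if (length(x) < 3L) return(0)
  d <- x[-c(1, 2)] - 2 * x[-c(1, length(x))] + x[-c(length(x) - 1, length(x))]
  median(abs(d)) / (0.6745 * sqrt(6))
}

#' Non-local means filtering of a plane
#'
#' Each output pixel is a weighted average of the pixels in its
#' `(2Q+1)^2` search window (truncated at the plane borders), with weights
#' \deqn{\omega(m,n) = \exp(-d^2(m,n) / (2 L_\Delta \lambda^2))}
#' where \eqn{d^2} is the sum of squared differences between the
#' `(2P+1)^2` patches centred on the two pixels (patches mirror the plane
#' symmetrically at the borders), \eqn{L_\Delta = (2P+1)^2}, and the
#' self-weight is \eqn{\exp(0) = 1}.  Output values are convex
#' combinations of input values, so the input range is preserved.
#'
#' @param plane Real matrix.
#' @param params An [nlm_params].  A `NULL` bandwidth resolves to
#'   `0.5 * sigma`; if the resolved bandwidth is 0 (noise-free or constant
#'   plane) the input is returned unchanged.
#' @return Filtered plane, same shape.
#' @export
nlm_denoise <- function(plane, params = nlm_params()) {
  check_plane(plane)
  if (!inherits(params, "nlm_params"))
    stop_invalid_param("`params` must be an nlm_params object")
  P <- params$patch_hw; Q <- params$search_hw
  if (2 * P + 1 > min(dim(plane)))
    stop_invalid_param("`patch_hw` too large for the plane")
  if (Q > max(dim(plane)) - 1)
    stop_invalid_param("`search_hw` too large for the plane")
  lambda <- params$bandwidth
  if (is.null(lambda)) {
    sigma <- params$sigma %||% estimate_sigma(plane)
    lambda <- 0.5 * sigma
  }
  if (lambda <= 0) return(plane)
  nlm2d_cpp(plane, P, Q, lambda)
}
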