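#' Sifting configuration for bi-dimensional EMD
#'
#' @param max_bimfs Maximum number of intrinsic mode planes to extract
#'   (default 4; decomposition of ECG time-frequency magnitude planes
#'   typically saturates at four scales).  `0` is allowed and yields an
#'   empty decomposition whose residue is the input.
#' @param max_sift_iters Cap on sifting iterations per mode (default 10).
#' @param sd_threshold Cauchy stopping criterion: sifting of a mode stops
#'   once `sum((prev - cur)^2) / sum(prev^2) < sd_threshold` (default 0.2,
#'   the EMD-literature default).
#' @param extrema_connectivity Pixel neighbourhood used for extrema
#'   detection, 4 or 8 (default 8).
#' @param envelope_method `"auto"` (default), `"tps"` or `"orderstat"`.
#'   Thin-plate-spline interpolation of the extrema is exact but cubic in
#'   the number of extrema; the order-statistics envelope (moving max/min
#'   followed by box smoothing, window set from the extrema density) scales
#'   linearly and is the standard fast-BEMD surrogate.  `"auto"` uses the
#'   spline whenever both extrema sets have at most `tps_max_points` points
#'   and the plane has at most `tps_max_pixels` pixels.
#' @param tps_max_points Extrema-count switch-over for `"auto"` (default 600).
#' @param tps_max_pixels Pixel-count switch-over for `"auto"` (default
#'   16384, i.e. 128 x 128).
#' @return A `sift_config` list.
#' @export
sift_config <- function(max_bimfs = 4L, max_sift_iters = 10L,
                        sd_threshold = 0.2, extrema_connectivity = 8L,
                        envelope_method = c("auto", "tps", "orderstat"),
                        tps_max_points = 600L, tps_max_pixels = 16384L) {
  envelope_method <- match.arg(envelope_method)
  if (!is_scalar_num(max_bimfs) || max_bimfs < 0 || max_bimfs != round(max_bimfs))
    stop_invalid_param("`max_bimfs` must be a non-negative integer")
  if (!is_scalar_num(max_sift_iters) || max_sift_iters < 1)
    stop_invalid_param("`max_sift_iters` must be a positive integer")
  if (!is_scalar_num(sd_threshold) || sd_threshold <= 0)
    stop_invalid_param("`sd_threshold` must be > 0")
  if (!extrema_connectivity %in% c(4L, 8L))
    stop_invalid_param("`extrema_connectivity` must be 4 or 8")
  structure(list(max_bimfs = as.integer(max_bimfs),
                 max_sift_iters = as.integer(max_sift_iters),
                 sd_threshold = sd_threshold,
                 extrema_connectivity = as.integer(extrema_connectivity),
                 envelope_method = envelope_method,
                 tps_max_points = as.integer(tps_max_points),
                 tps_max_pixels = as.integer(tps_max_pixels)),
            class = "sift_config")
}

#' Locate local extrema of a plane
#'
#' A pixel is a maximum (minimum) iff its value is strictly greater
#' (smaller) than all of its neighbours under the chosen connectivity;
#' border pixels are compared against their existing neighbours only.
#' Plateaus (connected regions of equal value strictly above/below all
#' surrounding pixels) contribute a single extremum at the region pixel
#' closest to the plateau centroid (ties broken by smallest row, then
#' column).
#'
#' @param plane Real matrix, at least 4 x 4.
#' @param connectivity 4 or 8 (default 8).
#' @return List with data frames `maxima` and `minima`, columns
#'   `row`, `col`, `value`.
#' @export
find_extrema <- function(plane, connectivity = 8L) {
  check_plane(plane, min_dim = 4L)
  if (!connectivity %in% c(4L, 8L))
    stop_invalid_param("`connectivity` must be 4 or 8")
  code <- extrema_scan_cpp(plane, as.integer(connectivity))
  maxima <- which(code == 1L, arr.ind = TRUE)
  minima <- which(code == -1L, arr.ind = TRUE)
  res <- list(
    maxima = data.frame(row = maxima[, 1], col = maxima[, 2],
                        value = plane[maxima]),
    minima = data.frame(row = minima[, 1], col = minima[, 2],
                        value = plane[minima])
  )
  if (any(code == 2L)) {
    pl <- plateau_extrema(plane, code, connectivity)
    res$maxima <- rbind(res$maxima, pl$maxima)
    res$minima <- rbind(res$minima, pl$minima)
    res$maxima <- res$maxima[order(res$maxima$row, res$maxima$col), , drop = FALSE]
    res$minima <- res$minima[order(res$minima$row, res$minima$col), , drop = FALSE]
    rownames(res$maxima) <- NULL
    rownames(res$minima) <- NULL
  }
  res
}

# Flood-fill equal-valued components containing tie pixels; a component is
# an extremum if all bordering outside pixels lie strictly below (above) it.
plateau_extrema <- function(plane, code, connectivity) {
  R <- nrow(plane); C <- ncol(plane)
  offs <- if (connectivity == 8L)
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  visited <- matrix(FALSE, R, C)
  maxima <- list(); minima <- list()
  tie_idx <- which(code == 2L)
  for (start in tie_idx) {
    if (visited[start]) next
    v <- plane[start]
    # BFS over the equal-valued component
    comp <- integer(0)
    queue <- start
    visited[start] <- TRUE
    is_max <- TRUE; is_min <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, p)
      pr <- (p - 1L) %% R + 1L
      pc <- (p - 1L) %/% R + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- pr + offs[k, 1]; cc <- pc + offs[k, 2]
        if (rr < 1 || rr > R || cc < 1 || cc > C) next
        q <- (cc - 1L) * R + rr
        u <- plane[q]
        if (u == v) {
          if (!visited[q]) { visited[q] <- TRUE; queue <- c(queue, q) }
        } else if (u > v) is_max <- FALSE
        else is_min <- FALSE
      }
    }
    if (length(comp) == R * C) next     # constant plane: no extrema
    if (!is_max && !is_min) next
    rows <- (comp - 1L) %% R + 1L
    cols <- (comp - 1L) %/% R + 1L
    d2 <- (rows - mean(rows))^2 + (cols - mean(cols))^2
    pick <- order(d2, rows, cols)[1]
    rec <- data.frame(row = rows[pick], col = cols[pick], value = v)
    if (is_max) maxima[[length(maxima) + 1L]] <- rec
    else minima[[length(minima) + 1L]] <- rec
  }
  list(maxima = do.call(rbind, c(maxima, list(data.frame(row = integer(0),
                                                         col = integer(0),
                                                         value = numeric(0))))),
       minima = do.call(rbind, c(minima, list(data.frame(row = integer(0),
                                                         col = integer(0),
                                                         value = numeric(0))))))
}

#' Interpolate an envelope surface through scattered extrema
#'
#' Fits an exact thin-plate spline (radial basis \eqn{r^2 \log r} plus an
#' affine trend) through the supplied points and evaluates it on the full
#' grid.  Outside the convex hull of the points the spline is unconstrained
#' and can diverge, so extrapolated grid nodes are replaced by the value of
#' the nearest supplied point (`extrapolate = "clamp"`, the default);
#' `extrapolate = "tps"` keeps the raw spline everywhere.
#'
#' @param points Data frame with columns `row`, `col`, `value` (at least 4
#'   non-collinear points).
#' @param shape Integer vector `c(nrow, ncol)` of the target grid.
#' @param extrapolate `"clamp"` (default) or `"tps"`.
#' @return A matrix of dimension `shape`.
#' @export
build_envelope <- function(points, shape, extrapolate = c("clamp", "tps")) {
  extrapolate <- match.arg(extrapolate)
  if (!is.data.frame(points) || !all(c("row", "col", "value") %in% names(points)))
    stop_invalid_input("`points` must have columns row, col, value")
  pts <- unique(points[, c("row", "col", "value")])
  n <- nrow(pts)
  if (n < 4L)
    stop_insufficient_extrema(sprintf(
      "need at least 4 distinct points to build an envelope, got %d", n))
  fit <- tryCatch(tps_fit(pts$row, pts$col, pts$value),
                  error = function(e) NULL)
  if (is.null(fit))
    stop_insufficient_extrema("degenerate point geometry (collinear points?)")
  env <- tps_eval_grid(fit, shape[1], shape[2])
  if (extrapolate == "clamp") {
    outside <- grid_outside_hull(pts$row, pts$col, shape[1], shape[2])
    if (any(outside)) {
      idx <- which(outside, arr.ind = TRUE)
      nn <- nearest_point_index(idx[, 1], idx[, 2], pts$row, pts$col)
      env[outside] <- pts$value[nn]
    }
  }
  env
}

# Exact thin-plate spline: solve [[K P][P' 0]] [w; a] = [v; 0] with
# K_ij = U(|p_i - p_j|), U(r) = r^2 log r, P = [1, x, y].  Coordinates are
# rescaled to the unit box (raw pixel indices make the kernel matrix
# catastrophically ill-conditioned) and the kernel diagonal gets a tiny
# ridge for numerical stability; planar data are still reproduced exactly
# (their solution has zero kernel weights).
tps_fit <- function(x, y, v, scale = max(x, y)) {
  n <- length(x)
  xs <- x / scale; ys <- y / scale
  dx <- outer(xs, xs, "-"); dy <- outer(ys, ys, "-")
  r2 <- dx * dx + dy * dy
  K <- ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))   # r^2 log r = r^2 log(r^2)/2
  diag(K) <- diag(K) + 1e-10
  P <- cbind(1, xs, ys)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(v, 0, 0, 0)
  coef <- solve(A, rhs)
  list(x = xs, y = ys, scale = scale, w = coef[seq_len(n)], a = coef[n + 1:3])
}

tps_eval_grid <- function(fit, nr, nc) {
  gr <- seq_len(nr) / fit$scale
  gc <- seq_len(nc) / fit$scale
  # affine part
  env <- outer(fit$a[2] * gr, fit$a[3] * gc, "+") + fit$a[1]
  for (i in seq_along(fit$x)) {
    dr2 <- (gr - fit$x[i])^2
    dc2 <- (gc - fit$y[i])^2
    r2 <- outer(dr2, dc2, "+")
    U <- ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))
    env <- env + fit$w[i] * U
  }
  env
}

grid_outside_hull <- function(px, py, nr, nc) {
  hull <- chull(px, py)
  if (length(hull) < 3L) return(matrix(TRUE, nr, nc))
  bnd <- cbind(px[hull], py[hull])
  # dilate slightly about the centroid so grid nodes exactly on a hull
  # edge count as inside
  ctr <- colMeans(bnd)
  eps <- 1e-6 * max(nr, nc)
  bnd <- sweep(sweep(bnd, 2, ctr) * (1 + eps), 2, ctr, `+`)
  grid <- cbind(rep(seq_len(nr), times = nc), rep(seq_len(nc), each = nr))
  inside <- mgcv::in.out(rbind(bnd, bnd[1, , drop = FALSE]), grid)
  matrix(!inside, nr, nc)
}

nearest_point_index <- function(qr, qc, px, py) {
  vapply(seq_along(qr), function(i) {
    which.min((px - qr[i])^2 + (py - qc[i])^2)
  }, integer(1))
}

# Order-statistics envelope (fast-BEMD style): moving max (or min) over a
# square window sized from the extrema density, then box-mean smoothing
# with the same window.
envelope_orderstat <- function(plane, window, which = c("max", "min")) {
  which <- match.arg(which)
  h <- (window - 1L) %/% 2L
  ext <- moving_extreme_cpp(plane, h, which == "max")
  box_mean_cpp(ext, h)
}

# Window for the order-statistics envelope: the median nearest-neighbour
# distance among the extrema (fast-BEMD practice), so the envelope tracks
# the finest oscillation present rather than the average extrema density.
orderstat_window <- function(plane, maxima, minima) {
  d <- median(c(nn_dist(maxima), nn_dist(minima)))
  if (!is.finite(d)) d <- sqrt(length(plane) / 4)
  w <- max(3L, as.integer(2 * floor(d / 2) + 1))
  min(w, 2L * (min(dim(plane)) %/% 2L) - 1L)
}

# Euclidean nearest-neighbour distance per point (grid-bucketed; exact).
nn_dist <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(numeric(0))
  if (n <= 2000L) {
    d2 <- outer(pts$row, pts$row, "-")^2 + outer(pts$col, pts$col, "-")^2
    diag(d2) <- Inf
    return(sqrt(apply(d2, 1L, min)))
  }
  # coarse spatial hashing: search the point's own and adjacent buckets,
  # widening until a neighbour is found
  cell <- max(1, floor(sqrt(
    (diff(range(pts$row)) + 1) * (diff(range(pts$col)) + 1) / n)))
  key <- paste(pts$row %/% cell, pts$col %/% cell)
  buckets <- split(seq_len(n), key)
  out <- numeric(n)
  bx <- pts$row %/% cell; by <- pts$col %/% cell
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(buckets)) assign(k, buckets[[k]], envir = lookup)
  for (i in seq_len(n)) {
    ring <- 1L
    best <- Inf
    repeat {
      cand <- integer(0)
      for (dx in -ring:ring) for (dy in -ring:ring) {
        k <- paste(bx[i] + dx, by[i] + dy)
        if (!is.null(ids <- lookup[[k]])) cand <- c(cand, ids)
      }
      cand <- setdiff(cand, i)
      if (length(cand)) {
        best <- sqrt(min((pts$row[cand] - pts$row[i])^2 +
                         (pts$col[cand] - pts$col[i])^2))
        # a neighbour in an adjacent bucket is conclusive once the ring
        # radius (in cells) covers the found distance
        if (best <= ring * cell) break
      }
      ring <- ring + 1L
      if (ring > 64L) break
    }
    out[i] <- best
  }
  out[is.finite(out)]
}

#' One sifting step
#'
#' Subtracts the mean of the upper and lower envelope surfaces from the
#' plane: `plane - (E_max + E_min) / 2`.
#'
#' @param plane Real matrix (at least 4 x 4).
#' @param config A [sift_config].
#' @return The sifted plane.  Signals an `stecg_insufficient_extrema`
#'   condition when either extrema set is too small to support an envelope.
#' @export
sift_once <- function(plane, config = sift_config()) {
  check_plane(plane, min_dim = 4L)
  ext <- find_extrema(plane, config$extrema_connectivity)
  n_max <- nrow(ext$maxima); n_min <- nrow(ext$minima)
  if (n_max < 4L || n_min < 4L)
    stop_insufficient_extrema(sprintf(
      "not enough extrema to sift (%d maxima, %d minima)", n_max, n_min))
  method <- config$envelope_method
  if (method == "auto") {
    # exact splines only where both the dense solve (extrema count) and the
    # grid evaluation (pixel count) stay cheap; otherwise the linear-cost
    # order-statistics envelope
    method <- if (max(n_max, n_min) <= config$tps_max_points &&
                  length(plane) <= config$tps_max_pixels) "tps" else "orderstat"
  }
  if (method == "tps") {
    e_max <- build_envelope(ext$maxima, dim(plane))
    e_min <- build_envelope(ext$minima, dim(plane))
  } else {
    w <- orderstat_window(plane, ext$maxima, ext$minima)
    e_max <- envelope_orderstat(plane, w, "max")
    e_min <- envelope_orderstat(plane, w, "min")
  }
  plane - (e_max + e_min) / 2
}

#' Bi-dimensional empirical mode decomposition
#'
#' Decomposes a plane into bi-dimensional intrinsic mode functions (BIMFs)
#' plus a residue by envelope sifting.  Each mode is obtained by repeatedly
#' applying [sift_once()] to the current residue until the Cauchy criterion
#' `sum((prev - cur)^2) / sum(prev^2) < sd_threshold` or the iteration cap
#' is reached; the mode is subtracted and the recursion continues on the new
#' residue until `max_bimfs` modes are extracted or the extrema are
#' exhausted.  By construction `Reduce("+", bimfs) + residue` equals the
#' input exactly.
#'
#' @param plane Real matrix (at least 4 x 4).
#' @param config A [sift_config].
#' @return An object of class `bimf_set`: list with `bimfs` (list of
#'   planes, decreasing spatial frequency), `residue`, and `n_sifts`
#'   (iterations spent on each mode).
#' @export
bemd_decompose <- function(plane, config = sift_config()) {
  check_plane(plane, min_dim = 4L)
  bimfs <- list()
  n_sifts <- integer(0)
  residue <- plane
  while (length(bimfs) < config$max_bimfs) {
    h_prev <- residue
    h <- tryCatch(sift_once(h_prev, config),
                  stecg_insufficient_extrema = function(e) NULL)
    if (is.null(h)) break                    # residue keeps remaining signal
    iters <- 1L
    while (iters < config$max_sift_iters) {
      denom <- sum(h_prev^2)
      sd_val <- if (denom == 0) 0 else sum((h_prev - h)^2) / denom
      if (sd_val < config$sd_threshold) break
      h_prev <- h
      h_next <- tryCatch(sift_once(h_prev, config),
                         stecg_insufficient_extrema = function(e) NULL)
      if (is.null(h_next)) break
      h <- h_next
      iters <- iters + 1L
    }
    bimfs[[length(bimfs) + 1L]] <- h
    n_sifts <- c(n_sifts, iters)
    residue <- residue - h
  }
  structure(list(bimfs = bimfs, residue = residue, n_sifts = n_sifts),
            class = "bimf_set")
}

#' @export
print.bimf_set <- function(x, ...) {
  cat(sprintf("<bimf_set> %d BIMF(s) + residue [%d x %d], sift counts: %s\n",
              length(x$bimfs),
              nrow(x$residue), ncol(x$residue),
              if (length(x$n_sifts)) paste(x$n_sifts, collapse = ", ") else "-"))
  invisible(x)
}
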