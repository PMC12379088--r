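#' Curve geometry for tongue contours
#'
#' The complexity metrics are defined on signed curvature sampled at
#' equidistant points along the contour. These helpers resample an open
#' planar polyline to equal arc-length spacing, smooth it with a running
#' average, and estimate signed curvature, either from finite-difference
#' derivatives or from the circle circumscribing consecutive point triples
#' (the osculating-circle reading: curvature is the reciprocal of the radius
#' of the circle that best conforms to the curve at a point).
#'
#' Curvature is returned both per millimetre (`kappa_mm`) and on the
#' normalised arc-length scale (`kappa = kappa_mm * L`, with `L` the contour
#' length in mm). On the normalised scale the integral of `|kappa|` over
#' s in \[0, 1\] is the total absolute turning angle in radians, which makes
#' the modified curvature index invariant to uniform scaling.
#'
#' @name curve_geometry
NULL

# --- per-curve primitives (matrix in / matrix out) ------------------------

resample_curve <- function(xy, n_points) {
  if (n_points < 10) abort("`n_points` must be at least 10.")
  len <- arc_lengths(xy)
  total <- len[length(len)]
  if (total <= 0) abort("Degenerate contour: total arc length is zero.", class = "tsc_geometry_error")
  s_new <- seq(0, total, length.out = n_points)
  # cubic-spline interpolation of x(s), y(s): unlike linear interpolation it
  # does not cut corners, so equal arc positions give equal chords on
  # smooth curves to ~1e-9 relative
  out <- cbind(
    x = stats::spline(len, xy[, 1], xout = s_new, method = "fmm")$y,
    y = stats::spline(len, xy[, 2], xout = s_new, method = "fmm")$y
  )
  # endpoints preserved exactly
  out[1, ] <- xy[1, ]
  out[n_points, ] <- xy[nrow(xy), ]
  out
}

# Centred running mean. Even windows have no symmetric centring, so an
# even `window` is applied as the mean of the two w-point windows offset by
# half a step (a (w+1)-point kernel with half weights at the extremes).
# Near the ends the half-width shrinks symmetrically so endpoints move
# minimally and no data is invented.
smooth_curve <- function(xy, window = 6) {
  n <- nrow(xy)
  if (window < 1) abort("`window` must be >= 1.")
  if (window >= n) abort("`window` must be smaller than the number of points.", class = "tsc_parameter_error")
  if (window == 1) return(xy)
  if (window %% 2 == 1) {
    h <- (window - 1) / 2
    wts <- rep(1, window)
  } else {
    h <- window / 2
    wts <- c(0.5, rep(1, window - 1), 0.5)
  }
  smooth_one <- function(v) {
    vapply(seq_len(n), function(i) {
      hi <- min(h, i - 1, n - i)
      idx <- (i - hi):(i + hi)
      if (hi == h) sum(v[idx] * wts[(h - hi + 1):(h + hi + 1)]) / sum(wts) else mean(v[idx])
    }, numeric(1))
  }
  cbind(x = smooth_one(xy[, 1]), y = smooth_one(xy[, 2]))
}

# signed curvature per point; assumes equidistant samples
curve_curvature <- function(xy, method = c("derivative", "circumcircle")) {
  method <- match.arg(method)
  n <- nrow(xy)
  if (n < 3) abort("Curvature needs at least 3 points.", class = "tsc_geometry_error")
  len <- arc_lengths(xy)
  total <- len[length(len)]
  h <- total / (n - 1)
  if (method == "derivative") {
    d1 <- function(v) {
      c(
        (-3 * v[1] + 4 * v[2] - v[3]) / (2 * h),
        (v[3:n] - v[1:(n - 2)]) / (2 * h),
        (3 * v[n] - 4 * v[n - 1] + v[n - 2]) / (2 * h)
      )
    }
    d2 <- function(v) {
      mid <- (v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)]) / h^2
      c(mid[1], mid, mid[length(mid)])
    }
    xp <- d1(xy[, 1]); yp <- d1(xy[, 2])
    xpp <- d2(xy[, 1]); ypp <- d2(xy[, 2])
    kappa <- (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  } else {
    # signed Menger curvature of consecutive triples: 2 * cross / (|a||b||c|)
    p1 <- xy[1:(n - 2), , drop = FALSE]
    p2 <- xy[2:(n - 1), , drop = FALSE]
    p3 <- xy[3:n, , drop = FALSE]
    cross <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
    a <- sqrt(rowSums((p2 - p1)^2))
    b <- sqrt(rowSums((p3 - p2)^2))
    cc <- sqrt(rowSums((p3 - p1)^2))
    k_mid <- 2 * cross / (a * b * cc)
    kappa <- c(k_mid[1], k_mid, k_mid[length(k_mid)])
  }
  # retroflex signature: the tangent doubles back against the dominant
  # anterior-posterior travel direction
  dx <- c(xy[2, 1] - xy[1, 1], (xy[3:n, 1] - xy[1:(n - 2), 1]) / 2, xy[n, 1] - xy[n - 1, 1])
  dominant <- sign(xy[n, 1] - xy[1, 1])
  if (dominant == 0) dominant <- sign(sum(dx)) + (sign(sum(dx)) == 0)
  retro <- sign(dx) == -dominant & abs(dx) > 1e-9 * total
  list(
    s = seq(0, 1, length.out = n),
    kappa_mm = kappa,
    kappa = kappa * total,
    retroflex = retro,
    length_mm = total
  )
}

# --- tidy wrappers --------------------------------------------------------

#' Resample contours to equidistant arc-length spacing
#'
#' @param contours Data frame with columns `token_id`, `point`, `x`, `y`
#'   (coordinates in mm; any extra columns are dropped).
#' @param n_points Number of equidistant samples per contour (default 100).
#' @return A tibble with the same columns, `n_points` rows per token,
#'   endpoints preserved exactly.
#' @export
resample_contours <- function(contours, n_points = 100) {
  mats <- split_contours(contours)
  bind_contours(lapply(mats, resample_curve, n_points = n_points))
}

#' Smooth contours with a centred running average
#'
#' @inheritParams resample_contours
#' @param window Window size in points (default 6, the conventional
#'   6-point average smoother). Even windows use the centred even-order
#'   moving average; the window shrinks symmetrically at the ends.
#' @return A tibble of smoothed contours; point counts unchanged.
#' @export
smooth_contours <- function(contours, window = 6) {
  mats <- split_contours(contours)
  bind_contours(lapply(mats, smooth_curve, window = window))
}

#' Signed curvature profiles of tongue contours
#'
#' Resamples each contour to `n_points` equidistant points, smooths with the
#' running average, and computes signed curvature. The default order is
#' resample then smooth; set `smooth_first = TRUE` for the other order.
#'
#' @inheritParams smooth_contours
#' @param n_points Equidistant samples per contour (default 100).
#' @param method `"derivative"` (finite differences, default) or
#'   `"circumcircle"` (three-point circumscribed circle).
#' @param smooth_first Smooth before resampling instead of after.
#' @param trim_factor Trim factor defining the inflection threshold: points
#'   whose osculating radius exceeds `trim_factor * L` count as straight.
#'   Stored as `trim_threshold = 1 / trim_factor` on the normalised scale.
#' @return A tibble with one row per sample point: `token_id`, `s`
#'   (normalised arc position), `kappa` (signed curvature, normalised scale),
#'   `kappa_mm` (per mm), `retroflex` (tangent doubling back), `length_mm`,
#'   and `trim_threshold`.
#' @export
curvature_profiles <- function(contours, n_points = 100, window = 6,
                               method = c("derivative", "circumcircle"),
                               smooth_first = FALSE, trim_factor = 0.3) {
  method <- match.arg(method)
  mats <- split_contours(contours)
  purrr::map2_dfr(mats, names(mats), function(m, id) {
    if (smooth_first) {
      m <- resample_curve(smooth_curve(m, window = window), n_points = n_points)
    } else {
      # final resample restores exact equidistance after smoothing
      m <- resample_curve(smooth_curve(resample_curve(m, n_points = n_points),
                                       window = window), n_points = n_points)
    }
    prof <- curve_curvature(m, method = method)
    tibble(
      token_id = id,
      s = prof$s,
      kappa = prof$kappa,
      kappa_mm = prof$kappa_mm,
      retroflex = prof$retroflex,
      length_mm = prof$length_mm,
      trim_threshold = 1 / trim_factor
    )
  })
}
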