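#' Synthetic tongue-like contours with known complexity
#'
#' A contour is built as a circular base arc (the overall convex tongue
#' body) plus Gaussian displacement bumps orthogonal to the arc (local
#' differentiation features: grooves and humps), plus optional point-wise
#' Gaussian jitter emulating tracking noise. Gaussian bumps are smooth,
#' analytically differentiable, and have closed-form peak extra curvature
#' `|A| / w^2` (amplitude over squared width in mm), which makes it possible
#' to place a bump deliberately above or below the inflection trim
#' threshold.
#'
#' Ground truth is computed from the *noise-free* analytic curve by dense
#' sampling (10 x `n_points`), never by the metric pipeline under test: the
#' true reported NINFL is `max(k, 1)` with `k` the number of supra-threshold
#' bumps (k alternating-sign bumps on a sub-threshold base give k - 1
#' curvature sign changes, reported k), and the true MCI is the dense
#' trapezoidal integral of unsigned curvature.
#'
#' @name synthetic_contours
NULL

#' Specify a synthetic contour
#'
#' @param chord_mm Straight-line distance between the contour endpoints
#'   (default 70 mm, a typical child midsagittal tongue contour).
#' @param bulge_mm Height of the base arc above the chord (sagitta). May
#'   exceed `chord_mm / 2` for arcs turning more than pi.
#' @param bumps Tibble/data frame with columns `center` (arc-length
#'   fraction, in \[0.1, 0.9\]), `amplitude` (mm, signed; alternate signs for
#'   guaranteed sign changes), `width` (as fraction of contour length).
#'   Bump centres must be sorted and separated by at least 1.5 x width.
#' @param noise_sd Gaussian jitter SD in mm added to each sampled
#'   coordinate (default 0; typical tracking noise is ~0.2 mm).
#' @param n_points Number of sampled points (default 100).
#' @param seed Integer seed for the jitter.
#' @return A `contour_recipe` list.
#' @export
contour_recipe <- function(chord_mm = 70, bulge_mm = 12, bumps = NULL,
                           noise_sd = 0, n_points = 100, seed = 1) {
  bumps <- if (is.null(bumps)) {
    tibble(center = numeric(0), amplitude = numeric(0), width = numeric(0))
  } else {
    as_tibble(bumps)
  }
  if (nrow(bumps)) {
    if (is.unsorted(bumps$center)) abort("Bump centers must be sorted.", class = "tsc_recipe_error")
    if (any(bumps$center < 0.1 | bumps$center > 0.9)) {
      abort("Bump centers must lie in [0.1, 0.9].", class = "tsc_recipe_error")
    }
    if (nrow(bumps) > 1) {
      gap <- diff(bumps$center)
      minw <- pmax(bumps$width[-1], bumps$width[-nrow(bumps)])
      if (any(gap < 1.5 * minw)) {
        abort("Bumps overlap: centers must be separated by >= 1.5 x width.",
          class = "tsc_recipe_error")
      }
    }
  }
  structure(list(
    chord_mm = chord_mm, bulge_mm = bulge_mm, bumps = bumps,
    noise_sd = noise_sd, n_points = n_points, seed = seed
  ), class = "contour_recipe")
}

# analytic curve of a recipe: base arc + orthogonal Gaussian displacements,
# evaluated at arc-length fractions t of the base arc
recipe_curve <- function(recipe, t) {
  c0 <- recipe$chord_mm
  h <- recipe$bulge_mm
  R <- (c0^2 + 4 * h^2) / (8 * h)
  half <- asin(pmin(c0 / (2 * R), 1))
  theta <- if (h <= R) 2 * half else 2 * pi - 2 * half
  L0 <- R * theta
  # arc from angle (pi/2 + theta/2) to (pi/2 - theta/2), apex up, tip first
  ang <- pi / 2 + theta / 2 - t * theta
  base <- cbind(x = R * cos(ang), y = R * sin(ang) - (R - h))
  # inward unit normal (towards the chord) is -(cos, sin); bumps displace
  # along the outward normal for positive amplitude
  disp <- rep(0, length(t))
  if (nrow(recipe$bumps)) {
    for (i in seq_len(nrow(recipe$bumps))) {
      b <- recipe$bumps[i, ]
      disp <- disp + b$amplitude * exp(-(t - b$center)^2 / (2 * b$width^2))
    }
  }
  cbind(x = base[, 1] + disp * cos(ang), y = base[, 2] + disp * sin(ang))
}

#' Peak extra curvature of a Gaussian displacement bump
#'
#' On a locally straight base, a bump of amplitude `A` mm and width `w` mm
#' adds peak curvature `|A| / w^2` (per mm); a bump is supra-threshold when
#' its peak osculating radius `w^2 / |A|` is below `trim_factor * L`.
#'
#' @param amplitude_mm,width_mm Bump parameters in mm.
#' @return Peak curvature in 1/mm.
#' @export
bump_peak_curvature <- function(amplitude_mm, width_mm) {
  abs(amplitude_mm) / width_mm^2
}

#' Generate a synthetic tongue contour with ground truth
#'
#' @param recipe A [contour_recipe()].
#' @param token_id Token identifier for the output table.
#' @param trim_factor Trim factor used for the ground-truth supra-threshold
#'   decision (default 0.3).
#' @return A list: `contour` (tibble `token_id`, `point`, `x`, `y`; jittered
#'   when `noise_sd > 0`) and `truth` (list with `ninfl_reported`,
#'   `ninfl_raw`, `analytic_mci`, `length_mm`, `n_supra_bumps`), computed
#'   from the noise-free analytic curve at 10 x `n_points` density.
#' @export
make_contour <- function(recipe, token_id = "tok1", trim_factor = 0.3) {
  stopifnot(inherits(recipe, "contour_recipe"))
  n <- recipe$n_points
  # --- ground truth from the analytic parametric curve, dense sampling ---
  # deliberately self-contained (simple parametric finite differences, no
  # smoothing, no arc-length resampling) so the truth does not run through
  # the metric pipeline under test
  nd <- 10L * n
  t_dense <- seq(0, 1, length.out = nd)
  dt <- t_dense[2] - t_dense[1]
  r <- recipe_curve(recipe, t_dense)
  xp <- c(NA, (r[3:nd, 1] - r[1:(nd - 2), 1]) / (2 * dt), NA)
  yp <- c(NA, (r[3:nd, 2] - r[1:(nd - 2), 2]) / (2 * dt), NA)
  xpp <- c(NA, (r[3:nd, 1] - 2 * r[2:(nd - 1), 1] + r[1:(nd - 2), 1]) / dt^2, NA)
  ypp <- c(NA, (r[3:nd, 2] - 2 * r[2:(nd - 1), 2] + r[1:(nd - 2), 2]) / dt^2, NA)
  speed <- sqrt(xp^2 + yp^2)
  kappa_mm <- (xp * ypp - yp * xpp) / speed^3 # per mm, parametrisation-free
  i <- 2:(nd - 1)
  L <- sum(speed[i] * dt) # dense arc length
  # total absolute turning angle: integral of |kappa| dl = |kappa| * speed dt
  mci <- sum(abs(kappa_mm[i]) * speed[i] * dt)
  thr_mm <- 1 / (trim_factor * L)
  s_dense <- cumsum(c(0, speed[i[-length(i)]] * dt)) / L # arc position of interior samples
  z <- ifelse(abs(kappa_mm[i]) < thr_mm, 0, sign(kappa_mm[i]))
  nzidx <- which(z != 0)
  crossings_s <- numeric(0)
  s_a <- s_b <- numeric(0)
  if (length(nzidx) > 1) {
    sgn <- z[nzidx]
    flips <- which(sgn[-1] != sgn[-length(sgn)])
    s_a <- s_dense[nzidx[flips]]
    s_b <- s_dense[nzidx[flips + 1]]
    crossings_s <- (s_a + s_b) / 2
  }
  # the edge rule is part of the metric definition: a sign change whose
  # flanking supra-threshold points touch the first or last 5% of arc
  # length does not count
  edge_fraction <- 0.05
  counted <- s_a >= edge_fraction & s_b <= 1 - edge_fraction
  raw <- sum(counted)
  # threshold margins: how decisively the supra regions clear the trim
  # threshold (margin_hi, min over supra runs of peak/threshold) and how far
  # the sub-threshold *local maxima* (side lobes, gentle wiggles) stay below
  # it (margin_lo). Shoulders of supra runs are not local maxima, so
  # margin_lo is not trivially 1 by continuity.
  ak <- abs(kappa_mm[i])
  rl <- rle(z != 0)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  runs <- if (any(rl$values)) {
    idx <- which(rl$values)
    tibble(
      s_start = s_dense[starts[idx]],
      s_end = s_dense[ends[idx]],
      peak_ratio = vapply(idx, function(j) max(ak[starts[j]:ends[j]]), numeric(1)) / thr_mm
    )
  } else {
    tibble(s_start = numeric(0), s_end = numeric(0), peak_ratio = numeric(0))
  }
  margin_hi <- if (nrow(runs)) min(runs$peak_ratio) else NA_real_
  na <- length(ak)
  locmax <- c(FALSE, ak[2:(na - 1)] >= ak[1:(na - 2)] &
    ak[2:(na - 1)] >= ak[3:na], FALSE)
  sub_peaks <- ak[locmax & ak < thr_mm]
  margin_lo <- if (length(sub_peaks)) max(sub_peaks) / thr_mm else NA_real_
  supra <- if (nrow(recipe$bumps)) {
    sum(bump_peak_curvature(recipe$bumps$amplitude, recipe$bumps$width * L) > thr_mm)
  } else {
    0L
  }
  # --- emitted contour: n_points samples plus seeded smooth noise ---
  # Tracking error on vendor spline exports is smooth at the contour scale
  # (the spline fit absorbs pixel-level noise), so the jitter is a smooth
  # random field: a few low-order harmonics with a red spectrum, scaled to
  # pointwise SD ~ noise_sd, applied to each coordinate.
  pts <- recipe_curve(recipe, seq(0, 1, length.out = n))
  if (recipe$noise_sd > 0) {
    tt <- seq(0, 1, length.out = n)
    pts <- pts + withr::with_seed(recipe$seed, {
      field <- function() {
        w <- rowSums(vapply(1:4, function(j) {
          (rnorm(1) * sin(j * pi * tt) + rnorm(1) * cos(j * pi * tt)) / j
        }, numeric(n)))
        w / sqrt(sum(1 / (1:4)^2) / 2) # unit pointwise SD, approximately
      }
      recipe$noise_sd * cbind(field(), field())
    })
  }
  list(
    contour = tibble(token_id = token_id, point = seq_len(n), x = pts[, 1], y = pts[, 2]),
    truth = list(
      ninfl_raw = as.integer(raw),
      ninfl_reported = as.integer(raw + 1L),
      n_supra_bumps = as.integer(supra),
      analytic_mci = mci,
      length_mm = L,
      margin_hi = margin_hi,
      margin_lo = margin_lo,
      runs = runs,
      crossings_s = crossings_s,
      crossings_counted = counted
    )
  )
}
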