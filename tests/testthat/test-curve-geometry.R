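test_that("equidistant resampling preserves endpoints, spacing and length", {
  # straight segment: resampled points land on the integer grid
  seg <- curve_tbl(c(0, 10), c(0, 0))
  got <- resample_contours(seg, n_points = 11)
  expect_equal(got$x, 0:10, tolerance = 1e-12)
  expect_equal(got$y, rep(0, 11), tolerance = 1e-12)

  # quarter circle: adjacent chords equal within 1e-6 relative
  qc <- circle_arc(10, pi / 2, n = 200)
  rs <- resample_contours(qc, n_points = 100)
  chords <- sqrt(diff(rs$x)^2 + diff(rs$y)^2)
  expect_lt((max(chords) - min(chords)) / mean(chords), 1e-6)
  expect_equal(c(rs$x[1], rs$y[1]), c(qc$x[1], qc$y[1]))
  expect_equal(c(rs$x[100], rs$y[100]), c(qc$x[200], qc$y[200]))

  # dense sine: arc length preserved within 0.1% (10x-density oracle)
  x <- seq(0, 50, length.out = 2000)
  sine <- curve_tbl(x, 8 * sin(2 * pi * x / 25))
  L_oracle <- sum(sqrt(diff(sine$x)^2 + diff(sine$y)^2))
  rs2 <- resample_contours(sine, n_points = 200)
  L_got <- sum(sqrt(diff(rs2$x)^2 + diff(rs2$y)^2))
  expect_lt(abs(L_got - L_oracle) / L_oracle, 1e-3)

  expect_error(
    resample_contours(curve_tbl(rep(1, 12), rep(2, 12))),
    class = "tsc_geometry_error"
  )
})

test_that("running-average smoothing behaves as an averaging operator", {
  x <- seq(0, 30, length.out = 40)
  line <- curve_tbl(x, 2 * x + 1)

  # window 1 is the identity
  expect_equal(smooth_contours(line, window = 1), dplyr::as_tibble(line))

  # collinear points stay collinear (averaging is affine)
  sm <- smooth_contours(line, window = 6)
  expect_equal(sm$y, 2 * sm$x + 1, tolerance = 1e-9)

  # white-noise-perturbed arc gets strictly closer to the clean arc
  clean <- circle_arc(30, pi / 3, n = 120)
  noisy <- withr::with_seed(4, dplyr::mutate(clean,
    x = x + rnorm(120, sd = 0.4), y = y + rnorm(120, sd = 0.4)
  ))
  rms <- function(d) sqrt(mean((d$x - clean$x)^2 + (d$y - clean$y)^2))
  expect_lt(rms(smooth_contours(noisy, window = 6)), rms(noisy))

  expect_error(smooth_contours(curve_tbl(1:12, rep(0, 12)), window = 12),
    class = "tsc_parameter_error")
})

test_that("signed curvature matches analytic values on canonical curves", {
  # circle radius 10: |kappa| = 0.1 per mm at interior points, both methods
  circ <- circle_arc(10, 1.8 * pi, n = 300)
  for (m in c("derivative", "circumcircle")) {
    pr <- curvature_profiles(circ, method = m)
    interior <- abs(pr$kappa_mm[10:90])
    expect_true(all(abs(interior - 0.1) / 0.1 < 0.02))
  }

  # straight line: kappa = 0 everywhere
  pr0 <- curvature_profiles(curve_tbl(seq(0, 60, length.out = 80), rep(0, 80)))
  expect_true(all(abs(pr0$kappa) < 1e-8))

  # sine arc: matches closed-form curvature within 2% away from endpoints
  x <- seq(0, 25, length.out = 1200)
  a <- 5
  lam <- 25
  sine <- curve_tbl(x, a * sin(2 * pi * x / lam))
  pr <- curvature_profiles(sine, n_points = 400, window = 1)
  # closed form at the resampled x locations
  xs <- approx(cumsum(c(0, sqrt(diff(x)^2 + diff(a * sin(2 * pi * x / lam))^2))),
    x, xout = pr$s * pr$length_mm[1], ties = "ordered")$y
  yp <- a * 2 * pi / lam * cos(2 * pi * xs / lam)
  ypp <- -a * (2 * pi / lam)^2 * sin(2 * pi * xs / lam)
  k_true <- ypp / (1 + yp^2)^1.5
  idx <- 20:380
  big <- abs(k_true[idx]) > 0.1 * max(abs(k_true)) # away from the zero crossings
  rel <- abs(pr$kappa_mm[idx][big] - k_true[idx][big]) / abs(k_true[idx][big])
  expect_lt(stats::quantile(rel, 0.95), 0.02)

  expect_error(resample_contours(curve_tbl(c(0, 1), c(0, 0)), n_points = 5),
    "at least 10")
})

test_that("curvature is equivariant under rigid motion, reflection, reversal, scale", {
  rec <- make_contour(contour_recipe(
    bumps = tibble::tibble(center = c(0.35, 0.65), amplitude = c(2.5, -2.5), width = 0.08),
    noise_sd = 0
  ))
  base <- rec$contour
  pr <- curvature_profiles(base)

  # rigid motion: rotate 37 degrees, translate
  th <- 37 * pi / 180
  rot <- dplyr::mutate(base,
    x2 = cos(th) * x - sin(th) * y + 12,
    y2 = sin(th) * x + cos(th) * y - 5, x = x2, y = y2
  )
  pr_rot <- curvature_profiles(rot[, c("token_id", "point", "x", "y")])
  expect_equal(pr_rot$kappa, pr$kappa, tolerance = 1e-6)

  # reflection flips the sign pointwise
  refl <- dplyr::mutate(base, y = -y)
  expect_equal(curvature_profiles(refl)$kappa, -pr$kappa, tolerance = 1e-6)

  # reversal flips sign and reverses the sequence
  rev_d <- base |>
    dplyr::arrange(dplyr::desc(point)) |>
    dplyr::mutate(point = dplyr::row_number())
  expect_equal(curvature_profiles(rev_d)$kappa, rev(-pr$kappa), tolerance = 1e-6)

  # scaling leaves normalised curvature unchanged
  sc <- dplyr::mutate(base, x = 10 * x, y = 10 * y)
  expect_equal(curvature_profiles(sc)$kappa, pr$kappa, tolerance = 1e-6)
})

test_that("derivative and circumcircle methods agree on analytic curves", {
  shapes <- list(
    circle_arc(10, pi, n = 300),
    circle_arc(35, pi / 2, n = 300),
    { # ellipse quadrant
      t <- seq(0, pi / 2, length.out = 300)
      curve_tbl(40 * cos(t), 22 * sin(t))
    },
    { # gentle sine arc
      x <- seq(0, 60, length.out = 300)
      curve_tbl(x, 10 * sin(pi * x / 60))
    }
  )
  for (sh in shapes) {
    pa <- curvature_profiles(sh, method = "derivative", window = 1)
    pb <- curvature_profiles(sh, method = "circumcircle", window = 1)
    idx <- 10:90
    rel <- abs(pa$kappa[idx] - pb$kappa[idx]) /
      pmax(abs(pb$kappa[idx]), max(abs(pb$kappa)) * 0.05)
    expect_lt(max(rel), 0.02)
  }
})
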