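test_that("NINFL counts trimmed sign changes with the +1 convention", {
  # straight line: raw 0, reported 1
  line <- curve_tbl(seq(0, 60, length.out = 80), rep(0, 80))
  nf <- compute_ninfl(curvature_profiles(line))
  expect_equal(nf$ninfl_raw, 0L)
  expect_equal(nf$ninfl_reported, 1L)

  # single circular arc, one curvature sign: raw 0, reported 1
  arc <- circle_arc(15, 2, n = 150)
  nf_arc <- compute_ninfl(curvature_profiles(arc))
  expect_equal(nf_arc$ninfl_raw, 0L)
  expect_equal(nf_arc$ninfl_reported, 1L)

  # S-curve from two tangent arcs of radius 0.2 * L each: raw 1, reported 2
  # (each arc's radius is below 0.3 L, so both halves survive the trim);
  # with r = 0.2 L and L = 2 r a, each arc sweeps a = 2.5 rad
  r <- 10
  t1 <- seq(0, 2.5, length.out = 100)
  left <- cbind(r * sin(t1), r * (1 - cos(t1)))
  c2 <- left[100, ] + r * c(sin(t1[100]), -cos(t1[100]))
  t2 <- seq(0, 2.5, length.out = 100)
  right <- cbind(
    c2[1] - r * sin(t1[100] - t2),
    c2[2] + r * cos(t1[100] - t2)
  )
  s_curve <- curve_tbl(c(left[, 1], right[-1, 1]), c(left[, 2], right[-1, 2]))
  prof <- curvature_profiles(s_curve)
  # geometry check: each arc radius = 0.2 * L
  expect_equal(0.2 * prof$length_mm[1], r, tolerance = 0.01)
  nf_s <- compute_ninfl(prof)
  expect_equal(nf_s$ninfl_raw, 1L)
  expect_equal(nf_s$ninfl_reported, 2L)

  # k alternating supra-threshold bumps: reported k (k = 2..4)
  for (k in 2:4) {
    rec <- random_bump_recipe(k, seed = 100 + k)
    mc <- make_contour(rec)
    expect_equal(mc$truth$ninfl_reported, k)
    prof_k <- curvature_profiles(mc$contour)
    expect_equal(compute_ninfl(prof_k)$ninfl_reported, k)
  }
})

test_that("NINFL parameter validation and variants work", {
  prof <- curvature_profiles(circle_arc(15, 2, n = 100))
  expect_error(compute_ninfl(prof, trim_factor = 0), class = "tsc_parameter_error")
  expect_error(compute_ninfl(prof, edge_fraction = 0.5), class = "tsc_parameter_error")
  # literal trim reading keeps only gentle curvature: on a gentle S-curve
  # (|kappa_norm| = 2 on both halves, below the threshold) the conventional
  # reading trims everything (reported 1) while the literal reading keeps
  # the sign change (reported 2)
  r <- 10
  t1 <- seq(0, 1, length.out = 100)
  left <- cbind(r * sin(t1), r * (1 - cos(t1)))
  c2 <- left[100, ] + r * c(sin(t1[100]), -cos(t1[100]))
  right <- cbind(
    c2[1] - r * sin(t1[100] - t1),
    c2[2] + r * cos(t1[100] - t1)
  )
  s_curve <- curve_tbl(c(left[, 1], right[-1, 1]), c(left[, 2], right[-1, 2]))
  prof2 <- curvature_profiles(s_curve)
  expect_equal(compute_ninfl(prof2)$ninfl_reported, 1L)
  expect_equal(compute_ninfl(prof2, literal_trim = TRUE)$ninfl_reported, 2L)
})

test_that("MCI equals total absolute turning and is scale invariant", {
  # straight line: 0
  line <- curve_tbl(seq(0, 60, length.out = 80), rep(0, 80))
  expect_lt(compute_mci(curvature_profiles(line)), 1e-6)

  # semicircle: pi within 1% at n = 100
  semi <- circle_arc(20, pi, n = 400)
  expect_equal(compute_mci(curvature_profiles(semi)), pi, tolerance = 0.01)

  # quarter circle: pi/2 within 1%; scaled x10: identical within 1e-6 rel
  quarter <- circle_arc(20, pi / 2, n = 400)
  m1 <- compute_mci(curvature_profiles(quarter))
  expect_equal(m1, pi / 2, tolerance = 0.01)
  big <- dplyr::mutate(quarter, x = 10 * x, y = 10 * y)
  m2 <- compute_mci(curvature_profiles(big))
  expect_lt(abs(m2 - m1) / m1, 1e-6)

  # non-equidistant profile is rejected
  bad <- curvature_profiles(quarter)[c(1:50, 52:100), ]
  expect_error(compute_mci(bad), class = "tsc_geometry_error")
})

test_that("MCI is additive over concatenated sub-arcs", {
  # a quarter circle followed by its continuation to a semicircle
  semi <- circle_arc(25, pi, n = 401)
  first <- semi[1:201, ]
  second <- semi[201:401, ] |> dplyr::mutate(point = dplyr::row_number())
  m_whole <- compute_mci(curvature_profiles(semi))
  m_parts <- compute_mci(curvature_profiles(first)) +
    compute_mci(curvature_profiles(second))
  expect_equal(m_whole, m_parts, tolerance = 0.02)
})

test_that("exclusion rules implement the over-5 / over-6 caps", {
  recs <- tibble::tibble(
    token_id = paste0("t", 1:4),
    ninfl_raw = c(0L, 1L, 5L, 2L),
    ninfl_reported = c(1L, 2L, 6L, 3L),
    mci = c(2.0, 2.5, 1.0, 6.5)
  )
  out <- apply_exclusions(recs)
  expect_equal(nrow(out$kept), 3) # kept for the NINFL analysis
  expect_equal(sum(!out$kept$excluded_mci), 2) # kept for the MCI analysis
  expect_equal(out$n_excluded_ninfl, 1)
  expect_equal(out$n_excluded_mci, 1)
  # a NINFL-excluded token is always MCI-excluded too
  expect_true(all(out$records$excluded_mci[out$records$excluded_ninfl]))

  # all under caps: nothing excluded, input preserved
  ok <- apply_exclusions(dplyr::mutate(recs, ninfl_reported = 2L, mci = 1))
  expect_equal(ok$n_excluded_ninfl + ok$n_excluded_mci, 0)
  expect_equal(nrow(ok$kept), 4)

  # empty input: empty output, zero counts
  empty <- apply_exclusions(recs[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(empty$n_excluded_ninfl, 0L)
})

test_that("reported NINFL is raw + 1 and confined to 1..5 after exclusion", {
  mets <- purrr::map_dfr(1:12, function(i) {
    k <- i %% 4
    tongue_metrics(make_contour(random_bump_recipe(k, seed = 300 + i),
      token_id = paste0("t", i))$contour)
  })
  expect_equal(mets$ninfl_reported, mets$ninfl_raw + 1L)
  kept <- apply_exclusions(mets)$kept
  expect_true(all(kept$ninfl_reported %in% 1:5))
})

test_that("a below-threshold wiggle never changes the reported NINFL", {
  for (k in c(0L, 1L, 2L)) {
    rec <- random_bump_recipe(k, seed = 40 + k)
    base_n <- compute_ninfl(curvature_profiles(make_contour(rec)$contour))$ninfl_reported
    # inject a gentle wiggle (peak normalised curvature ~2, i.e. peak
    # osculating radius > 0.3 L) in the free mid-contour gap
    L <- make_contour(rec)$truth$length_mm
    wig <- tibble::tibble(center = 0.5, amplitude = 2 * 0.05^2 * L, width = 0.05)
    rec2 <- contour_recipe(
      chord_mm = rec$chord_mm, bulge_mm = rec$bulge_mm,
      bumps = dplyr::arrange(dplyr::bind_rows(wig, rec$bumps), center),
      noise_sd = 0, n_points = rec$n_points, seed = rec$seed
    )
    new_n <- compute_ninfl(curvature_profiles(make_contour(rec2)$contour))$ninfl_reported
    expect_equal(new_n, base_n)
  }
})

test_that("tongue_metrics joins metadata and flags exclusions", {
  mc1 <- make_contour(random_bump_recipe(2, seed = 1), token_id = "t1")
  mc2 <- make_contour(random_bump_recipe(0, seed = 2), token_id = "t2")
  contours <- dplyr::bind_rows(mc1$contour, mc2$contour)
  meta <- tibble::tibble(
    token_id = c("t1", "t2"), speaker_id = "s1", group = "SSD",
    age_months = 90, phoneme = c("r", "a"),
    accuracy = c("correct", "unlabeled"), repetition = 1L
  )
  met <- tongue_metrics(contours, meta)
  expect_equal(met$token_id, c("t1", "t2"))
  expect_equal(met$phoneme, c("r", "a"))
  expect_equal(met$ninfl_reported, c(2L, 1L))
  expect_false(any(met$excluded_ninfl))
})
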