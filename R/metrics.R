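#' Tongue-shape complexity metrics
#'
#' Two complementary statistics quantify the complexity of a midsagittal
#' tongue contour:
#'
#' * **NINFL** (number of inflections): the count of sign changes of the
#'   trimmed signed-curvature sequence, plus one. Curvature whose osculating
#'   radius exceeds `trim_factor * L` (i.e. nearly-straight stretches) is
#'   treated as zero, inflections in the first and last `edge_fraction` of
#'   the contour are disregarded, and (optionally) retroflex points where the
#'   contour doubles back are trimmed. The +1 offset reflects the convention
#'   that a contour always carries at least one curve, so a count of zero
#'   sign changes is reported as 1.
#' * **MCI** (modified curvature index): the integral of unsigned curvature
#'   over normalised arc length, i.e. the total absolute turning angle in
#'   radians. A straight line scores 0, a semicircle scores pi, and the value
#'   is invariant to uniform scaling.
#'
#' Token-exclusion convention: reported NINFL over 5 removes a token from
#' both analyses; among the remainder, MCI over 6 removes it from the MCI
#' analysis only.
#'
#' @name complexity_metrics
NULL

# --- single-profile computations ------------------------------------------

#' Number of inflections of one curvature profile
#'
#' @param profile A single-token curvature profile (rows of `s`, `kappa`,
#'   `retroflex` as produced by [curvature_profiles()]).
#' @param trim_factor Osculating radii larger than `trim_factor * L` count as
#'   straight (default 0.3); on the normalised curvature scale the threshold
#'   is `1 / trim_factor`.
#' @param edge_fraction Sign changes located in the first or last
#'   `edge_fraction` of arc length are disregarded (default 0.05).
#' @param retroflex_trim Zero out curvature at retroflex points where the
#'   tangent reverses against the dominant travel direction (default FALSE;
#'   enable for real retroflex-prone data).
#' @param literal_trim Use the literal reading of the trim rule (trim where
#'   the radius is *smaller* than `trim_factor * L`, i.e. keep only gentle
#'   curvature). Default FALSE: the conventional reading trims gentle
#'   curvature and keeps substantive inflections.
#' @return A list with integer components `ninfl_raw` (sign-change count)
#'   and `ninfl_reported` (`ninfl_raw + 1`).
#' @export
compute_ninfl <- function(profile, trim_factor = 0.3, edge_fraction = 0.05,
                          retroflex_trim = FALSE, literal_trim = FALSE) {
  if (trim_factor <= 0) abort("`trim_factor` must be positive.", class = "tsc_parameter_error")
  if (edge_fraction < 0 || edge_fraction >= 0.5) {
    abort("`edge_fraction` must be in [0, 0.5).", class = "tsc_parameter_error")
  }
  k <- profile$kappa
  s <- profile$s
  thr <- 1 / trim_factor
  z <- if (literal_trim) ifelse(abs(k) > thr, 0, k) else ifelse(abs(k) < thr, 0, k)
  if (retroflex_trim && !is.null(profile$retroflex)) z[profile$retroflex] <- 0
  nz <- which(z != 0)
  raw <- 0L
  if (length(nz) > 1) {
    sgn <- sign(z[nz])
    flips <- which(sgn[-1] != sgn[-length(sgn)])
    if (length(flips)) {
      # a sign change is located between the last surviving point of the
      # old sign and the first of the new sign; it is disregarded when
      # either flank falls in the edge zone, so endpoint estimation
      # artifacts cannot masquerade as interior inflections
      s_a <- s[nz[flips]]
      s_b <- s[nz[flips + 1]]
      raw <- sum(s_a >= edge_fraction & s_b <= 1 - edge_fraction)
    }
  }
  list(ninfl_raw = as.integer(raw), ninfl_reported = as.integer(raw) + 1L)
}

#' Modified curvature index of one curvature profile
#'
#' Trapezoidal integral of `|kappa|` (normalised scale) over s in \[0, 1\];
#' equals the total absolute turning angle in radians. No trimming is
#' applied.
#'
#' @inheritParams compute_ninfl
#' @return A single non-negative number.
#' @export
compute_mci <- function(profile) {
  s <- profile$s
  if (length(s) < 2) abort("Profile needs at least 2 points.", class = "tsc_geometry_error")
  ds <- diff(s)
  if (max(ds) - min(ds) > 1e-6 * mean(ds)) {
    abort("Profile samples are not equidistant.", class = "tsc_geometry_error")
  }
  a <- abs(profile$kappa)
  sum((a[-1] + a[-length(a)]) / 2 * ds)
}

# --- cohort-level wrappers ------------------------------------------------

#' Compute complexity records for a set of contours
#'
#' Runs the full metric stage: resample to equidistant points, smooth,
#' compute signed curvature, count inflections, integrate unsigned
#' curvature, and flag exclusions.
#'
#' @param contours Data frame of contour points (`token_id`, `point`, `x`,
#'   `y`), e.g. from [read_contours()] or [make_contour()].
#' @param metadata Optional data frame of token metadata keyed by
#'   `token_id` (columns `speaker_id`, `group`, `age_months`, `phoneme`,
#'   `accuracy`, `repetition`); joined onto the result.
#' @inheritParams curvature_profiles
#' @inheritParams compute_ninfl
#' @param ninfl_cap Reported NINFL above this excludes the token from both
#'   analyses (default 5).
#' @param mci_cap MCI above this excludes the token from the MCI analysis
#'   (default 6).
#' @return A tibble with one row per token: metadata (if supplied),
#'   `ninfl_raw`, `ninfl_reported`, `mci`, `excluded_ninfl`, `excluded_mci`.
#' @export
tongue_metrics <- function(contours, metadata = NULL, n_points = 100, window = 6,
                           method = c("derivative", "circumcircle"),
                           smooth_first = FALSE,
                           trim_factor = 0.3, edge_fraction = 0.05,
                           retroflex_trim = FALSE, literal_trim = FALSE,
                           ninfl_cap = 5, mci_cap = 6) {
  method <- match.arg(method)
  profiles <- curvature_profiles(contours,
    n_points = n_points, window = window,
    method = method, smooth_first = smooth_first, trim_factor = trim_factor
  )
  recs <- profiles |>
    group_by(.data$token_id) |>
    group_modify(function(p, key) {
      nf <- compute_ninfl(p,
        trim_factor = trim_factor, edge_fraction = edge_fraction,
        retroflex_trim = retroflex_trim, literal_trim = literal_trim
      )
      tibble(
        ninfl_raw = nf$ninfl_raw,
        ninfl_reported = nf$ninfl_reported,
        mci = compute_mci(p)
      )
    }) |>
    ungroup()
  # restore input token order (group_by sorts)
  recs <- recs[match(unique(contours$token_id), recs$token_id), ]
  recs <- flag_exclusions(recs, ninfl_cap = ninfl_cap, mci_cap = mci_cap)
  if (!is.null(metadata)) {
    meta_cols <- setdiff(names(metadata), "token_id")
    recs <- left_join(recs, as_tibble(metadata), by = "token_id") |>
      relocate(dplyr::all_of(meta_cols), .after = "token_id")
  }
  as_tibble(recs)
}

flag_exclusions <- function(records, ninfl_cap = 5, mci_cap = 6) {
  records |>
    mutate(
      excluded_ninfl = .data$ninfl_reported > ninfl_cap,
      excluded_mci = .data$excluded_ninfl | .data$mci > mci_cap
    )
}

#' Apply the token-exclusion rules
#'
#' Tokens with reported NINFL over `ninfl_cap` are removed from both
#' analyses; among the remainder, tokens with MCI over `mci_cap` are removed
#' from the MCI analysis only (flagged, retained in the returned table).
#'
#' @param records Tibble of complexity records (as from [tongue_metrics()])
#'   with columns `ninfl_reported` and `mci`.
#' @inheritParams tongue_metrics
#' @return A list: `records` (all rows, exclusion flags set), `kept` (rows
#'   retained for the NINFL analysis; those additionally flagged
#'   `excluded_mci` drop out of the MCI analysis), `n_excluded_ninfl`,
#'   `n_excluded_mci`.
#' @export
apply_exclusions <- function(records, ninfl_cap = 5, mci_cap = 6) {
  if (nrow(records) == 0) {
    return(list(
      records = records, kept = records,
      n_excluded_ninfl = 0L, n_excluded_mci = 0L
    ))
  }
  records <- flag_exclusions(records, ninfl_cap = ninfl_cap, mci_cap = mci_cap)
  kept <- filter(records, !.data$excluded_ninfl)
  list(
    records = records,
    kept = kept,
    n_excluded_ninfl = sum(records$excluded_ninfl),
    n_excluded_mci = sum(kept$excluded_mci)
  )
}
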