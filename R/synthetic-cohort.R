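#' Synthetic cohorts from the generative mixed-model structure
#'
#' `simulate_cohort()` draws a cohort of speakers and tokens directly from
#' the statistical models used in the analysis stage, so that the model
#' fitters can be verified by parameter recovery:
#'
#' * MCI: `mci = X beta + Z b + e`, truncated at 0, with by-speaker random
#'   intercept and independent phoneme-contrast slopes and Gaussian
#'   residual.
#' * NINFL: a cumulative-logit latent model, `y = 1 + #(thresholds < eta +
#'   logistic noise)`, confined to 1..5 by construction.
#' * Accuracy: consonant tokens are labelled correct/error from a
#'   per-phoneme, age-dependent logistic error-probability curve; the
#'   reference vowel /a/ stays unlabeled.
#'
#' Defaults mirror the unbalanced cross-sectional design the package
#' targets: 29 typically-developing (TD) speakers with one repetition per
#' phoneme and 30 speakers with speech sound disorder (SSD) with ten, ages
#' spanning 5;0-12;11 (60-155 months), and fixed-effect magnitudes at the
#' scale of published group-comparison fits.
#'
#' @name synthetic_cohort
NULL

# fixed-effect defaults on the MCI scale (group-comparison term order:
# age, diag, ph x5, age:diag, diag:ph x5, age:ph x5)
.beta_mci_default <- c(
  intercept = 3.52, age_c = -0.01, diag = -0.01,
  ph_l = 0.11, ph_r = 0.54, ph_sh = 0.52, ph_s = -0.42, ph_t = -0.62,
  `age_c:diag` = -0.01,
  `diag:ph_l` = -0.32, `diag:ph_r` = -0.08, `diag:ph_sh` = -0.26,
  `diag:ph_s` = -0.02, `diag:ph_t` = 0.26,
  `age_c:ph_l` = 0.01, `age_c:ph_r` = 0.01, `age_c:ph_sh` = -0.01,
  `age_c:ph_s` = 0, `age_c:ph_t` = 0
)

# ordinal latent-scale defaults (same term order, no intercept; thresholds
# separate)
.beta_ord_default <- c(
  age_c = 0, diag = -0.44,
  ph_l = 0.78, ph_r = 2.36, ph_sh = 0.04, ph_s = -1.53, ph_t = -1.60,
  `age_c:diag` = 0.01,
  `diag:ph_l` = -0.94, `diag:ph_r` = -0.89, `diag:ph_sh` = 0.29,
  `diag:ph_s` = 0.83, `diag:ph_t` = 0.58,
  `age_c:ph_l` = -0.02, `age_c:ph_r` = 0, `age_c:ph_sh` = 0,
  `age_c:ph_s` = 0, `age_c:ph_t` = 0
)

#' Specify a synthetic cohort
#'
#' @param n_td,n_ssd Speakers per group (defaults 29 and 30).
#' @param reps_td,reps_ssd Repetitions per phoneme (defaults 1 and 10; the
#'   TD single-repetition imbalance is part of the stated design).
#' @param age_range_td,age_range_ssd Age ranges in months (68-154 and
#'   60-155).
#' @param beta_mci Named fixed-effect vector on the MCI scale, including
#'   `intercept` (defaults at published group-comparison magnitudes).
#' @param beta_ordinal Named fixed-effect vector on the ordinal latent
#'   scale (no intercept).
#' @param thresholds Ordered latent thresholds for the five NINFL levels
#'   (default `c(-2.5, -0.5, 1, 2.5)`, giving a realistic distribution
#'   concentrated at 1-3 for the reference vowel).
#' @param sd_intercept_mci,sd_slope_mci,sd_resid_mci Random-intercept,
#'   phoneme-slope, and residual SDs on the MCI scale.
#' @param sd_intercept_ord,sd_slope_ord Random-effect SDs on the latent
#'   scale.
#' @param error_intercepts Named per-phoneme logit of error probability for
#'   an SSD speaker at the age midpoint (consonants only).
#' @param error_age_slope Change of the error logit per month of age.
#' @param error_prob_td Constant error probability for TD consonant tokens.
#' @param age_center Age (months) at which the generative age effects are
#'   anchored (default 108, the design midpoint).
#' @param seed Integer seed.
#' @return A `cohort_recipe` list.
#' @export
cohort_recipe <- function(n_td = 29, n_ssd = 30, reps_td = 1, reps_ssd = 10,
                          age_range_td = c(68, 154), age_range_ssd = c(60, 155),
                          beta_mci = .beta_mci_default,
                          beta_ordinal = .beta_ord_default,
                          thresholds = c(-2.5, -0.5, 1, 2.5),
                          sd_intercept_mci = 0.3, sd_slope_mci = 0.25,
                          sd_resid_mci = 0.5,
                          sd_intercept_ord = 0.8, sd_slope_ord = 0.5,
                          error_intercepts = c(l = -1, r = 0.5, sh = 0, s = 0, t = -1.5),
                          error_age_slope = -0.03, error_prob_td = 0.02,
                          age_center = 108, seed = 1) {
  stopifnot(
    all(diff(thresholds) > 0),
    sd_intercept_mci >= 0, sd_slope_mci >= 0, sd_resid_mci >= 0,
    sd_intercept_ord >= 0, sd_slope_ord >= 0,
    error_prob_td >= 0, error_prob_td <= 1
  )
  structure(as.list(environment()), class = "cohort_recipe")
}

#' Simulate a cohort dataset with metrics drawn from the generative models
#'
#' @param recipe A [cohort_recipe()].
#' @return A tibble with one row per token: `token_id`, `speaker_id`,
#'   `group`, `age_months`, `phoneme`, `accuracy`, `repetition`,
#'   `ninfl_reported`, `mci`, and exclusion flags. `ninfl_raw` is derived
#'   as `ninfl_reported - 1` for completeness.
#' @export
simulate_cohort <- function(recipe = cohort_recipe()) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  withr::with_seed(recipe$seed, {
    speakers <- tibble(
      speaker_id = c(
        sprintf("TD%02d", seq_len(recipe$n_td)),
        sprintf("SSD%02d", seq_len(recipe$n_ssd))
      ),
      group = rep(c("TD", "SSD"), c(recipe$n_td, recipe$n_ssd)),
      age_months = c(
        round(runif(recipe$n_td, recipe$age_range_td[1], recipe$age_range_td[2])),
        round(runif(recipe$n_ssd, recipe$age_range_ssd[1], recipe$age_range_ssd[2]))
      )
    )
    d <- speakers |>
      tidyr::crossing(phoneme = .phonemes) |>
      mutate(reps = ifelse(.data$group == "TD", recipe$reps_td, recipe$reps_ssd)) |>
      tidyr::uncount(.data$reps, .id = "repetition") |>
      mutate(token_id = paste(.data$speaker_id, .data$phoneme, .data$repetition, sep = "_"))
    n <- nrow(d)
    # design columns at the generative anchor age
    d$age_c <- d$age_months - recipe$age_center
    for (ph in .phonemes[-1]) {
      d[[paste0("ph_", ph)]] <- ifelse(d$phoneme == ph, 1, ifelse(d$phoneme == "a", -1, 0))
    }
    d$diag <- as.integer(d$group == "SSD")
    term_value <- function(tm) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      Reduce(`*`, lapply(parts, function(p) d[[p]]))
    }
    lin_pred <- function(beta) {
      terms <- setdiff(names(beta), "intercept")
      b0 <- if ("intercept" %in% names(beta)) beta[["intercept"]] else 0
      eta <- rep(b0, n)
      for (tm in terms) eta <- eta + beta[[tm]] * term_value(tm)
      eta
    }
    # by-speaker random effects: intercept + phoneme-contrast slopes
    ns <- nrow(speakers)
    ph_cols <- paste0("ph_", .phonemes[-1])
    re_draw <- function(sd_int, sd_slope) {
      b <- cbind(
        rnorm(ns, sd = sd_int),
        matrix(rnorm(ns * 5, sd = sd_slope), ns)
      )
      rownames(b) <- speakers$speaker_id
      b
    }
    Z <- cbind(1, as.matrix(d[, ph_cols]))
    b_mci <- re_draw(recipe$sd_intercept_mci, recipe$sd_slope_mci)
    b_ord <- re_draw(recipe$sd_intercept_ord, recipe$sd_slope_ord)
    re_mci <- rowSums(Z * b_mci[d$speaker_id, , drop = FALSE])
    re_ord <- rowSums(Z * b_ord[d$speaker_id, , drop = FALSE])
    d$mci <- pmax(
      lin_pred(recipe$beta_mci) + re_mci + rnorm(n, sd = recipe$sd_resid_mci),
      0
    )
    latent <- lin_pred(recipe$beta_ordinal) + re_ord + stats::rlogis(n)
    d$ninfl_reported <- 1L + rowSums(outer(latent, recipe$thresholds, `>`))
    d$ninfl_raw <- d$ninfl_reported - 1L
    # accuracy labels from the per-phoneme age-dependent error curve; the
    # reference vowel /a/ is judged too but essentially never in error
    logit_td <- qlogis(pmin(pmax(recipe$error_prob_td, 1e-6), 1 - 1e-6))
    logit_err <- ifelse(
      d$phoneme == "a",
      ifelse(d$group == "SSD", qlogis(0.02), logit_td),
      ifelse(
        d$group == "SSD",
        recipe$error_intercepts[d$phoneme] +
          recipe$error_age_slope * (d$age_months - recipe$age_center),
        logit_td
      )
    )
    d$accuracy <- ifelse(rbinom(n, 1, plogis(logit_err)) == 1, "error", "correct")
    d |>
      select(dplyr::all_of(c(
        "token_id", "speaker_id", "group", "age_months", "phoneme",
        "accuracy", "repetition", "ninfl_raw", "ninfl_reported", "mci"
      ))) |>
      flag_exclusions()
  })
}

#' Realise a simulated cohort as tongue contours
#'
#' Maps every token of a simulated cohort to a [contour_recipe()] whose
#' ground-truth complexity matches the token's generative `ninfl_reported`
#' and `mci`, so the full pipeline (contours -> metrics -> models) can be
#' exercised end to end. Construction: a reported NINFL of 1 becomes a
#' plain circular arc whose turning angle equals the target MCI; a reported
#' NINFL of n >= 2 becomes a shallow base arc carrying n alternating-sign
#' blocks of Gaussian bumps (one sign change per block boundary), with bump
#' count, width and sharpness chosen to approach the target MCI while each
#' bump's centre stays above and its side lobes below the inflection trim
#' threshold. Very high MCI targets saturate the bump budget, so the
#' achieved MCI compresses at the top; across tokens the achieved-vs-target
#' correlation stays above 0.9.
#'
#' @param cohort A cohort tibble from [simulate_cohort()] (or a
#'   `cohort_recipe`, which is simulated first).
#' @param noise_sd Coordinate jitter in mm (default 0.15, light tracking
#'   noise).
#' @param n_points Points per emitted contour.
#' @param seed Seed for the jitter (one stream per token, derived).
#' @return A list: `contours` (long tibble of points), `metadata` (token
#'   metadata incl. the targets as `target_ninfl`, `target_mci` and the
#'   analytic truth `truth_ninfl`, `truth_mci`).
#' @export
contour_cohort_bridge <- function(cohort, noise_sd = 0.15, n_points = 100,
                                  seed = 1) {
  if (inherits(cohort, "cohort_recipe")) cohort <- simulate_cohort(cohort)
  if (any(cohort$ninfl_reported > 5)) {
    abort("Target reported NINFL above 5 is not realisable by the bridge.",
      class = "tsc_recipe_error")
  }
  rows <- purrr::pmap(
    list(cohort$token_id, cohort$ninfl_reported, cohort$mci, seq_len(nrow(cohort))),
    function(id, n_target, m_target, i) {
      rec <- bridge_recipe(n_target, m_target,
        noise_sd = noise_sd,
        n_points = n_points, seed = seed * 10000 + i
      )
      mc <- make_contour(rec, token_id = id)
      list(
        contour = mc$contour,
        truth = tibble(
          token_id = id,
          truth_ninfl = mc$truth$ninfl_reported,
          truth_mci = mc$truth$analytic_mci
        )
      )
    }
  )
  contours <- purrr::map_dfr(rows, "contour")
  truth <- purrr::map_dfr(rows, "truth")
  metadata <- cohort |>
    rename(target_ninfl = "ninfl_reported", target_mci = "mci") |>
    select(-dplyr::any_of(c("ninfl_raw", "excluded_ninfl", "excluded_mci"))) |>
    left_join(truth, by = "token_id")
  list(contours = contours, metadata = metadata)
}

# chord + sagitta of a circular arc with turning angle theta
arc_base <- function(theta, chord_mm = 70) {
  R <- if (theta > pi) {
    chord_mm / (2 * sin((2 * pi - theta) / 2))
  } else {
    chord_mm / (2 * sin(theta / 2))
  }
  h <- if (theta > pi) R * (1 + cos((2 * pi - theta) / 2)) else R * (1 - cos(theta / 2))
  list(chord = chord_mm, bulge = h)
}

# Candidate bump configuration -> contour_recipe (noise-free by default).
# `n_sharp` supra-threshold alternating-sign bumps carry the inflection
# count; `n_wiggle` wide sub-threshold wiggles add unsigned-curvature mass
# (MCI) without entering the trimmed inflection count. Centres are packed
# left-to-right at the minimum legal spacing (1.5 x the wider neighbour).
bridge_config_recipe <- function(n_sharp, sharp_w, sharp_p, theta0,
                                 n_wiggle = 0, wig_w = 0.15, wig_p = 2.5,
                                 n_points = 100, chord_mm = 70,
                                 noise_sd = 0, seed = 1) {
  base <- arc_base(theta0, chord_mm)
  L0 <- chord_mm * theta0 / (2 * sin(theta0 / 2))
  if (n_sharp + n_wiggle == 0) {
    return(contour_recipe(
      chord_mm = base$chord, bulge_mm = base$bulge,
      noise_sd = noise_sd, n_points = n_points, seed = seed
    ))
  }
  widths <- c(rep(sharp_w, n_sharp), rep(wig_w, n_wiggle))
  peaks <- c(rep(sharp_p, n_sharp), rep(wig_p, n_wiggle))
  signs <- ifelse(seq_along(widths) %% 2 == 1, -1, 1)
  f <- length(widths)
  centers <- numeric(f)
  centers[1] <- 0.12
  if (f > 1) {
    for (i in 2:f) {
      centers[i] <- centers[i - 1] + 1.5 * max(widths[i - 1], widths[i]) + 0.005
    }
  }
  if (centers[f] > 0.88) return(NULL) # infeasible packing
  amp <- signs * peaks * widths^2 * L0 # peak normalised curvature ~ peaks
  contour_recipe(
    chord_mm = base$chord, bulge_mm = base$bulge,
    bumps = tibble(center = centers, amplitude = amp, width = widths),
    noise_sd = noise_sd, n_points = n_points, seed = seed
  )
}

# "Arch" family: a strongly curved supra-threshold base (the usual convex
# tongue arch) carrying `g` interior grooves -- each groove flips curvature
# sign at its centre and back, adding exactly two counted inflections --
# plus optionally one bump at the posterior end (centre 0.9) whose outer
# sign change falls inside the edge-excluded last 5% of the contour, adding
# exactly one. Reported NINFL = 1 + 2g + e; MCI is high because the arch
# itself carries most of the turning.
arch_config_recipe <- function(theta0, g, e, feat_p, feat_w, amp_sign,
                               n_points = 100, chord_mm = 70,
                               noise_sd = 0, seed = 1) {
  base <- arc_base(theta0, chord_mm)
  L0 <- chord_mm * theta0 / (2 * sin(min(theta0, pi) / 2))
  centers <- numeric(0)
  if (g == 1) centers <- 0.45
  if (g == 2) centers <- c(0.32, 0.58)
  widths <- rep(feat_w, length(centers))
  if (e == 1) {
    # the edge bump is wider so its outer sign change falls decisively
    # inside the edge-excluded last 5% of the contour
    centers <- c(centers, 0.9)
    widths <- c(widths, 0.10)
  }
  if (!length(centers)) {
    return(contour_recipe(
      chord_mm = base$chord, bulge_mm = base$bulge,
      noise_sd = noise_sd, n_points = n_points, seed = seed
    ))
  }
  amp <- amp_sign * feat_p * widths^2 * L0
  contour_recipe(
    chord_mm = base$chord, bulge_mm = base$bulge,
    bumps = tibble(center = centers, amplitude = amp, width = widths),
    noise_sd = noise_sd, n_points = n_points, seed = seed
  )
}

# robustness filter for a candidate configuration's analytic truth:
# the intended count must be realised with clear margins around the trim
# threshold (narrow features lose ~10-12% of peak curvature to the 6-point
# smoother, so they need more headroom than broad arches) and all counted
# sign changes must sit away from the 5% edge cut-off
bridge_config_ok <- function(tr, n, edge_fraction = 0.05) {
  if (tr$ninfl_reported != n) return(FALSE)
  if (tr$analytic_mci > 5.9) return(FALSE)
  if (nrow(tr$runs)) {
    req <- ifelse(tr$runs$s_end - tr$runs$s_start >= 0.12, 1.10, 1.30)
    if (any(tr$runs$peak_ratio < req)) return(FALSE)
  }
  if (!is.na(tr$margin_lo) && tr$margin_lo > 0.86) return(FALSE)
  cs <- tr$crossings_s
  ok_counted <- cs[tr$crossings_counted]
  ok_disc <- cs[!tr$crossings_counted]
  if (length(ok_counted) &&
    any(ok_counted < edge_fraction + 0.03 | ok_counted > 1 - edge_fraction - 0.03)) {
    return(FALSE)
  }
  if (length(ok_disc) &&
    any(ok_disc > edge_fraction - 0.01 & ok_disc < 1 - edge_fraction + 0.01)) {
    return(FALSE)
  }
  TRUE
}

# Self-validating configuration grid for the bridge: enumerate candidate
# configurations from both families (shallow base + alternating sharp bumps
# and wiggles; supra arch + grooves/edge bump), measure each one's
# *achieved* ground truth with the analytic oracle, and keep only
# configurations that realise the intended NINFL robustly. Mapping a token
# then reduces to a nearest-neighbour lookup in achieved MCI.
bridge_grid <- function(n_points = 100, chord_mm = 70, trim_factor = 0.3) {
  key <- paste(n_points, chord_mm, trim_factor, sep = "_")
  if (!is.null(.bridge_cache[[key]])) return(.bridge_cache[[key]])
  rows <- list()
  add <- function(rec, n, family, params) {
    if (is.null(rec)) return(invisible())
    tr <- make_contour(rec, trim_factor = trim_factor)$truth
    if (bridge_config_ok(tr, n)) {
      rows[[length(rows) + 1]] <<- tibble(
        n_target = n, family = family, truth_mci = tr$analytic_mci,
        params = list(params)
      )
    }
    invisible()
  }
  for (n in 2:5) {
    # family A: shallow base, alternating sharp bumps, optional wiggles
    for (sw in c(0.06, 0.08)) {
      for (sp in c(4.8, 5.4)) {
        for (th in c(0.3, 0.6)) {
          if (th + 0.446 * sp > 2.8) next
          for (nw in 0:3) {
            for (ww in c(0.12, 0.18)) {
              for (wp in c(1.6, 2.3)) {
                if (nw == 0 && (ww != 0.12 || wp != 1.6)) next
                p <- list(n_sharp = n, sharp_w = sw, sharp_p = sp, theta0 = th,
                  n_wiggle = nw, wig_w = ww, wig_p = wp)
                add(do.call(bridge_config_recipe,
                  c(p, list(n_points = n_points, chord_mm = chord_mm))),
                  n, "shallow", p)
              }
            }
          }
        }
      }
    }
    # family B: supra arch with grooves and/or an edge bump
    g <- (n - 1) %/% 2
    e <- (n - 1) %% 2
    for (th in c(3.6, 4.0, 4.4)) {
      for (fp in c(8.5, 9.5)) {
        for (fw in c(0.06, 0.08)) {
          for (sgn in c(-1, 1)) {
            p <- list(theta0 = th, g = g, e = e, feat_p = fp, feat_w = fw,
              amp_sign = sgn)
            add(do.call(arch_config_recipe,
              c(p, list(n_points = n_points, chord_mm = chord_mm))),
              n, "arch", p)
          }
        }
      }
    }
  }
  grid <- dplyr::bind_rows(rows)
  .bridge_cache[[key]] <- grid
  grid
}

.bridge_cache <- new.env(parent = emptyenv())

# one token's contour recipe for a (reported NINFL, MCI) target
bridge_recipe <- function(n_target, m_target, noise_sd = 0.15, n_points = 100,
                          seed = 1, chord_mm = 70, grid = NULL) {
  if (n_target < 1) abort("Target NINFL must be >= 1.", class = "tsc_recipe_error")
  if (n_target == 1) {
    # a plain arc: any turning angle, single curvature sign, reported 1
    theta <- min(max(m_target, 0.15), 5.8)
    base <- arc_base(theta, chord_mm)
    return(contour_recipe(
      chord_mm = base$chord, bulge_mm = base$bulge,
      noise_sd = noise_sd, n_points = n_points, seed = seed
    ))
  }
  if (is.null(grid)) grid <- bridge_grid(n_points = n_points, chord_mm = chord_mm)
  cand <- grid[grid$n_target == n_target, ]
  best <- cand[which.min(abs(cand$truth_mci - m_target)), ]
  builder <- if (best$family == "shallow") bridge_config_recipe else arch_config_recipe
  do.call(builder, c(best$params[[1]], list(
    n_points = n_points, chord_mm = chord_mm, noise_sd = noise_sd, seed = seed
  )))
}
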