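small_cohort <- function(seed = 2, n = 8, reps = 3) {
  simulate_cohort(cohort_recipe(n_td = n, n_ssd = n, reps_ssd = reps, seed = seed))
}

test_that("build_design produces the published term structure and codings", {
  co <- small_cohort()
  des <- build_design(co, "group_comparison", "ninfl")
  # 18 non-intercept predictors: age, diagnosis, 5 phoneme contrasts,
  # age:diagnosis, 5 diagnosis:phoneme, 5 age:phoneme
  expect_length(des$fixed_terms, 18)
  expect_length(term_labels(des), 18)
  expect_true("Diagnosis (TD vs. SSD)" %in% term_labels(des))
  expect_equal(sum(grepl("^Age: phoneme|^Age: Phoneme", term_labels(des), ignore.case = TRUE)), 5)

  d <- des$data
  # deviation coding: /a/ rows get -1 in every contrast, /l/ rows +1 in
  # ph_l and 0 elsewhere; columns sum to zero across the six levels
  arow <- d[d$phoneme == "a", ][1, ]
  lrow <- d[d$phoneme == "l", ][1, ]
  ph_cols <- paste0("ph_", c("l", "r", "sh", "s", "t"))
  expect_equal(unlist(arow[ph_cols]), setNames(rep(-1, 5), ph_cols))
  expect_equal(unname(unlist(lrow[ph_cols])), c(1, 0, 0, 0, 0))
  one_each <- dplyr::distinct(d, phoneme, .keep_all = TRUE)
  expect_equal(colSums(one_each[, ph_cols]), setNames(rep(0, 5), ph_cols))

  # centring on the analysis subset
  expect_lt(abs(mean(d$age_c)), 1e-10)

  # accuracy design: SSD labelled tokens only, error slope in the REs
  des_acc <- build_design(co, "accuracy_within_ssd", "mci")
  expect_true(all(des_acc$data$group == "SSD"))
  expect_true(all(des_acc$data$accuracy %in% c("correct", "error")))
  expect_length(des_acc$fixed_terms, 18)
  expect_true("err" %in% des_acc$re_slopes)

  # a missing phoneme level is a contrast error naming the level
  co_no_r <- dplyr::filter(co, phoneme != "r")
  err <- tryCatch(build_design(co_no_r, "group_comparison", "ninfl"),
    error = function(e) e)
  expect_s3_class(err, "tsc_contrast_error")
  expect_match(conditionMessage(err), "\\br\\b")

  # exclusion flags gate the rows that enter each model
  co2 <- co
  co2$excluded_ninfl <- FALSE
  co2$excluded_mci <- FALSE
  co2$excluded_ninfl[1:5] <- TRUE
  co2$excluded_mci[1:9] <- TRUE
  expect_equal(nrow(build_design(co2, "group_comparison", "ninfl")$data), nrow(co) - 5)
  expect_equal(nrow(build_design(co2, "group_comparison", "mci")$data), nrow(co) - 9)
})

test_that("linear mixed fit recovers generative fixed effects", {
  # moderate-size recovery check; the full 20-replicate coverage check
  # lives in the acceptance suite
  co <- simulate_cohort(cohort_recipe(n_td = 15, n_ssd = 15, reps_ssd = 5, seed = 11))
  des <- build_design(co, "group_comparison", "mci")
  fit <- fit_mci_model(des, ddf = "residual")
  est <- fit$coefficients
  truth <- c(`(Intercept)` = 3.52, ph_r = 0.54, ph_t = -0.62)
  for (tm in names(truth)) {
    row <- est[est$term == tm, ]
    expect_lt(abs(row$estimate - truth[[tm]]) / row$std.error, 2.5)
  }
  expect_true(fit$convergence$converged)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 19)
  expect_equal(nrow(model_report(fit)), 19)
  expect_true(all(tidy(fit, "ran_pars")$variance >= 0))
})

test_that("pure-noise outcomes give no spurious effects and order invariance holds", {
  rec <- cohort_recipe(
    n_td = 12, n_ssd = 12, reps_ssd = 4,
    beta_mci = c(intercept = 3), beta_ordinal = c(age_c = 0),
    sd_intercept_mci = 0, sd_slope_mci = 0, sd_resid_mci = 0.4,
    seed = 13
  )
  co <- simulate_cohort(rec)
  des <- build_design(co, "group_comparison", "mci")
  # zero generative random effects make the fit singular by design
  fit <- suppressWarnings(fit_mci_model(des, ddf = "residual"))
  expect_true(fit$convergence$singular)
  stats <- fit$coefficients$statistic[fit$coefficients$term != "(Intercept)"]
  expect_true(all(abs(stats) < 3))

  # permuting row order leaves the estimates unchanged
  co_perm <- withr::with_seed(1, co[sample(nrow(co)), ])
  fit_perm <- suppressWarnings(
    fit_mci_model(build_design(co_perm, "group_comparison", "mci"),
      ddf = "residual")
  )
  expect_equal(fit_perm$coefficients$estimate, fit$coefficients$estimate,
    tolerance = 1e-8)
})

test_that("Satterthwaite df are sensible and between-speaker terms get fewer", {
  co <- small_cohort(seed = 7, n = 10, reps = 4)
  des <- build_design(co, "group_comparison", "mci")
  fit <- fit_mci_model(des, ddf = "satterthwaite")
  est <- fit$coefficients
  n <- fit$n_obs
  p <- nrow(est)
  expect_true(all(est$df >= 1 & est$df <= n - p))
  # diagnosis varies between speakers only: its df should be near the
  # speaker count, far below the token-level residual df
  df_diag <- est$df[est$term == "diag"]
  expect_lt(df_diag, 3 * fit$n_speakers)
  expect_lt(df_diag, (n - p) / 2)
})

test_that("the ordinal fitter matches independent no-random-effect oracles", {
  set.seed(42)
  n <- 150
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.5)
  y <- 1 + rowSums(outer(1.2 * x1 - 0.8 * x2 + rlogis(n), c(-1.5, 0, 1.5), `>`))
  X <- cbind(x1 = x1, x2 = x2)
  fit <- clmm_fit(y, X)
  # hand-written direct-ML oracle
  oracle <- oracle_ordered_logit(y, X)
  expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-4)
  expect_equal(unname(fit$alpha), oracle$alpha, tolerance = 1e-4)
  # independent library implementation agrees too
  pf <- MASS::polr(factor(y, ordered = TRUE) ~ x1 + x2, method = "logistic")
  expect_equal(unname(fit$beta), unname(coef(pf)), tolerance = 1e-3)

  # single observed level is a model error
  expect_error(clmm_fit(rep(2L, 20), matrix(rnorm(20))), class = "tsc_model_error")
})

test_that("binary-collapsed ordinal fit agrees with a logistic mixed fit", {
  set.seed(31)
  ng <- 24
  per <- 15
  g <- rep(seq_len(ng), each = per)
  b <- rnorm(ng, sd = 0.9)
  x <- rnorm(ng * per)
  y <- as.integer(plogis(0.5 + 1.3 * x + b[g]) > runif(ng * per)) + 1L
  fit <- clmm_fit(y, cbind(x = x), group = g, Z = matrix(1, ng * per, 1))
  gl <- lme4::glmer(I(y == 2) ~ x + (1 | g), family = stats::binomial())
  # cumulative-logit threshold = -logistic intercept; shared slope
  expect_equal(unname(fit$beta), unname(lme4::fixef(gl)["x"]), tolerance = 1e-3)
  expect_equal(unname(fit$alpha), -unname(lme4::fixef(gl)["(Intercept)"]),
    tolerance = 1e-3)
  expect_equal(unname(fit$re_sd),
    unname(attr(lme4::VarCorr(gl)$g, "stddev")), tolerance = 1e-3)
})

test_that("fit_ninfl_model returns the report structure and falls back cleanly", {
  co <- small_cohort(seed = 5)
  des <- build_design(co, "group_comparison", "ninfl")
  fit <- fit_ninfl_model(des, re = "intercept")
  expect_s3_class(fit, "tsc_clmm")
  expect_equal(nrow(fit$coefficients), 18)
  expect_true(all(diff(fit$thresholds$estimate) > 0))
  expect_true(all(tidy(fit, "ran_pars")$sd >= 0))
  expect_equal(nrow(model_report(fit)), 18)
  expect_true(glance(fit)$converged)
  # Wald p values correspond to the z statistics
  z <- fit$coefficients$statistic
  expect_equal(fit$coefficients$p.value, 2 * pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("Cohen's kappa matches hand-computed and degenerate cases", {
  expect_equal(kappa_agreement(c("a", "b", "a"), c("a", "b", "a")), 1)
  # hand-worked 2x2 example: 8/10 agreements so p_o = 0.8; margins are
  # 6c/4e for both raters so p_e = 0.6^2 + 0.4^2 = 0.52
  a <- c("c", "c", "e", "e", "c", "e", "c", "c", "e", "c")
  b <- c("c", "e", "e", "e", "c", "e", "c", "c", "c", "c")
  expect_equal(kappa_agreement(a, b), (0.8 - 0.52) / (1 - 0.52), tolerance = 1e-12)
  # chance-level agreement for independent labels
  lab <- withr::with_seed(8, list(
    a = sample(c("x", "y"), 10000, replace = TRUE),
    b = sample(c("x", "y"), 10000, replace = TRUE)
  ))
  expect_lt(abs(kappa_agreement(lab$a, lab$b)), 0.05)
  # both raters constant and identical
  expect_equal(kappa_agreement(rep("c", 5), rep("c", 5)), 1)
  expect_error(kappa_agreement(c("a", "b"), c("a")), "same length")
})

test_that("PCC counts correct consonant tokens per speaker", {
  d <- tibble::tibble(
    speaker_id = rep(c("s1", "s2", "s3"), c(50, 4, 3)),
    phoneme = c(
      rep(c("r", "s", "t", "l", "sh"), 8), rep("a", 10),
      "r", "r", "a", "a",
      rep("a", 3)
    ),
    accuracy = c(
      rep(c("correct", "error"), c(30, 10)), rep("unlabeled", 10),
      "correct", "correct", "unlabeled", "unlabeled",
      rep("unlabeled", 3)
    )
  )
  expect_warning(pcc <- percentage_consonants_correct(d), "omitted")
  expect_equal(pcc$pcc[pcc$speaker_id == "s1"], 75)
  expect_equal(pcc$pcc[pcc$speaker_id == "s2"], 100)
  expect_false("s3" %in% pcc$speaker_id)

  # recount oracle on a simulated cohort
  co <- small_cohort(seed = 3)
  pcc2 <- percentage_consonants_correct(co)
  check <- co |>
    dplyr::filter(phoneme != "a", accuracy != "unlabeled") |>
    dplyr::group_by(speaker_id) |>
    dplyr::summarise(pcc = 100 * mean(accuracy == "correct"))
  expect_equal(
    pcc2$pcc[order(pcc2$speaker_id)],
    check$pcc[order(check$speaker_id)]
  )
})

test_that("paired t test matches the closed form and handles degeneracies", {
  expect_equal(paired_t_test(1:5, 1:5)$statistic, 0)
  expect_equal(paired_t_test(1:5, 1:5)$p.value, 1)

  res <- paired_t_test(c(3, 5, 6, 8), c(1, 1, 2, 2))
  expect_equal(res$statistic, 4 / (sd(c(2, 4, 4, 6)) / 2), tolerance = 1e-12)
  expect_equal(res$statistic, sqrt(24), tolerance = 1e-6)
  expect_equal(res$df, 3)
  tt <- t.test(c(3, 5, 6, 8), c(1, 1, 2, 2), paired = TRUE)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p.value, tt$p.value, tolerance = 1e-12)

  deg <- paired_t_test(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_equal(deg$statistic, Inf)
  expect_true(deg$degenerate)
  expect_equal(deg$p.value, 0)
})
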