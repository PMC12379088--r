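#' Linear mixed model for the MCI analyses
#'
#' Fits the MCI outcome by REML (via lme4) with the design's fixed effects
#' and by-speaker random intercept plus independent random slopes for the
#' phoneme contrasts (and the error contrast in the accuracy design).
#' t statistics use Satterthwaite-approximated denominator degrees of
#' freedom, computed from the non-profiled REML criterion over the variance
#' parameters (theta, sigma): the df for a coefficient with variance
#' `f = Var(beta_k)` is `2 f^2 / (g' A g)`, where `g` is the gradient of `f`
#' in the variance parameters and `A` their asymptotic covariance
#' (2 x inverse Hessian of the REML deviance). If that Hessian is not
#' invertible (e.g. a variance on the boundary), residual df are used with
#' a warning.
#'
#' @param design A `tsc_design` with a linear (`mci`) outcome from
#'   [build_design()].
#' @param re Random-effect structure: `"slopes"` (intercept + independent
#'   slopes, default), `"intercept"`, or `"none"` (plain least squares,
#'   mainly for diagnostics).
#' @param ddf Denominator-df method: `"satterthwaite"` (default) or
#'   `"residual"` (n - p, much faster; used in simulation loops).
#' @return An object of class `tsc_lmm`: list with the `lme4` fit, a
#'   `coefficients` tibble (term, label, estimate, std.error, df, statistic,
#'   p.value), `random_effects` (variance/SD table), `sigma`, `n_obs`,
#'   `n_speakers`, and `convergence` diagnostics. Singular or non-converged
#'   fits are returned with diagnostics set and a warning, never silently.
#' @export
fit_mci_model <- function(design, re = c("slopes", "intercept", "none"),
                          ddf = c("satterthwaite", "residual")) {
  re <- match.arg(re)
  ddf <- match.arg(ddf)
  stopifnot(inherits(design, "tsc_design"), design$outcome_kind == "linear")
  d <- design$data
  d$.y <- d[[design$outcome]]
  fixed <- paste(design$fixed_terms, collapse = " + ")
  re_term <- switch(re,
    slopes = paste0(" + (1 + ", paste(design$re_slopes, collapse = " + "), " || speaker_id)"),
    intercept = " + (1 | speaker_id)",
    none = NULL
  )
  if (re == "none") {
    fml <- stats::as.formula(paste0(".y ~ ", fixed))
    fit <- stats::lm(fml, data = d)
    sm <- summary(fit)$coefficients
    coefs <- tibble(
      term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
      df = fit$df.residual, statistic = sm[, 3], p.value = sm[, 4]
    )
    coefs$label <- label_map(design)[coefs$term]
    return(structure(list(
      fit = fit, coefficients = coefs, random_effects = NULL,
      sigma = summary(fit)$sigma, n_obs = nrow(d),
      n_speakers = dplyr::n_distinct(d$speaker_id),
      convergence = list(converged = TRUE, singular = FALSE, messages = character()),
      model_kind = "linear_fixed", design = design[c("analysis", "outcome")]
    ), class = "tsc_lmm"))
  }
  fml <- stats::as.formula(paste0(".y ~ ", fixed, re_term))
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = d, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  singular <- lme4::isSingular(fit, tol = 1e-5)
  conv_ok <- length(fit@optinfo$conv$lme4) == 0
  if (singular) warn("Linear mixed fit is singular (a random-effect variance is ~0).")
  if (!conv_ok) warn(paste0(
    "Linear mixed fit did not fully converge: ",
    paste(unlist(fit@optinfo$conv$lme4), collapse = "; ")
  ))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n <- nrow(d)
  p <- length(beta)
  df_res <- n - p
  df_out <- rep(df_res, p)
  if (ddf == "satterthwaite") {
    df_sat <- tryCatch(satterthwaite_df(fit), error = function(e) NULL)
    if (is.null(df_sat)) {
      warn("Satterthwaite df unavailable (boundary fit?); using residual df.")
    } else {
      df_out <- pmin(pmax(df_sat, 1), df_res)
    }
  }
  t_stat <- beta / se
  coefs <- tibble(
    term = names(beta), estimate = unname(beta), std.error = unname(se),
    df = unname(df_out), statistic = unname(t_stat),
    p.value = 2 * pt(-abs(unname(t_stat)), df = unname(df_out))
  )
  coefs$label <- label_map(design)[coefs$term]
  vc <- as.data.frame(lme4::VarCorr(fit))
  re_tab <- tibble(
    group = vc$grp, term = ifelse(is.na(vc$var1), "Residual", vc$var1),
    variance = vc$vcov, sd = vc$sdcor
  )
  structure(list(
    fit = fit, coefficients = coefs, random_effects = re_tab,
    sigma = stats::sigma(fit), n_obs = n,
    n_speakers = dplyr::n_distinct(d$speaker_id),
    convergence = list(converged = conv_ok, singular = singular, messages = msgs),
    model_kind = "linear_mixed", design = design[c("analysis", "outcome")]
  ), class = "tsc_lmm")
}

# term -> human-readable label, including the intercept (lme4 may drop
# rank-deficient columns in small subsets, so labels are matched by name)
label_map <- function(design) {
  c(`(Intercept)` = "(Intercept)",
    stats::setNames(term_labels(design), design$fixed_terms))
}

# Satterthwaite denominator df for every fixed effect of an lmerMod,
# via the non-profiled REML criterion in (theta, sigma).
satterthwaite_df <- function(fit) {
  devfun <- update(fit, devFunOnly = TRUE)
  env <- environment(devfun)
  n <- nrow(env$pp$X)
  p <- ncol(env$pp$X)
  reml <- lme4::isREML(fit)
  nmp <- if (reml) n - p else n
  dev_vp <- function(vp) {
    m <- length(vp)
    theta <- vp[-m]
    sg2 <- vp[m]^2
    devfun(theta) # updates pp/resp as a side effect
    pwrss <- env$resp$wrss() + env$pp$sqrL(1)
    ld <- env$pp$ldL2() + if (reml) env$pp$ldRX2() else 0
    ld + nmp * log(2 * pi * sg2) + pwrss / sg2
  }
  vcov_diag_vp <- function(vp) {
    m <- length(vp)
    devfun(vp[-m])
    vp[m]^2 * diag(as.matrix(env$pp$unsc()))
  }
  vp_hat <- c(lme4::getME(fit, "theta"), stats::sigma(fit))
  m <- length(vp_hat)
  h <- 1e-4 * pmax(abs(vp_hat), 1)
  # Hessian of the deviance by central differences
  H <- matrix(0, m, m)
  f0 <- dev_vp(vp_hat)
  for (j in seq_len(m)) {
    for (k in j:m) {
      if (j == k) {
        fp <- dev_vp(vp_hat + h * (seq_len(m) == j))
        fm <- dev_vp(vp_hat - h * (seq_len(m) == j))
        H[j, j] <- (fp - 2 * f0 + fm) / h[j]^2
      } else {
        ej <- h * (seq_len(m) == j)
        ek <- h * (seq_len(m) == k)
        H[j, k] <- H[k, j] <-
          (dev_vp(vp_hat + ej + ek) - dev_vp(vp_hat + ej - ek) -
            dev_vp(vp_hat - ej + ek) + dev_vp(vp_hat - ej - ek)) /
            (4 * h[j] * h[k])
      }
    }
  }
  A <- 2 * solve(H) # asymptotic covariance of the variance parameters
  # gradient of each Var(beta_k) in the variance parameters
  G <- matrix(0, m, p)
  for (j in seq_len(m)) {
    ej <- h * (seq_len(m) == j)
    G[j, ] <- (vcov_diag_vp(vp_hat + ej) - vcov_diag_vp(vp_hat - ej)) / (2 * h[j])
  }
  f <- vcov_diag_vp(vp_hat)
  devfun(vp_hat[-m]) # restore the fitted state
  denom <- colSums(G * (A %*% G))
  df <- 2 * f^2 / denom
  if (any(!is.finite(df)) || any(df <= 0)) stop("Satterthwaite df not finite")
  df
}
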