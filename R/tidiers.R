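#' Broom-style tidiers for fitted complexity models
#'
#' `tidy()` returns the fixed-effect table (one row per predictor, with the
#' human-readable label of the report layout); `glance()` returns one-row
#' model-level summaries.
#'
#' @param x A `tsc_lmm` or `tsc_clmm` fit.
#' @param effects `"fixed"` (default), `"ran_pars"` (random-effect SDs), or
#'   for ordinal fits `"thresholds"`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy tsc_lmm
#' @export
tidy.tsc_lmm <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    return(select(x$coefficients, dplyr::all_of(c(
      "term", "label", "estimate", "std.error", "df", "statistic", "p.value"
    ))))
  }
  if (is.null(x$random_effects)) {
    return(tibble(group = character(), term = character(),
      variance = numeric(), sd = numeric()))
  }
  x$random_effects
}

#' @rdname tidiers
#' @method tidy tsc_clmm
#' @export
tidy.tsc_clmm <- function(x, effects = c("fixed", "ran_pars", "thresholds"), ...) {
  effects <- match.arg(effects)
  switch(effects,
    fixed = select(x$coefficients, dplyr::all_of(c(
      "term", "label", "estimate", "std.error", "statistic", "p.value"
    ))),
    thresholds = x$thresholds,
    ran_pars = x$random_effects %||% tibble(
      group = character(), term = character(),
      sd = numeric(), variance = numeric()
    )
  )
}

#' @rdname tidiers
#' @method glance tsc_lmm
#' @export
glance.tsc_lmm <- function(x, ...) {
  tibble(
    n_obs = x$n_obs, n_speakers = x$n_speakers, sigma = x$sigma,
    converged = x$convergence$converged, singular = isTRUE(x$convergence$singular),
    model_kind = x$model_kind
  )
}

#' @rdname tidiers
#' @method glance tsc_clmm
#' @export
glance.tsc_clmm <- function(x, ...) {
  tibble(
    n_obs = x$n_obs, n_speakers = x$n_speakers, logLik = x$logLik,
    converged = x$convergence$converged,
    fallback = isTRUE(x$convergence$fallback),
    model_kind = x$model_kind
  )
}

#' @export
print.tsc_lmm <- function(x, ...) {
  cat("<tsc_lmm> linear mixed model:", x$design$analysis, "/", x$design$outcome, "\n")
  cat("  n =", x$n_obs, "tokens,", x$n_speakers, "speakers; sigma =",
    signif(x$sigma, 4), "\n")
  print(as.data.frame(x$coefficients[, c("label", "estimate", "std.error",
    "df", "statistic", "p.value")]), digits = 3)
  invisible(x)
}

#' @export
print.tsc_clmm <- function(x, ...) {
  cat("<tsc_clmm> cumulative-link mixed model:", x$design$analysis, "/",
    x$design$outcome, "\n")
  cat("  n =", x$n_obs, "tokens,", x$n_speakers, "speakers; logLik =",
    signif(x$logLik, 6), "\n")
  print(as.data.frame(x$coefficients[, c("label", "estimate", "std.error",
    "statistic", "p.value")]), digits = 3)
  cat("  thresholds:", paste(signif(x$thresholds$estimate, 4), collapse = " "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
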