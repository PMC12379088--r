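#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement between two label sequences:
#' `kappa = (p_o - p_e) / (1 - p_e)`, with observed agreement `p_o` and
#' chance agreement `p_e` from the confusion-matrix margins. Used here to
#' check transcription reliability between two raters' correct/error
#' judgements.
#'
#' @param labels_a,labels_b Equal-length vectors of category labels.
#' @return Cohen's kappa. If both raters are constant and identical
#'   (`p_e = 1`), agreement is perfect and 1 is returned.
#' @export
kappa_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("`labels_a` and `labels_b` must have the same length.")
  }
  if (length(labels_a) < 2) abort("Need at least 2 paired labels.")
  levs <- union(unique(labels_a), unique(labels_b))
  a <- factor(labels_a, levels = levs)
  b <- factor(labels_b, levels = levs)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    return(if (p_o == 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Percentage consonants correct per speaker
#'
#' PCC is the percentage of a speaker's labelled *consonant* tokens
#' perceived as correct; /a/ (the reference vowel) and unlabeled tokens are
#' excluded from the denominator.
#'
#' @param data Cohort tibble with `speaker_id`, `phoneme`, `accuracy`.
#' @return A tibble `(speaker_id, n_consonants, n_correct, pcc)`; speakers
#'   with zero labelled consonant tokens are omitted with a warning.
#' @export
percentage_consonants_correct <- function(data) {
  labelled <- data |>
    filter(.data$phoneme != "a", .data$accuracy %in% c("correct", "error"))
  out <- labelled |>
    group_by(.data$speaker_id) |>
    summarise(
      n_consonants = dplyr::n(),
      n_correct = sum(.data$accuracy == "correct"),
      pcc = 100 * .data$n_correct / .data$n_consonants,
      .groups = "drop"
    )
  missing_speakers <- setdiff(unique(data$speaker_id), out$speaker_id)
  if (length(missing_speakers)) {
    warn(paste0(
      length(missing_speakers),
      " speaker(s) with no labelled consonant tokens omitted from PCC."
    ))
  }
  out
}

#' Paired two-tailed t test
#'
#' t statistic on the n paired differences with df = n - 1. Degenerate
#' inputs are reported rather than erroring: zero-variance differences give
#' `t = Inf` (sign of the mean) with p = 0 when the mean is nonzero, and
#' `t = 0`, p = 1 when the differences are all zero.
#'
#' @param x,y Equal-length numeric vectors paired by subject.
#' @return A tibble `(statistic, df, p.value, mean_diff, degenerate)`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  n <- length(x)
  if (n < 2) abort("Need at least 2 pairs.")
  d <- x - y
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) {
      return(tibble(statistic = 0, df = n - 1, p.value = 1, mean_diff = 0, degenerate = TRUE))
    }
    return(tibble(
      statistic = sign(m) * Inf, df = n - 1, p.value = 0,
      mean_diff = m, degenerate = TRUE
    ))
  }
  t_stat <- m / (s / sqrt(n))
  tibble(
    statistic = t_stat, df = n - 1,
    p.value = 2 * pt(-abs(t_stat), df = n - 1),
    mean_diff = m, degenerate = FALSE
  )
}
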