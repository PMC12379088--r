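#' Build a model design for the cohort analyses
#'
#' Constructs the analysis subset, the coding scheme, and the term list for
#' one of the two research designs:
#'
#' * `group_comparison`: all speakers; fixed effects are centred age,
#'   treatment-coded diagnosis (TD reference), five deviation-coded phoneme
#'   contrasts (/a/ reference), age:diagnosis, diagnosis:phoneme, and
#'   age:phoneme. No three-way interaction.
#' * `accuracy_within_ssd`: SSD speakers with labelled tokens only; fixed
#'   effects are centred age, treatment-coded error (correct reference), the
#'   phoneme contrasts, error:phoneme, age:error, and age:phoneme.
#'
#' Deviation coding is sum-to-zero with /a/ omitted: the row for /a/ gets -1
#' in every contrast column, each other phoneme gets +1 in its own column
#' and 0 elsewhere, so each contrast estimates that phoneme against the
#' grand mean. Age is centred on the mean of the analysis subset (after
#' exclusions), so the intercept stays interpretable per model.
#'
#' Random effects are by-speaker: an intercept plus slopes for the phoneme
#' contrasts, and additionally an error slope in the accuracy design.
#'
#' @param data Cohort tibble with metadata columns (`speaker_id`, `group`,
#'   `age_months`, `phoneme`, `accuracy`), the outcomes `ninfl_reported` and
#'   `mci`, and the exclusion flags `excluded_ninfl`, `excluded_mci`.
#' @param analysis `"group_comparison"` or `"accuracy_within_ssd"`.
#' @param outcome `"ninfl"` (ordinal, exclusion flag `excluded_ninfl`) or
#'   `"mci"` (linear, exclusion flag `excluded_mci`).
#' @return An object of class `tsc_design`: a list with the model frame
#'   (`data`), the outcome column name, the fixed-effect term names
#'   (`fixed_terms`, matching the report layout), the random-slope columns
#'   (`re_slopes`), and the analysis/outcome labels.
#' @export
build_design <- function(data, analysis = c("group_comparison", "accuracy_within_ssd"),
                         outcome = c("ninfl", "mci")) {
  analysis <- match.arg(analysis)
  outcome <- match.arg(outcome)
  d <- as_tibble(data)
  d <- if (outcome == "ninfl") filter(d, !.data$excluded_ninfl) else filter(d, !.data$excluded_mci)
  if (analysis == "accuracy_within_ssd") {
    d <- filter(d, .data$group == "SSD", .data$accuracy %in% c("correct", "error"))
  }
  present <- unique(d$phoneme)
  absent <- setdiff(.phonemes, present)
  if (length(absent)) {
    abort(paste0(
      "Phoneme level(s) absent from the analysis subset: ",
      paste(absent, collapse = ", "), "; deviation contrasts are undefined."
    ), class = "tsc_contrast_error")
  }
  d$age_c <- d$age_months - mean(d$age_months)
  # deviation coding, /a/ as omitted reference (-1 row)
  for (ph in .phonemes[-1]) {
    d[[paste0("ph_", ph)]] <- ifelse(d$phoneme == ph, 1, ifelse(d$phoneme == "a", -1, 0))
  }
  ph_cols <- paste0("ph_", .phonemes[-1])
  if (analysis == "group_comparison") {
    d$diag <- as.integer(d$group == "SSD") # treatment coded, TD reference
    main <- c("age_c", "diag", ph_cols)
    inter <- c("age_c:diag", paste0("diag:", ph_cols), paste0("age_c:", ph_cols))
    re_slopes <- ph_cols
  } else {
    d$err <- as.integer(d$accuracy == "error") # treatment coded, correct reference
    main <- c("age_c", "err", ph_cols)
    inter <- c(paste0("err:", ph_cols), "age_c:err", paste0("age_c:", ph_cols))
    re_slopes <- c(ph_cols, "err")
  }
  y <- if (outcome == "ninfl") "ninfl_reported" else "mci"
  structure(
    list(
      data = d,
      outcome = y,
      outcome_kind = if (outcome == "ninfl") "ordinal" else "linear",
      fixed_terms = c(main, inter),
      re_slopes = re_slopes,
      analysis = analysis
    ),
    class = "tsc_design"
  )
}

#' @export
print.tsc_design <- function(x, ...) {
  cat("<tsc_design> ", x$analysis, " / ", x$outcome, "\n", sep = "")
  cat("  n =", nrow(x$data), "tokens,", dplyr::n_distinct(x$data$speaker_id), "speakers\n")
  cat("  fixed terms:", paste(x$fixed_terms, collapse = ", "), "\n")
  cat("  random slopes (by speaker):", paste(x$re_slopes, collapse = ", "), "\n")
  invisible(x)
}

# expand "a:b" interaction labels into a numeric model matrix (no intercept)
design_matrix <- function(design) {
  d <- design$data
  cols <- lapply(design$fixed_terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, lapply(parts, function(p) d[[p]]))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- design$fixed_terms
  X
}

#' Human-readable predictor labels matching the report layout
#'
#' @param design A `tsc_design`.
#' @return Character vector of labels, same order as `fixed_terms`.
#' @export
term_labels <- function(design) {
  lab_one <- function(p) {
    if (p == "age_c") return("Age")
    if (p == "diag") return("Diagnosis (TD vs. SSD)")
    if (p == "err") return("Error (correct vs. error)")
    ph <- sub("^ph_", "", p)
    paste0("Phoneme /a/ vs. /", ph, "/")
  }
  vapply(design$fixed_terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    paste(vapply(parts, lab_one, character(1)), collapse = ": ")
  }, character(1), USE.NAMES = FALSE)
}
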