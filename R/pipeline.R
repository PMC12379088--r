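#' Pipeline configuration
#'
#' Collects every tunable of the metric and model stages with defaults at
#' the conventional values: trim factor 0.3, edge fraction 5%, 6-point
#' smoothing window, 100 equidistant samples, NINFL cap 5, MCI cap 6.
#'
#' @param contours Path to a contour file (see [read_contours()]) or a
#'   contour tibble. `NULL` to run from a synthetic recipe.
#' @param metadata Path to (or tibble of) token metadata.
#' @param recipe A [cohort_recipe()] used when `contours` is `NULL`; the
#'   cohort is simulated and realised as contours via
#'   [contour_cohort_bridge()].
#' @param dialect Contour file dialect, `"long"` or `"wide"`.
#' @param analyses Character vector of analyses to run, from
#'   `"group_ninfl"`, `"group_mci"`, `"accuracy_ninfl"`, `"accuracy_mci"`.
#' @param n_points,window,trim_factor,edge_fraction,retroflex_trim Metric
#'   parameters (see [tongue_metrics()]).
#' @param ninfl_cap,mci_cap Exclusion caps.
#' @param re Random-effect structure for both model stages (`"slopes"`,
#'   `"intercept"`, `"none"`).
#' @param ddf Denominator-df method for the linear models.
#' @param out_dir Output directory (created if missing). `NULL` to skip
#'   writing files.
#' @param seed Integer seed governing all randomness of a synthetic run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(contours = NULL, metadata = NULL,
                            recipe = cohort_recipe(),
                            dialect = "long",
                            analyses = c("group_ninfl", "group_mci",
                              "accuracy_ninfl", "accuracy_mci"),
                            n_points = 100, window = 6, trim_factor = 0.3,
                            edge_fraction = 0.05, retroflex_trim = FALSE,
                            ninfl_cap = 5, mci_cap = 6,
                            re = "slopes", ddf = "satterthwaite",
                            out_dir = NULL, seed = 1) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates contours -> curvature metrics -> exclusions -> mixed models
#' -> reports. With file inputs the contours and metadata are read from
#' disk; otherwise a synthetic cohort is simulated from the config's recipe
#' and realised as contours, so the pipeline always exercises the metric
#' stage. All requested artifacts are written under `out_dir`: the metrics
#' table (`metrics.csv`), one model report per analysis
#' (`report_<analysis>.csv`), and a machine-readable run summary
#' (`run_summary.json`) carrying the config echo, seed, exclusion counts
#' and convergence flags. Identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with `metrics`, `exclusions`, `models` (one
#'   fit per analysis), and `summary`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, paste0(...))
    inform(msg)
  }
  stage <- "input"
  result <- tryCatch({
    if (is.null(config$contours)) {
      say("simulating synthetic cohort (seed ", config$seed, ")")
      recipe <- config$recipe
      recipe$seed <- config$seed
      cohort <- simulate_cohort(recipe)
      bridged <- contour_cohort_bridge(cohort, seed = config$seed)
      contours <- bridged$contours
      metadata <- bridged$metadata |>
        select(dplyr::all_of(c(
          "token_id", "speaker_id", "group", "age_months",
          "phoneme", "accuracy", "repetition"
        )))
    } else {
      say("reading contours")
      contours <- if (is.character(config$contours)) {
        read_contours(config$contours, dialect = config$dialect)
      } else {
        as_tibble(config$contours)
      }
      metadata <- if (is.character(config$metadata)) {
        validate_metadata(read_delim_auto(config$metadata))
      } else if (!is.null(config$metadata)) {
        validate_metadata(config$metadata)
      } else {
        abort("Token metadata is required to fit the cohort models.")
      }
    }
    stage <- "metrics"
    say("computing complexity metrics for ", dplyr::n_distinct(contours$token_id), " tokens")
    metrics <- tongue_metrics(contours, metadata,
      n_points = config$n_points, window = config$window,
      trim_factor = config$trim_factor, edge_fraction = config$edge_fraction,
      retroflex_trim = config$retroflex_trim,
      ninfl_cap = config$ninfl_cap, mci_cap = config$mci_cap
    )
    stage <- "exclusions"
    excl <- apply_exclusions(metrics,
      ninfl_cap = config$ninfl_cap, mci_cap = config$mci_cap
    )
    say(
      "exclusions: ", excl$n_excluded_ninfl, " token(s) with NINFL > ",
      config$ninfl_cap, "; ", excl$n_excluded_mci, " further with MCI > ",
      config$mci_cap
    )
    stage <- "models"
    specs <- list(
      group_ninfl = c("group_comparison", "ninfl"),
      group_mci = c("group_comparison", "mci"),
      accuracy_ninfl = c("accuracy_within_ssd", "ninfl"),
      accuracy_mci = c("accuracy_within_ssd", "mci")
    )
    models <- list()
    for (an in config$analyses) {
      say("fitting ", an)
      des <- build_design(excl$records, analysis = specs[[an]][1], outcome = specs[[an]][2])
      models[[an]] <- if (specs[[an]][2] == "ninfl") {
        fit_ninfl_model(des, re = config$re)
      } else {
        fit_mci_model(des, re = config$re, ddf = config$ddf)
      }
    }
    summary <- list(
      package_version = as.character(utils::packageVersion("tonguecomplexity")),
      seed = config$seed,
      config = config[c(
        "n_points", "window", "trim_factor", "edge_fraction",
        "retroflex_trim", "ninfl_cap", "mci_cap", "re", "ddf", "analyses"
      )],
      n_tokens = nrow(metrics),
      n_speakers = dplyr::n_distinct(metrics$speaker_id),
      n_excluded_ninfl = excl$n_excluded_ninfl,
      n_excluded_mci = excl$n_excluded_mci,
      convergence = lapply(models, function(m) m$convergence)
    )
    if (!is.null(config$out_dir)) {
      stage <- "output"
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_metrics(metrics, file.path(config$out_dir, "metrics.csv"))
      for (an in names(models)) {
        readr::write_csv(
          model_report(models[[an]]),
          file.path(config$out_dir, paste0("report_", an, ".csv"))
        )
      }
      jsonlite::write_json(summary,
        file.path(config$out_dir, "run_summary.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA
      )
      writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
      say("artifacts written to ", config$out_dir)
    }
    list(metrics = metrics, exclusions = excl, models = models, summary = summary)
  }, error = function(e) {
    abort(
      paste0("Pipeline failed at stage '", stage, "': ", conditionMessage(e)),
      class = "tsc_pipeline_error", parent = e
    )
  })
  invisible(result)
}

#' Model report table in the standard layout
#'
#' One row per predictor: label, estimate, SE, df (linear models only),
#' test statistic, p value — the layout of published group-comparison
#' tables.
#'
#' @param fit A `tsc_lmm` or `tsc_clmm`.
#' @return A tibble.
#' @export
model_report <- function(fit) {
  co <- fit$coefficients
  if (inherits(fit, "tsc_lmm")) {
    tibble(
      predictor = co$label, estimate = co$estimate, se = co$std.error,
      df = co$df, statistic = co$statistic, p_value = co$p.value
    )
  } else {
    tibble(
      predictor = co$label, estimate = co$estimate, se = co$std.error,
      statistic = co$statistic, p_value = co$p.value
    )
  }
}
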