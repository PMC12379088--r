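#' Reading and writing contour and metric tables
#'
#' Tongue-spline exports vary by vendor; the package reads two simple
#' delimited dialects and leaves anything else to a user-supplied converter:
#'
#' * `"long"`: one row per contour point, columns `token_id`, `point`
#'   (ordering within token), `x`, `y` (mm).
#' * `"wide"`: one row per token, column `token_id` followed by paired
#'   coordinate columns `x1, y1, x2, y2, ...` (trailing NA pairs allowed for
#'   ragged point counts).
#'
#' Coordinates are taken as mm in an arbitrary origin and rotation — both
#' complexity metrics are invariant to rigid motion, so no registration is
#' performed. The canonical point order is anterior (tongue tip) first;
#' `flip = TRUE` reverses each contour on read.
#'
#' @name contour_io
NULL

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
}

#' Read tongue-spline contours from a delimited file
#'
#' @param path Path to a CSV (comma) or TSV/TXT (tab) file.
#' @param dialect `"long"` (one row per point) or `"wide"` (one row per
#'   token with `x1, y1, x2, y2, ...` columns).
#' @param metadata Optional path to (or data frame of) a sidecar metadata
#'   table keyed by `token_id`; validated with [validate_metadata()] and
#'   joined onto the contour points.
#' @param flip Reverse the point order of every contour on read (use when
#'   the export is posterior-first).
#' @param min_points Tokens with fewer points are skipped with a warning
#'   (default 10).
#' @return A tibble with columns `token_id`, `point`, `x`, `y` (plus
#'   metadata columns if supplied), in file order.
#' @export
read_contours <- function(path, dialect = c("long", "wide"), metadata = NULL,
                          flip = FALSE, min_points = 10) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- read_delim_auto(path)
  if (dialect == "long") {
    required <- c("token_id", "point", "x", "y")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols)) {
      abort(paste0(
        "Contour file is missing required column(s): ",
        paste(missing_cols, collapse = ", ")
      ), class = "tsc_format_error")
    }
    long <- raw |>
      mutate(token_id = as.character(.data$token_id)) |>
      select(dplyr::all_of(required))
  } else {
    if (!"token_id" %in% names(raw)) {
      abort("Contour file is missing required column(s): token_id",
        class = "tsc_format_error")
    }
    xcols <- grep("^x[0-9]+$", names(raw), value = TRUE)
    ycols <- grep("^y[0-9]+$", names(raw), value = TRUE)
    if (!length(xcols) || length(xcols) != length(ycols)) {
      abort("Wide contour file needs paired x<i>/y<i> coordinate columns.",
        class = "tsc_format_error")
    }
    ord <- order(as.integer(sub("^x", "", xcols)))
    xcols <- xcols[ord]
    ycols <- paste0("y", sub("^x", "", xcols))
    long <- purrr::map_dfr(seq_len(nrow(raw)), function(i) {
      xs <- as.numeric(raw[i, xcols])
      ys <- as.numeric(raw[i, ycols])
      keep <- !(is.na(xs) | is.na(ys))
      tibble(
        token_id = as.character(raw$token_id[i]),
        point = seq_len(sum(keep)), x = xs[keep], y = ys[keep]
      )
    })
  }
  long <- long |>
    group_by(.data$token_id) |>
    arrange(.data$point, .by_group = TRUE) |>
    ungroup()
  # preserve file order of tokens
  long <- long[order(match(long$token_id, unique(long$token_id))), ]
  if (flip) {
    long <- long |>
      group_by(.data$token_id) |>
      mutate(x = rev(.data$x), y = rev(.data$y)) |>
      ungroup()
  }
  # drop exact consecutive duplicate points
  long <- long |>
    group_by(.data$token_id) |>
    filter(.data$point == min(.data$point) |
      abs(.data$x - lag(.data$x)) + abs(.data$y - lag(.data$y)) > 0) |>
    mutate(point = dplyr::row_number()) |>
    ungroup()
  counts <- count(long, .data$token_id)
  short <- counts$token_id[counts$n < min_points]
  if (length(short)) {
    warn(paste0(
      "Skipping ", length(short), " token(s) with fewer than ", min_points,
      " points: ", paste(short, collapse = ", ")
    ))
    long <- filter(long, !.data$token_id %in% short)
  }
  if (!is.null(metadata)) {
    if (is.character(metadata)) metadata <- read_delim_auto(metadata)
    metadata <- validate_metadata(metadata)
    long <- left_join(long, metadata, by = "token_id")
  }
  long
}

#' Validate a token metadata table
#'
#' Checks the closed phoneme set (`a l r sh s t`), the group labels
#' (`TD`/`SSD`), plausibility of age in months (warning outside 48–200), and
#' fills `accuracy` with `"unlabeled"` where absent.
#'
#' @param metadata Data frame with columns `token_id`, `speaker_id`,
#'   `group`, `age_months`, `phoneme`, and optionally `accuracy`,
#'   `repetition`.
#' @return The validated tibble.
#' @export
validate_metadata <- function(metadata) {
  metadata <- as_tibble(metadata)
  required <- c("token_id", "speaker_id", "group", "age_months", "phoneme")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    abort(paste0(
      "Metadata is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "tsc_format_error")
  }
  bad_ph <- setdiff(unique(metadata$phoneme), .phonemes)
  if (length(bad_ph)) {
    abort(paste0(
      "Unknown phoneme symbol(s): ", paste(bad_ph, collapse = ", "),
      " (expected one of ", paste(.phonemes, collapse = ", "), ")"
    ), class = "tsc_format_error")
  }
  bad_gr <- setdiff(unique(metadata$group), .groups)
  if (length(bad_gr)) {
    abort(paste0("Unknown group label(s): ", paste(bad_gr, collapse = ", ")),
      class = "tsc_format_error")
  }
  if (any(metadata$age_months < 48 | metadata$age_months > 200)) {
    warn("Some `age_months` values fall outside the plausible child range [48, 200].")
  }
  if (!"accuracy" %in% names(metadata)) metadata$accuracy <- "unlabeled"
  metadata$accuracy[is.na(metadata$accuracy)] <- "unlabeled"
  bad_acc <- setdiff(unique(metadata$accuracy), .accuracy_levels)
  if (length(bad_acc)) {
    abort(paste0("Unknown accuracy label(s): ", paste(bad_acc, collapse = ", ")),
      class = "tsc_format_error")
  }
  if (!"repetition" %in% names(metadata)) metadata$repetition <- 1L
  metadata$token_id <- as.character(metadata$token_id)
  metadata
}

metric_columns <- c(
  "token_id", "speaker_id", "group", "age_months", "phoneme", "accuracy",
  "repetition", "ninfl_raw", "ninfl_reported", "mci",
  "excluded_ninfl", "excluded_mci"
)

#' Write a complexity-record table to CSV
#'
#' Column order is fixed and documented: token_id, speaker_id, group,
#' age_months, phoneme, accuracy, repetition, ninfl_raw, ninfl_reported,
#' mci, excluded_ninfl, excluded_mci. Excluded tokens are written with their
#' flags set, never dropped.
#'
#' @param records Non-empty tibble of complexity records.
#' @param path Output CSV path.
#' @export
write_metrics <- function(records, path) {
  if (nrow(records) == 0) abort("`records` must be non-empty.")
  cols <- intersect(metric_columns, names(records))
  readr::write_csv(select(records, dplyr::all_of(cols)), path)
  invisible(path)
}

#' Read a complexity-record table written by [write_metrics()]
#'
#' @param path CSV path.
#' @return A tibble of complexity records.
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out$token_id <- as.character(out$token_id)
  if ("speaker_id" %in% names(out)) out$speaker_id <- as.character(out$speaker_id)
  out
}

#' Write contours to a delimited file (long dialect)
#'
#' @param contours Tibble with `token_id`, `point`, `x`, `y`.
#' @param path Output CSV path.
#' @export
write_contours <- function(contours, path) {
  readr::write_csv(select(contours, dplyr::all_of(c("token_id", "point", "x", "y"))), path)
  invisible(path)
}
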