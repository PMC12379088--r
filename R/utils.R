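#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats approx plogis qlogis pnorm pt rnorm runif rbinom sd setNames
#' @importFrom utils head tail
NULL

# phoneme inventory: /a/ reference vowel plus the five lingual consonants
.phonemes <- c("a", "l", "r", "sh", "s", "t")
.groups <- c("TD", "SSD")
.accuracy_levels <- c("correct", "error", "unlabeled")

# split a long contour table into an ordered list of coordinate matrices,
# preserving first-appearance token order
split_contours <- function(contours) {
  stopifnot(all(c("token_id", "x", "y") %in% names(contours)))
  ids <- unique(contours$token_id)
  out <- lapply(ids, function(id) {
    d <- contours[contours$token_id == id, , drop = FALSE]
    if ("point" %in% names(d)) d <- d[order(d$point), , drop = FALSE]
    cbind(x = d$x, y = d$y)
  })
  setNames(out, ids)
}

bind_contours <- function(mats) {
  purrr::map2_dfr(mats, names(mats), function(m, id) {
    tibble(token_id = id, point = seq_len(nrow(m)), x = m[, 1], y = m[, 2])
  })
}

# cumulative arc length of a piecewise-linear curve
arc_lengths <- function(xy) {
  d <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  c(0, cumsum(d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
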