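#' Coral colony health categories
#'
#' The six ordered health categories used to score each colony in the field,
#' from fully healthy to dead, together with the integer severity weights
#' (0 for C1 up to 5 for C6) that enter the Bleaching Response Index.
#'
#' @return A tibble with one row per category and columns `code` (`"C1"` ..
#'   `"C6"`), `weight` (0..5), `label`, and `bleach_range` (the
#'   percent-of-colony-affected interval the category encodes).
#'
#' @details Categories C2 to C5 describe live colonies with increasing
#'   fractions of bleached tissue; C6 pools recently dead (turf- or
#'   microbially-covered) and long-dead (bare skeleton) colonies.
#'
#' @examples
#' health_categories()
#' @export
health_categories <- function() {
  tibble::tibble(
    code = paste0("C", 1:6),
    weight = 0:5,
    label = c("Healthy", "Low", "Medium", "High", "Extreme", "Dead"),
    bleach_range = c("<1%", "1-10%", "10-50%", "50-90%", ">90%", "dead")
  )
}

#' @rdname health_categories
#' @format NULL
#' @export
category_codes <- function() paste0("C", 1:6)

#' @rdname health_categories
#' @export
category_weights <- function() {
  stats::setNames(0:5, category_codes())
}

# codes for the "bleached" (live, any bleaching level) prevalence numerator
bleached_codes <- function() paste0("C", 2:5)

#' Normalise health-category labels to canonical codes
#'
#' Accepts canonical codes (`"C1"`..`"C6"`, any case), bare digits 1-6, and
#' the standard labels (`"Healthy"`, `"Low"`, `"Medium"`, `"High"`,
#' `"Extreme"`, `"Dead"`, any case). Idempotent: normalising an already
#' canonical vector is a no-op.
#'
#' @param x Character vector of category labels.
#' @return Character vector of canonical codes; unrecognised labels become
#'   `NA` (callers decide whether that is an error).
#' @export
normalize_category <- function(x) {
  x <- trimws(as.character(x))
  up <- toupper(x)
  out <- rep(NA_character_, length(x))
  codes <- category_codes()
  hit <- up %in% codes
  out[hit] <- up[hit]
  digit <- up %in% as.character(1:6)
  out[digit] <- paste0("C", up[digit])
  labs <- toupper(health_categories()$label)
  m <- match(up, labs)
  out[!is.na(m)] <- codes[m[!is.na(m)]]
  out
}
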