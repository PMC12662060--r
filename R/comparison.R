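#' Partition taxa into main genera and "Others"
#'
#' Ranks taxa by total abundance and names the smallest set of most-abundant
#' taxa whose cumulative share of all colonies strictly exceeds `coverage`;
#' the remaining, less-represented taxa are pooled as `"Others"`. A fixed
#' list of taxon names can override the automatic selection.
#'
#' @param dataset A [survey_dataset()].
#' @param coverage Target cumulative relative abundance (default 0.80).
#' @param fixed Optional character vector of taxa to name explicitly; all
#'   other taxa become `"Others"`.
#' @return A tibble with columns `genus`, `total_n`, `group` (the taxon name
#'   for named taxa, `"Others"` otherwise).
#' @export
main_genus_grouping <- function(dataset, coverage = 0.80, fixed = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  tot <- dataset$records |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(total_n = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total_n), .data$genus)
  if (nrow(tot) == 0) stop("dataset is empty", call. = FALSE)
  if (!is.null(fixed)) {
    fixed <- normalize_genus(fixed)
    tot$group <- ifelse(tot$genus %in% fixed, tot$genus, "Others")
    return(tot)
  }
  cum <- cumsum(tot$total_n) / sum(tot$total_n)
  # first index where the cumulative share strictly exceeds coverage
  k <- which(cum > coverage)[1]
  if (is.na(k)) k <- nrow(tot)
  tot$group <- ifelse(seq_len(nrow(tot)) <= k, tot$genus, "Others")
  tot
}

#' Per-unit relative abundance of a status within a genus group
#'
#' For one genus group and one status, computes per pairing unit (station by
#' default) and period the proportion of the group's colonies in that
#' status: bleached pools the live-bleaching categories C2-C5, dead is C6,
#' healthy is C1. Units where the group was not recorded in a period are
#' returned with `NA` (missing), not zero.
#'
#' @param dataset A [survey_dataset()].
#' @param taxa Character vector of taxon names forming the group.
#' @param status `"bleached"`, `"dead"` or `"healthy"`.
#' @param unit Pairing unit: `"station"` (default) or `"site"`.
#' @return A tibble with columns `unit`, `period`, `n_group`, `value`
#'   (proportion in `[0, 1]`, `NA` when the group is absent from the unit).
#' @export
station_relative_abundance <- function(dataset, taxa,
                                       status = c("bleached", "dead", "healthy"),
                                       unit = c("station", "site")) {
  status <- match.arg(status)
  unit <- match.arg(unit)
  stopifnot(inherits(dataset, "survey_dataset"))
  taxa <- normalize_genus(taxa)
  rec <- dataset$records[dataset$records$genus %in% taxa, ]
  if (nrow(rec) == 0) {
    stop("genus group absent from the dataset: ",
         paste(taxa, collapse = ", "), call. = FALSE)
  }
  status_codes <- switch(status,
                         bleached = bleached_codes(),
                         dead = "C6",
                         healthy = "C1")
  units <- unique(dataset$design$stations[[unit]])
  rec$unit <- rec[[unit]]
  obs <- rec |>
    dplyr::group_by(.data$unit, .data$period) |>
    dplyr::summarise(n_group = sum(.data$count),
                     n_status = sum(.data$count[.data$category %in% status_codes]),
                     .groups = "drop")
  grid <- expand.grid(unit = units, period = dataset$design$periods,
                      stringsAsFactors = FALSE)
  out <- dplyr::left_join(tibble::as_tibble(grid), obs,
                          by = c("unit", "period"))
  out$n_group[is.na(out$n_group)] <- 0L
  out$value <- ifelse(out$n_group > 0, out$n_status / out$n_group, NA_real_)
  out[, c("unit", "period", "n_group", "value")]
}

#' Matched-sample Student's t test
#'
#' Paired t test on per-unit values across the two periods, with the
#' difference taken as `y - x` (second period minus first), so a positive
#' statistic means higher values in the second period. Pairs with a missing
#' value on either side are dropped listwise. Degenerate differences are
#' handled explicitly: zero variance with zero mean gives `t = 0, p = 1`;
#' zero variance with nonzero mean gives a signed infinite statistic,
#' flagged.
#'
#' @param x,y Numeric vectors of per-unit values for period 1 and period 2.
#'   If named, pairs are matched by name; otherwise by position (equal
#'   lengths required).
#' @return A list of class `paired_t` with elements `t`, `df`, `p`,
#'   `n_pairs`, `n_dropped`, `infinite`.
#' @export
paired_t_test <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  } else if (length(x) != length(y)) {
    stop("unnamed samples must have equal length", call. = FALSE)
  }
  ok <- stats::complete.cases(x, y)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " incomplete pair(s) dropped")
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- y - x
  res <- list(n_pairs = n, n_dropped = n_dropped, df = n - 1L,
              infinite = FALSE)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      res$t <- 0; res$p <- 1
    } else {
      res$t <- sign(mean(d)) * Inf; res$p <- 0; res$infinite <- TRUE
    }
  } else {
    tt <- stats::t.test(y, x, paired = TRUE)
    res$t <- unname(tt$statistic)
    res$p <- tt$p.value
  }
  structure(res, class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("Matched-sample t test: t = %.3f, df = %d, p = %.4g (n = %d pairs)\n",
              x$t, x$df, x$p, x$n_pairs))
  invisible(x)
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Period comparison table for bleached and dead relative abundance
#'
#' For every main genus group (and "Others") and both statuses, runs the
#' matched-sample t test on the per-unit relative abundances between the two
#' survey periods (difference: second period minus first).
#'
#' @param dataset A [survey_dataset()].
#' @param groups Optional grouping as returned by [main_genus_grouping()];
#'   computed with defaults when omitted.
#' @param unit Pairing unit, `"station"` (default) or `"site"`.
#' @return A tibble with columns `genus_group`, `status`, `t`, `df`, `p`,
#'   `n_pairs`, `stars`. Groups with fewer than 2 complete pairs are
#'   returned with `NA` statistics.
#' @export
comparison_table <- function(dataset, groups = NULL,
                             unit = c("station", "site")) {
  unit <- match.arg(unit)
  if (is.null(groups)) groups <- main_genus_grouping(dataset)
  rows <- list()
  for (g in unique(groups$group)) {
    taxa <- groups$genus[groups$group == g]
    for (status in c("bleached", "dead")) {
      ra <- station_relative_abundance(dataset, taxa, status, unit)
      p1 <- dataset$design$periods[1]; p2 <- dataset$design$periods[2]
      x <- stats::setNames(ra$value[ra$period == p1], ra$unit[ra$period == p1])
      y <- stats::setNames(ra$value[ra$period == p2], ra$unit[ra$period == p2])
      res <- tryCatch(suppressMessages(paired_t_test(x, y)),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        genus_group = g, status = status,
        t = if (is.null(res)) NA_real_ else res$t,
        df = if (is.null(res)) NA_integer_ else res$df,
        p = if (is.null(res)) NA_real_ else res$p,
        n_pairs = if (is.null(res)) 0L else res$n_pairs
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$stars <- ifelse(is.na(out$p), "", significance_stars(out$p))
  out
}
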