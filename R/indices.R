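#' Category breakdown of a survey stratum
#'
#' Pools all colonies matching the given selectors and tabulates them over
#' the six health categories, as counts and percentages. An empty stratum is
#' a valid, flagged result (not an error), so downstream tables can
#' distinguish "not surveyed" from "all healthy".
#'
#' @param dataset A [survey_dataset()].
#' @param period,site,station,genus,quadrat Optional selectors; each may be a
#'   vector of values. Omitted selectors pool over that key.
#' @return A `category_breakdown`: list with `stratum` (the selectors used),
#'   `n_total`, `counts` (named length-6 integer), `percentages` (named
#'   length-6 numeric, `NA` when empty) and `empty` flag.
#' @export
category_breakdown <- function(dataset, period = NULL, site = NULL,
                               station = NULL, genus = NULL, quadrat = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  rec <- dataset$records
  sel <- list(period = period, site = site, station = station,
              genus = genus, quadrat = quadrat)
  if (!is.null(genus)) sel$genus <- normalize_genus(genus)
  for (key in names(sel)) {
    if (!is.null(sel[[key]])) rec <- rec[rec[[key]] %in% sel[[key]], ]
  }
  counts <- stats::setNames(integer(6), category_codes())
  tab <- tapply(rec$count, factor(rec$category, levels = category_codes()), sum)
  counts[!is.na(tab)] <- as.integer(tab[!is.na(tab)])
  n_total <- sum(counts)
  percentages <- if (n_total > 0) 100 * counts / n_total else
    stats::setNames(rep(NA_real_, 6), category_codes())
  structure(
    list(stratum = sel[!vapply(sel, is.null, logical(1))],
         n_total = n_total, counts = counts, percentages = percentages,
         empty = n_total == 0),
    class = "category_breakdown"
  )
}

#' @export
print.category_breakdown <- function(x, ...) {
  lab <- if (length(x$stratum))
    paste(names(x$stratum), vapply(x$stratum, paste, "", collapse = "/"),
          sep = "=", collapse = ", ") else "all colonies"
  cat("<category_breakdown> ", lab, ": n = ", x$n_total, "\n", sep = "")
  if (!x$empty) {
    print(round(rbind(count = x$counts, pct = x$percentages), 1))
  }
  invisible(x)
}

as_breakdown <- function(x) {
  if (inherits(x, "category_breakdown")) return(x)
  if (is.numeric(x) && length(x) == 6) {
    if (any(x < 0)) stop("category counts must be non-negative", call. = FALSE)
    counts <- stats::setNames(as.integer(round(x)), category_codes())
    n <- sum(counts)
    return(structure(list(
      stratum = list(), n_total = n, counts = counts,
      percentages = if (n > 0) 100 * counts / n else
        stats::setNames(rep(NA_real_, 6), category_codes()),
      empty = n == 0), class = "category_breakdown"))
  }
  stop("expected a category_breakdown or a length-6 count vector", call. = FALSE)
}

#' Bleaching Response Index (BRI)
#'
#' Weighted average of the category percentages with weights 0 (Healthy, C1)
#' through 5 (Dead, C6), divided by 5 so the index runs from 0 (all colonies
#' healthy) to 100 (all colonies dead):
#' `BRI = (0 P1 + 1 P2 + 2 P3 + 3 P4 + 4 P5 + 5 P6) / 5`
#' with `Pk` the percentage of colonies in category k. Higher values mean a
#' more severe bleaching response.
#'
#' @param breakdown A [category_breakdown()] or a length-6 count vector
#'   (C1..C6).
#' @return BRI on the 0-100 scale.
#' @export
bri <- function(breakdown) {
  b <- as_breakdown(breakdown)
  if (b$empty) stop("BRI is undefined for an empty stratum (no colonies)",
                    call. = FALSE)
  unname(sum(category_weights() * b$percentages) / 5)
}

#' Site-level BRI
#'
#' Pools all colonies of all genera recorded at a site in one period and
#' applies the BRI formula to the pooled category percentages. Because the
#' index is linear in the category shares, this equals the colony-weighted
#' mean of the genus-level BRIs.
#'
#' @param dataset A [survey_dataset()].
#' @param site Site name.
#' @param period Period label.
#' @return Site BRI on the 0-100 scale.
#' @export
site_bri <- function(dataset, site, period) {
  bri(category_breakdown(dataset, site = site, period = period))
}

#' Bleaching prevalence
#'
#' The percentage of recorded colonies showing live bleaching: categories C2
#' through C5. Dead colonies (C6) are excluded from the numerator but remain
#' in the denominator, matching the three-way Healthy / Bleached / Dead view
#' of colony status.
#'
#' @inheritParams bri
#' @return Prevalence in percent (0-100).
#' @export
prevalence <- function(breakdown) {
  b <- as_breakdown(breakdown)
  if (b$empty) stop("prevalence is undefined for an empty stratum", call. = FALSE)
  100 * sum(b$counts[bleached_codes()]) / b$n_total
}

#' Dead-colony share
#'
#' Percentage of colonies recorded as dead (C6).
#' @inheritParams bri
#' @return Dead share in percent (0-100).
#' @export
dead_share <- function(breakdown) {
  b <- as_breakdown(breakdown)
  if (b$empty) stop("dead share is undefined for an empty stratum", call. = FALSE)
  unname(100 * b$counts["C6"] / b$n_total)
}

#' Colony density over quadrats
#'
#' Mean and standard error of colonies per square metre across quadrats. The
#' denominator is the designed quadrat count for the selected stations
#' (quadrats in which no colony was recorded count as zeros), unless an
#' explicit list of surveyed quadrats overrides it.
#'
#' @param dataset A [survey_dataset()].
#' @param period Period label (required: quadrats are re-deployed each
#'   period).
#' @param site,station Optional selectors restricting the stratum.
#' @param surveyed_quadrats Optional integer overriding the number of
#'   quadrats actually surveyed in the stratum.
#' @return A list with `density` (colonies per m2), `se`, and `n_quadrats`.
#' @export
coral_density <- function(dataset, period, site = NULL, station = NULL,
                          surveyed_quadrats = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  rec <- dataset$records[dataset$records$period %in% period, ]
  des <- dataset$design$stations
  if (!is.null(site)) {
    rec <- rec[rec$site %in% site, ]
    des <- des[des$site %in% site, ]
  }
  if (!is.null(station)) {
    rec <- rec[rec$station %in% station, ]
    des <- des[des$station %in% station, ]
  }
  if (nrow(des) == 0) stop("no quadrats in the selected stratum", call. = FALSE)
  area <- des$area_m2[1]
  per_quadrat <- rec |>
    dplyr::group_by(.data$station, .data$quadrat) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop")
  n_quadrats <- if (!is.null(surveyed_quadrats)) surveyed_quadrats else
    sum(des$quadrats)
  if (n_quadrats <= 0) stop("no quadrats in the selected stratum", call. = FALSE)
  if (nrow(per_quadrat) > n_quadrats) n_quadrats <- nrow(per_quadrat)
  dens <- c(per_quadrat$n / area, rep(0, n_quadrats - nrow(per_quadrat)))
  list(density = mean(dens),
       se = if (n_quadrats > 1) stats::sd(dens) / sqrt(n_quadrats) else NA_real_,
       n_quadrats = n_quadrats)
}

#' Bleaching Susceptibility Index (BSI)
#'
#' Community-level susceptibility of a reef site in one period: each genus'
#' BRI is weighted by the genus' relative abundance `D_i` (in percent of all
#' colonies recorded at the site-period), summed over genera and divided by
#' the number of genera entering the sum:
#' `BSI = sum_i (BRI_i * D_i) / N`.
#' Taxa observed fewer than `min_n` times are excluded from the sum (minority
#' taxa with extreme BRIs would otherwise dominate the index) but still count
#' in the relative-abundance denominator.
#'
#' @param dataset A [survey_dataset()].
#' @param site Site name.
#' @param period Period label.
#' @param min_n Minimum colony count for a genus to enter the sum (default 5).
#' @param rel_abundance_scale `"percent"` (default) expresses `D_i` on the
#'   0-100 scale; `"fraction"` uses 0-1.
#' @return A list with `bsi` and `n_genera` (genera entering the sum).
#' @export
bsi <- function(dataset, site, period, min_n = 5,
                rel_abundance_scale = c("percent", "fraction")) {
  rel_abundance_scale <- match.arg(rel_abundance_scale)
  stopifnot(inherits(dataset, "survey_dataset"))
  rec <- dataset$records[dataset$records$site %in% site &
                           dataset$records$period %in% period, ]
  if (nrow(rec) == 0) stop("no colonies at this site-period", call. = FALSE)
  by_genus <- rec |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(n = sum(.data$count),
                     weighted = sum(.data$count *
                                      category_weights()[.data$category]),
                     .groups = "drop")
  total <- sum(by_genus$n)
  by_genus$bri <- 20 * by_genus$weighted / by_genus$n
  keep <- by_genus[by_genus$n >= min_n, ]
  if (nrow(keep) == 0) {
    stop("no genus reaches the minimum of ", min_n, " observations",
         call. = FALSE)
  }
  scale <- if (rel_abundance_scale == "percent") 100 else 1
  d_i <- scale * keep$n / total
  list(bsi = sum(keep$bri * d_i) / nrow(keep), n_genera = nrow(keep))
}

#' Change in dead-colony share between periods
#'
#' Signed percentage-point difference in the dead (C6) share of colonies
#' between the two survey periods: positive values mean more dead colonies
#' after the event than during it.
#'
#' @param dataset A [survey_dataset()].
#' @param site,station,genus Optional selectors restricting the stratum.
#' @param periods Ordered pair (reference, comparison); defaults to the
#'   design's period order, so the result is after minus during.
#' @return Percentage-point change (comparison minus reference).
#' @export
mortality_change <- function(dataset, site = NULL, station = NULL,
                             genus = NULL, periods = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (is.null(periods)) periods <- dataset$design$periods
  stopifnot(length(periods) == 2)
  shares <- vapply(periods, function(p) {
    b <- category_breakdown(dataset, period = p, site = site,
                            station = station, genus = genus)
    if (b$empty) stop("no colonies in period '", p, "' for this stratum",
                      call. = FALSE)
    dead_share(b)
  }, numeric(1))
  unname(shares[2] - shares[1])
}

#' Genus- and site-level summary tables
#'
#' Builds the two standard report tables. The genus table has one row per
#' taxon and period with the colony count `n` and the taxon BRI, ordered by
#' total abundance (descending). The site table has one row per site and
#' period with abundance, bleaching prevalence, site BRI, colony density with
#' standard error, BSI and the number of genera entering the BSI. Strata with
#' no colonies carry `NA` indices (surveyed-but-absent, not zero severity).
#'
#' @param dataset A [survey_dataset()].
#' @param min_n Minimum genus count for the BSI (default 5).
#' @return A list with tibbles `genus` and `site`.
#' @export
summary_tables <- function(dataset, min_n = 5) {
  stopifnot(inherits(dataset, "survey_dataset"))
  periods <- dataset$design$periods
  w <- category_weights()

  genus <- dataset$records |>
    dplyr::group_by(.data$genus, .data$period) |>
    dplyr::summarise(n = sum(.data$count),
                     bri = 20 * sum(.data$count * w[.data$category]) / sum(.data$count),
                     .groups = "drop") |>
    tidyr::complete(genus = unique(dataset$records$genus),
                    period = periods,
                    fill = list(n = 0L, bri = NA_real_)) |>
    dplyr::group_by(.data$genus) |>
    dplyr::mutate(total_n = sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$total_n), .data$genus,
                   match(.data$period, periods)) |>
    dplyr::select(!"total_n")

  sites <- unique(dataset$records$site)
  grid <- expand.grid(site = sites, period = periods,
                      stringsAsFactors = FALSE)
  site_rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$site[i]; p <- grid$period[i]
    b <- category_breakdown(dataset, site = s, period = p)
    d <- tryCatch(coral_density(dataset, period = p, site = s),
                  error = function(e) list(density = NA_real_, se = NA_real_))
    bs <- tryCatch(bsi(dataset, site = s, period = p, min_n = min_n),
                   error = function(e) list(bsi = NA_real_, n_genera = 0L))
    tibble::tibble(
      site = s, period = p, abundance = b$n_total,
      prevalence_pct = if (b$empty) NA_real_ else prevalence(b),
      bri = if (b$empty) NA_real_ else bri(b),
      density = d$density, density_se = d$se,
      bsi = bs$bsi, n_genera_bsi = bs$n_genera
    )
  })
  site <- dplyr::bind_rows(site_rows) |>
    dplyr::arrange(.data$site, match(.data$period, periods))

  list(genus = genus, site = site)
}
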