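#' Daily sea-surface-temperature series
#'
#' Validates a daily SST series for one location: one value per date, dates
#' strictly increasing, temperatures within the oceanographic sanity bounds
#' of -2 to 40 degrees C. Missing calendar days are allowed but flagged in a
#' `gap_before` column; thermal-stress accumulation requires a contiguous
#' series.
#'
#' @param dates Date vector (or coercible), daily resolution.
#' @param sst_c Numeric SST in degrees C, same length as `dates`.
#' @param location Location label.
#' @return A tibble with columns `location`, `date`, `sst_c`, `gap_before`,
#'   of class `sst_series`.
#' @export
sst_series <- function(dates, sst_c, location = "site") {
  dates <- as.Date(dates)
  if (length(dates) != length(sst_c)) {
    stop("`dates` and `sst_c` must have the same length", call. = FALSE)
  }
  if (length(dates) == 0) stop("empty SST series", call. = FALSE)
  if (anyNA(dates) || anyNA(sst_c)) stop("SST series contains NA", call. = FALSE)
  if (any(diff(dates) <= 0)) {
    stop("dates must be strictly increasing (one value per date)", call. = FALSE)
  }
  if (any(sst_c < -2 | sst_c > 40)) {
    stop("SST outside sanity bounds [-2, 40] degrees C", call. = FALSE)
  }
  out <- tibble::tibble(
    location = location, date = dates, sst_c = as.numeric(sst_c),
    gap_before = c(FALSE, diff(dates) > 1)
  )
  class(out) <- c("sst_series", class(out))
  out
}

#' Read daily SST series from delimited text
#'
#' Expects columns `location`, `date` (ISO-8601) and `sst_c`. Multiple
#' locations may share one file; a list of one series per location is
#' returned (a single series if only one location is present).
#'
#' @param path File path.
#' @return An `sst_series` tibble, or a named list of them.
#' @export
read_sst <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("location", "date", "sst_c"), names(raw))
  if (length(missing)) {
    stop("SST file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  series <- lapply(split(raw, raw$location), function(d) {
    d <- d[order(d$date), ]
    sst_series(d$date, d$sst_c, location = d$location[1])
  })
  if (length(series) == 1) series[[1]] else series
}

#' Monthly SST climatology and maximum monthly mean
#'
#' Averages the daily series by calendar month (pooling across years) and
#' takes the warmest of the twelve monthly means as the maximum monthly mean
#' (MMM), the baseline above which thermal-stress anomalies accumulate. The
#' series must cover every calendar month at least once.
#'
#' @param sst An [sst_series()].
#' @return A `climatology`: list with `location`, `monthly_means` (named
#'   length-12 numeric, Jan..Dec) and `mmm`.
#' @export
monthly_climatology <- function(sst) {
  stopifnot(inherits(sst, "sst_series"))
  mo <- as.integer(format(sst$date, "%m"))
  present <- sort(unique(mo))
  if (length(present) < 12) {
    miss <- setdiff(1:12, present)
    stop("SST series is missing calendar month(s): ",
         paste(month.name[miss], collapse = ", "), call. = FALSE)
  }
  means <- vapply(1:12, function(m) mean(sst$sst_c[mo == m]), numeric(1))
  names(means) <- month.abb
  structure(list(location = sst$location[1], monthly_means = means,
                 mmm = max(means)),
            class = "climatology")
}

#' Construct a climatology from a known baseline
#'
#' For use when the MMM comes from an external product rather than the
#' supplied SST history (e.g. a satellite climatology re-centred on a fixed
#' reference window).
#'
#' @param mmm Maximum monthly mean in degrees C.
#' @param monthly_means Optional named length-12 vector; defaults to `mmm`
#'   for every month.
#' @param location Location label.
#' @return A `climatology`.
#' @export
climatology <- function(mmm, monthly_means = NULL, location = "site") {
  if (is.null(monthly_means)) {
    monthly_means <- stats::setNames(rep(mmm, 12), month.abb)
  }
  stopifnot(length(monthly_means) == 12, max(monthly_means) <= mmm + 1e-9)
  structure(list(location = location,
                 monthly_means = stats::setNames(monthly_means, month.abb),
                 mmm = mmm),
            class = "climatology")
}

#' @export
print.climatology <- function(x, ...) {
  cat("<climatology> ", x$location, ": MMM = ",
      format(round(x$mmm, 2)), " C\n", sep = "")
  invisible(x)
}

#' HotSpot anomaly series
#'
#' Daily SST anomaly above the maximum monthly mean: `sst(t) - MMM`.
#' Negative anomalies are reported as such but never accumulate into degree
#' heating weeks.
#'
#' @param sst An [sst_series()].
#' @param clim A `climatology` (or a single numeric MMM).
#' @return A tibble with columns `location`, `date`, `hotspot_c`.
#' @export
hotspot_series <- function(sst, clim) {
  stopifnot(inherits(sst, "sst_series"))
  mmm <- if (inherits(clim, "climatology")) clim$mmm else as.numeric(clim)
  tibble::tibble(location = sst$location, date = sst$date,
                 hotspot_c = sst$sst_c - mmm)
}

#' Degree heating weeks (DHW)
#'
#' Accumulated thermal stress: the sum, over a trailing window of
#' `window_days` days (12 weeks by default), of the daily HotSpot anomalies
#' that reach at least `hotspot_floor` degrees C, each divided by 7 to
#' express the result in degree C-weeks. Values computed before a full
#' window of data is available are returned but flagged `partial`. An alert
#' classification accompanies each value (see [alert_level()]).
#'
#' @param sst An [sst_series()] with contiguous daily dates.
#' @param clim A `climatology` (or a single numeric MMM).
#' @param window_days Accumulation window in days (default 84 = 12 weeks).
#' @param hotspot_floor Minimum anomaly, in degrees C, for a day to
#'   contribute (default 1.0, the satellite-monitoring convention).
#' @param bleaching_threshold,mortality_threshold Alert thresholds in degree
#'   C-weeks (defaults 4 and 8).
#' @return A tibble with columns `location`, `date`, `sst_c`, `hotspot_c`,
#'   `dhw_cweeks`, `partial`, `alert`.
#' @export
dhw_series <- function(sst, clim, window_days = 84, hotspot_floor = 1.0,
                       bleaching_threshold = 4, mortality_threshold = 8) {
  stopifnot(inherits(sst, "sst_series"))
  if (!is.numeric(window_days) || length(window_days) != 1 || window_days <= 0) {
    stop("`window_days` must be a positive integer", call. = FALSE)
  }
  window_days <- as.integer(window_days)
  if (any(sst$gap_before)) {
    stop("DHW accumulation requires a contiguous daily series; ",
         "gaps present (see `gap_before`)", call. = FALSE)
  }
  hs <- hotspot_series(sst, clim)$hotspot_c
  contrib <- ifelse(hs >= hotspot_floor, hs / 7, 0)
  cs <- cumsum(contrib)
  n <- length(cs)
  lag <- c(rep(0, min(window_days, n)), cs[seq_len(max(0, n - window_days))])
  dhw <- cs - lag
  dhw <- pmax(dhw, 0)  # guard against floating-point dust
  out <- tibble::tibble(
    location = sst$location, date = sst$date, sst_c = sst$sst_c,
    hotspot_c = hs, dhw_cweeks = dhw,
    partial = seq_len(n) < window_days,
    alert = alert_level(dhw, bleaching_threshold, mortality_threshold)
  )
  class(out) <- c("dhw_series", class(out))
  out
}

#' Bleaching-risk alert classification
#'
#' Classifies DHW values against the standard thermal-stress thresholds:
#' below 4 degree C-weeks no widespread-bleaching alert, from 4 (inclusive)
#' widespread bleaching is expected, and from 8 (inclusive) widespread
#' bleaching-induced mortality is expected.
#'
#' @param dhw_value Numeric DHW value(s), in degree C-weeks, non-negative.
#' @param bleaching_threshold,mortality_threshold Thresholds in degree
#'   C-weeks (defaults 4 and 8).
#' @return Factor with levels `none`, `bleaching-risk`, `mortality-risk`.
#' @export
alert_level <- function(dhw_value, bleaching_threshold = 4,
                        mortality_threshold = 8) {
  if (any(is.na(dhw_value)) || any(dhw_value < 0)) {
    stop("DHW values must be non-negative", call. = FALSE)
  }
  lev <- c("none", "bleaching-risk", "mortality-risk")
  idx <- 1L + (dhw_value >= bleaching_threshold) + (dhw_value >= mortality_threshold)
  factor(lev[idx], levels = lev)
}
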