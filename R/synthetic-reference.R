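#' Synthetic category counts matching summary statistics
#'
#' Constructs a length-6 vector of colony counts over the health categories
#' (C1..C6) whose colony total, BRI, bleaching prevalence and dead share
#' match given summary values as closely as integer counts allow. This is a
#' synthetic stand-in generator: when only published summary statistics of a
#' survey are available (total N, BRI, prevalence, dead share) and not the
#' colony-level records, it produces one concrete colony table consistent
#' with those summaries, against which the index computations can be
#' exercised end to end.
#'
#' Integer granularity limits exactness: with weights 0..5, the BRI of n
#' colonies can only take values `20 * S / n` for integer weighted sums `S`,
#' so a printed one-decimal BRI is matched to the nearest attainable value
#' (within `10/n` index units).
#'
#' @param n Total colony count (positive integer).
#' @param bri Target BRI (0-100), or `NULL` to leave unconstrained.
#' @param prevalence_pct Target live-bleaching prevalence in percent, or
#'   `NULL` for the minimum compatible with `bri`.
#' @param dead_pct Target dead share in percent, or `NULL` for the minimum
#'   compatible with `bri` and the prevalence.
#' @return Named integer vector of six category counts summing to `n`.
#' @export
synthetic_category_counts <- function(n, bri = NULL, prevalence_pct = NULL,
                                      dead_pct = NULL) {
  n <- as.integer(n)
  stopifnot(n > 0)
  s_target <- if (is.null(bri)) NULL else as.integer(round(bri * n / 20))
  n_bl <- if (is.null(prevalence_pct)) NULL else
    as.integer(round(prevalence_pct * n / 100))
  n_dead <- if (is.null(dead_pct)) NULL else
    as.integer(round(dead_pct * n / 100))

  if (is.null(n_dead)) {
    # minimum dead count making the weighted sum reachable: bleached colonies
    # carry weight at most 4, dead colonies weight 5
    n_dead <- 0L
    if (!is.null(s_target)) {
      cap <- if (is.null(n_bl)) 4L * n else 4L * n_bl
      if (s_target > cap) {
        per_dead <- if (is.null(n_bl)) 1L else 5L  # swap vs add
        n_dead <- as.integer(ceiling((s_target - cap) / per_dead))
      }
    }
  }
  if (is.null(n_bl)) {
    n_bl <- 0L
    if (!is.null(s_target)) {
      s_rem <- s_target - 5L * n_dead
      if (s_rem > 0) n_bl <- as.integer(ceiling(s_rem / 4))
    }
  }
  n_healthy <- n - n_bl - n_dead
  if (n_healthy < 0) {
    stop("summary statistics are inconsistent: bleached + dead exceed n",
         call. = FALSE)
  }
  counts <- stats::setNames(integer(6), category_codes())
  counts["C1"] <- n_healthy
  counts["C6"] <- n_dead
  if (is.null(s_target)) {
    counts["C2"] <- n_bl
    return(counts)
  }
  s_bleached <- s_target - 5L * n_dead
  if (s_bleached < n_bl || s_bleached > 4L * n_bl) {
    stop(sprintf(
      "target BRI %s is unreachable with %d bleached and %d dead of %d colonies",
      format(bri), n_bl, n_dead, n), call. = FALSE)
  }
  # start every bleached colony at C2 (weight 1), then promote: each move to
  # C5 adds 3 to the weighted sum, one residual colony takes the remainder
  extra <- s_bleached - n_bl
  n_c5 <- extra %/% 3L
  resid <- extra %% 3L
  counts["C5"] <- n_c5
  counts["C2"] <- n_bl - n_c5
  if (resid > 0) {
    counts["C2"] <- counts["C2"] - 1L
    counts[paste0("C", 2L + resid)] <- counts[paste0("C", 2L + resid)] + 1L
  }
  stopifnot(sum(counts) == n,
            sum(category_weights() * counts) == s_target)
  counts
}

#' Expand category counts into colony records
#'
#' Turns a six-category count vector into long-format records for one
#' stratum, spreading colonies round-robin over the design's quadrats so the
#' records form a plausible quadrat survey.
#'
#' @param counts Named length-6 count vector (C1..C6).
#' @param site,station,period Stratum labels.
#' @param n_quadrats Number of quadrats to spread colonies over (default 20).
#' @param genus Taxon label for the records.
#' @return A tibble of colony records (one row per colony, `count = 1`).
#' @export
counts_to_records <- function(counts, site, station, period,
                              n_quadrats = 20, genus = "Mixed") {
  counts <- as_breakdown(counts)$counts
  cat_vec <- rep(category_codes(), counts)
  n <- length(cat_vec)
  if (n == 0) {
    return(tibble::tibble(site = character(), station = character(),
                          period = character(), quadrat = character(),
                          genus = character(), category = character(),
                          count = integer()))
  }
  tibble::tibble(
    site = site, station = station, period = period,
    quadrat = sprintf("q%02d", (seq_len(n) - 1L) %% n_quadrats + 1L),
    genus = genus, category = cat_vec, count = 1L
  )
}
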