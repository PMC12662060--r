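#' Genus simulation profile
#'
#' Describes one taxon in the synthetic community: its expected share of the
#' community, the probabilities of the six health categories during the
#' bleaching event, and the per-colony transition probabilities between the
#' two survey periods (a bleached colony either recovers to Healthy, dies,
#' or retains its category; healthy and dead colonies persist).
#'
#' @param genus Taxon name.
#' @param rel_abundance Expected fraction of the community in `[0, 1]`.
#' @param category_probs_during Length-6 probability vector over C1..C6,
#'   summing to 1.
#' @param recovery_prob Probability that a bleached (C2-C5) colony is
#'   Healthy in the after-event survey.
#' @param death_prob Probability that a bleached colony is Dead in the
#'   after-event survey; `recovery_prob + death_prob <= 1`.
#' @return A `genus_profile` list.
#' @export
genus_profile <- function(genus, rel_abundance, category_probs_during,
                          recovery_prob = 0.7, death_prob = 0.05) {
  p <- as.numeric(category_probs_during)
  if (length(p) != 6 || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop("category_probs_during must be 6 non-negative values summing to 1",
         call. = FALSE)
  }
  if (recovery_prob < 0 || death_prob < 0 || recovery_prob + death_prob > 1) {
    stop("recovery_prob + death_prob must lie in [0, 1]", call. = FALSE)
  }
  structure(list(genus = normalize_genus(genus),
                 rel_abundance = rel_abundance,
                 category_probs_during = stats::setNames(p, category_codes()),
                 recovery_prob = recovery_prob, death_prob = death_prob),
            class = "genus_profile")
}

# after-event category distribution implied by the per-colony transitions
evolved_category_probs <- function(profile) {
  p <- profile$category_probs_during
  r <- profile$recovery_prob; d <- profile$death_prob
  bleached <- sum(p[2:5])
  out <- p
  out[1] <- p[1] + r * bleached
  out[2:5] <- p[2:5] * (1 - r - d)
  out[6] <- p[6] + d * bleached
  out
}

#' Expected BRI of a category distribution
#'
#' The BRI implied by a probability vector over the six categories:
#' `20 * sum(weight_k * p_k)`, identical to applying the index formula to
#' percentages `100 * p_k`. Useful for parameter-recovery checks on
#' simulated data.
#'
#' @param category_probs Length-6 probability vector summing to 1.
#' @return Expected BRI on the 0-100 scale.
#' @export
expected_bri <- function(category_probs) {
  p <- as.numeric(category_probs)
  if (length(p) != 6 || abs(sum(p) - 1) > 1e-6) {
    stop("category_probs must be 6 values summing to 1", call. = FALSE)
  }
  20 * sum(category_weights() * p)
}

#' Default synthetic community profiles
#'
#' An illustrative tropical reef community of nine named genera plus a
#' pooled "Others" group. Relative abundances loosely follow the rank
#' structure of a southwest-Madagascar assemblage (Acropora and Galaxea
#' dominant); thermally sensitive branching taxa (Acropora, Pocillopora,
#' Seriatopora, Stylophora) carry more bleaching mass than massive and
#' encrusting taxa. Not fitted to any dataset.
#'
#' @return A list of [genus_profile()] objects whose `rel_abundance` sum
#'   to 1.
#' @export
default_genus_profiles <- function() {
  spec <- list(
    #                 relab   C1    C2    C3    C4    C5    C6     rec   die
    Acropora       = c(0.25, 0.45, 0.12, 0.14, 0.10, 0.12, 0.07,  0.75, 0.08),
    Galaxea        = c(0.13, 0.82, 0.06, 0.05, 0.02, 0.01, 0.04,  0.80, 0.02),
    Pocillopora    = c(0.13, 0.35, 0.12, 0.16, 0.14, 0.15, 0.08,  0.70, 0.10),
    Stylophora     = c(0.05, 0.58, 0.10, 0.12, 0.08, 0.06, 0.06,  0.60, 0.12),
    Favites        = c(0.06, 0.80, 0.07, 0.05, 0.03, 0.02, 0.03,  0.80, 0.02),
    Echinopora     = c(0.04, 0.81, 0.07, 0.05, 0.03, 0.02, 0.02,  0.80, 0.02),
    Seriatopora    = c(0.03, 0.15, 0.10, 0.20, 0.22, 0.28, 0.05,  0.65, 0.10),
    `massive Porites` = c(0.04, 0.70, 0.10, 0.08, 0.05, 0.04, 0.03, 0.85, 0.02),
    Montipora      = c(0.04, 0.84, 0.06, 0.04, 0.02, 0.02, 0.02,  0.80, 0.02),
    Others         = c(0.23, 0.60, 0.09, 0.10, 0.07, 0.08, 0.06,  0.70, 0.08)
  )
  lapply(names(spec), function(g) {
    v <- spec[[g]]
    genus_profile(g, v[1], v[2:7], recovery_prob = v[8], death_prob = v[9])
  })
}

#' Default synthetic survey design
#'
#' Six reef sites with two stations each except the last (one station),
#' giving 11 stations, each with 20 quadrats of 1 m2 and two sampling
#' periods (during/after the event).
#' @return A [survey_design()].
#' @export
default_survey_design <- function() {
  survey_design(list(
    Beheloke = c("Ranolaly", "Tanifaly"),
    Besambay = c("Analisoa", "Kirinjo"),
    Ambola = c("Vavan'Ambola", "Manangatse"),
    Itampolo = c("Kapikara", "Mahadrano"),
    Lembehitake = c("Etsomotse", "Vatove"),
    Ambohibola = "Ambolafotsy"
  ))
}

#' Simulation configuration
#'
#' @param design A [survey_design()] (default: [default_survey_design()]).
#' @param genus_profiles List of [genus_profile()]s with `rel_abundance`
#'   summing to 1 (default: [default_genus_profiles()]).
#' @param quadrat_mean Expected colonies per 1 m2 quadrat (default 18).
#' @param quadrat_dispersion Negative-binomial dispersion (size) of the
#'   per-quadrat colony count (default 9.3; larger = closer to Poisson).
#' @param seed Random seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(design = default_survey_design(),
                              genus_profiles = default_genus_profiles(),
                              quadrat_mean = 18,
                              quadrat_dispersion = 9.3,
                              seed = 1L) {
  stopifnot(inherits(design, "survey_design"))
  relab <- vapply(genus_profiles, `[[`, numeric(1), "rel_abundance")
  if (abs(sum(relab) - 1) > 1e-6) {
    stop("genus relative abundances must sum to 1", call. = FALSE)
  }
  if (quadrat_mean <= 0 || quadrat_dispersion <= 0) {
    stop("quadrat_mean and quadrat_dispersion must be positive", call. = FALSE)
  }
  structure(list(design = design, genus_profiles = genus_profiles,
                 quadrat_mean = quadrat_mean,
                 quadrat_dispersion = quadrat_dispersion,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a two-period bleaching survey
#'
#' Draws, for each station, period and quadrat, a colony count from a
#' negative binomial with mean `quadrat_mean` and dispersion
#' `quadrat_dispersion`, then assigns each colony a genus (by relative
#' abundance) and a health category. During-event categories come from each
#' genus' `category_probs_during`; after-event surveys re-deploy fresh
#' quadrats and draw categories from the transition-evolved community
#' distribution (bleached colonies recover with `recovery_prob`, die with
#' `death_prob`, otherwise retain their category; healthy and dead persist).
#' Deterministic for a fixed `seed`.
#'
#' @param config A [simulation_config()].
#' @return A [survey_dataset()] covering both periods.
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  profiles <- config$genus_profiles
  genera <- vapply(profiles, `[[`, character(1), "genus")
  relab <- vapply(profiles, `[[`, numeric(1), "rel_abundance")
  probs <- list(
    during = t(vapply(profiles, `[[`, numeric(6), "category_probs_during")),
    after = t(vapply(profiles, evolved_category_probs, numeric(6)))
  )
  stations <- config$design$stations
  periods <- config$design$periods
  rows <- list()
  for (p_idx in 1:2) {
    period <- periods[p_idx]
    cat_probs <- probs[[p_idx]]
    # joint genus x category cell probabilities for this period
    joint <- relab * cat_probs
    cells <- expand.grid(g = seq_along(genera), k = 1:6)
    cell_prob <- joint[cbind(cells$g, cells$k)]
    for (s in seq_len(nrow(stations))) {
      nq <- stations$quadrats[s]
      n_col <- stats::rnbinom(nq, size = config$quadrat_dispersion,
                              mu = config$quadrat_mean)
      for (q in seq_len(nq)) {
        if (n_col[q] == 0) next
        draw <- stats::rmultinom(1, n_col[q], cell_prob)[, 1]
        nz <- which(draw > 0)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          site = stations$site[s], station = stations$station[s],
          period = period, quadrat = sprintf("q%02d", q),
          genus = genera[cells$g[nz]],
          category = category_codes()[cells$k[nz]],
          count = as.integer(draw[nz])
        )
      }
    }
  }
  survey_dataset(dplyr::bind_rows(rows), design = config$design)
}

#' Simulate a daily SST series
#'
#' A sinusoidal seasonal cycle around `baseline_mean` (warm peak in
#' mid-February, as in the southern hemisphere), plus additive warm-anomaly
#' events (trapezoidal: linear ramp up, plateau at `peak_c`, linear ramp
#' down) and Gaussian noise. Deterministic for a fixed `seed`.
#'
#' @param baseline_mean Annual mean SST in degrees C.
#' @param seasonal_amplitude Half-range of the seasonal cycle in degrees C.
#' @param anomaly_events List of events, each a list with `start` (date),
#'   `duration_days` (plateau length, >= 1), `peak_c` and optional
#'   `ramp_days` (default 0).
#' @param noise_sd Standard deviation of daily Gaussian noise in degrees C.
#' @param years Number of calendar years to generate (>= 1).
#' @param start_date First day of the series (default `"2023-01-01"`).
#' @param seed Random seed.
#' @param location Location label.
#' @return An [sst_series()].
#' @export
simulate_sst <- function(baseline_mean = 26, seasonal_amplitude = 2,
                         anomaly_events = list(), noise_sd = 0.1,
                         years = 1, start_date = "2023-01-01", seed = 1L,
                         location = "synthetic-reef") {
  if (years < 1) stop("`years` must be at least 1", call. = FALSE)
  start <- as.Date(start_date)
  end <- seq(start, by = paste(years, "years"), length.out = 2)[2] - 1
  dates <- seq(start, end, by = "day")
  doy <- as.integer(format(dates, "%j"))
  peak_doy <- 46  # mid-February warm peak
  sst <- baseline_mean +
    seasonal_amplitude * cos(2 * pi * (doy - peak_doy) / 365.25)
  for (ev in anomaly_events) {
    if (is.null(ev$start) || is.null(ev$duration_days) || is.null(ev$peak_c)) {
      stop("each anomaly event needs `start`, `duration_days`, `peak_c`",
           call. = FALSE)
    }
    if (ev$duration_days < 1) stop("event duration must be >= 1 day", call. = FALSE)
    ramp <- if (is.null(ev$ramp_days)) 0L else as.integer(ev$ramp_days)
    ev_start <- as.Date(ev$start)
    offset <- as.integer(dates - ev_start)  # 0 on the first plateau day
    shape <- rep(0, length(dates))
    shape[offset >= 0 & offset < ev$duration_days] <- 1
    if (ramp > 0) {
      up <- offset < 0 & offset >= -ramp
      shape[up] <- 1 + offset[up] / ramp
      down <- offset >= ev$duration_days & offset < ev$duration_days + ramp
      shape[down] <- 1 - (offset[down] - ev$duration_days + 1) / ramp
    }
    sst <- sst + ev$peak_c * shape
  }
  if (noise_sd > 0) {
    set.seed(seed)
    sst <- sst + stats::rnorm(length(dates), 0, noise_sd)
  }
  sst_series(dates, sst, location = location)
}
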