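# shared fixtures, all generated in code

# the 3-record toy survey used across io/index tests
toy_records <- function() {
  tibble::tibble(
    site = "Ambola", station = "Manangatse", period = "during",
    quadrat = "q1",
    genus = c("Acropora", "Acropora", "Pocillopora"),
    category = c("C1", "C5", "C3"),
    count = c(4L, 1L, 2L)
  )
}

toy_dataset <- function() survey_dataset(toy_records())

# a random valid dataset for property tests (fixed seed per call site)
random_dataset <- function(n_sites = 3, n_genera = 5, quadrat_mean = 10,
                           seed = 42) {
  stations <- stats::setNames(
    lapply(seq_len(n_sites), function(i) paste0("st", i, c("a", "b"))),
    paste0("site", seq_len(n_sites)))
  profiles <- local({
    set.seed(seed)
    relab <- as.numeric(stats::rgamma(n_genera, 2))
    relab <- relab / sum(relab)
    lapply(seq_len(n_genera), function(i) {
      p <- as.numeric(stats::rgamma(6, 1)) + 0.01
      genus_profile(paste0("Genus", i), relab[i], p / sum(p),
                    recovery_prob = stats::runif(1, 0.4, 0.8),
                    death_prob = stats::runif(1, 0, 0.15))
    })
  })
  simulate_survey(simulation_config(
    design = survey_design(stations, quadrats_per_station = 5),
    genus_profiles = profiles, quadrat_mean = quadrat_mean,
    quadrat_dispersion = 5, seed = seed))
}

write_toy_csv <- function(path, rows) {
  writeLines(c("site,station,period,quadrat,genus,category,count", rows), path)
  path
}
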