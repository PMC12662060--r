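test_that("category breakdowns tabulate counts and percentages", {
  b <- category_breakdown(toy_dataset(), period = "during")
  expect_equal(unname(b$counts), c(4L, 0L, 2L, 0L, 1L, 0L))
  expect_equal(b$n_total, 7)
  expect_equal(sum(b$percentages), 100)

  expect_equal(bri(c(10, 5, 5, 0, 0, 0)), 15)  # (0*50 + 1*25 + 2*25)/5

  # empty stratum is flagged, not an error
  e <- category_breakdown(toy_dataset(), period = "after")
  expect_true(e$empty)
  expect_equal(e$n_total, 0)
  expect_true(all(is.na(e$percentages)))
  expect_error(bri(e), "undefined")
})

test_that("BRI anchors: all healthy is 0, all dead is 100", {
  expect_equal(bri(c(50, 0, 0, 0, 0, 0)), 0)
  expect_equal(bri(c(0, 0, 0, 0, 0, 7)), 100)
  expect_equal(bri(c(0, 0, 0, 0, 0, 1)), 100)  # single-colony stratum
})

test_that("BRI is bounded and monotone in colony severity", {
  set.seed(11)
  for (i in 1:50) {
    counts <- as.numeric(rmultinom(1, sample(5:200, 1), runif(6)))
    v <- bri(counts)
    expect_gte(v, 0); expect_lte(v, 100)
    # move one colony from a lower to a higher category
    from <- which(counts > 0)[1]
    if (from < 6) {
      up <- counts
      up[from] <- up[from] - 1; up[from + 1] <- up[from + 1] + 1
      expect_gte(bri(up), v)
    }
  }
})

test_that("site BRI pools genera and equals the count-weighted genus mean", {
  rec <- dplyr::bind_rows(
    counts_to_records(c(50, 0, 0, 0, 0, 0), "S", "st1", "during", genus = "A"),
    counts_to_records(c(0, 0, 0, 0, 0, 50), "S", "st1", "during", genus = "B"))
  d <- survey_dataset(rec)
  expect_equal(site_bri(d, "S", "during"), 50)

  d2 <- random_dataset(seed = 5)
  for (s in unique(d2$records$site)) {
    for (p in d2$design$periods) {
      g <- d2$records[d2$records$site == s & d2$records$period == p, ]
      if (nrow(g) == 0) next
      per_genus <- sapply(split(g, g$genus), function(x) {
        b <- category_breakdown(d2, site = s, period = p, genus = x$genus[1])
        c(bri = bri(b), n = b$n_total)
      })
      pooled <- sum(per_genus["bri", ] * per_genus["n", ]) /
        sum(per_genus["n", ])
      expect_equal(site_bri(d2, s, p), pooled, tolerance = 1e-10)
    }
  }
})

test_that("prevalence counts live bleaching only, dead stays in denominator", {
  expect_equal(prevalence(c(10, 5, 5, 0, 0, 0)), 50)
  expect_equal(prevalence(c(10, 0, 0, 0, 0, 0)), 0)
  expect_equal(prevalence(c(0, 0, 0, 0, 5, 5)), 50)
  expect_error(prevalence(c(0, 0, 0, 0, 0, 0)), "undefined")
})

test_that("prevalence, healthy share and dead share partition every stratum", {
  set.seed(21)
  for (i in 1:30) {
    counts <- as.numeric(rmultinom(1, sample(1:500, 1), runif(6)))
    if (sum(counts) == 0) next
    healthy <- 100 * counts[1] / sum(counts)
    expect_equal(prevalence(counts) + healthy + dead_share(counts), 100)
  }
})

test_that("density averages per-quadrat counts with designed-zeros", {
  # 20 quadrats of 1 m2 with 15 colonies each
  rec <- dplyr::bind_rows(lapply(1:20, function(q)
    tibble::tibble(site = "S", station = "st1", period = "during",
                   quadrat = sprintf("q%02d", q), genus = "Acropora",
                   category = "C1", count = 15L)))
  d <- survey_dataset(rec)
  res <- coral_density(d, period = "during", site = "S")
  expect_equal(res$density, 15)
  expect_equal(res$se, 0)

  # 2 quadrats with 10 and 20 colonies -> 15 +/- 5
  rec2 <- tibble::tibble(site = "S", station = "st1", period = "during",
                         quadrat = c("q1", "q2"), genus = "Acropora",
                         category = "C1", count = c(10L, 20L))
  d2 <- survey_dataset(rec2, design = survey_design(
    list(S = "st1"), quadrats_per_station = 2))
  res2 <- coral_density(d2, period = "during")
  expect_equal(res2$density, 15)
  expect_equal(res2$se, 5)

  # unrecorded quadrats count as zeros against the designed 20
  res3 <- coral_density(d2, period = "during",
                        surveyed_quadrats = 20)
  expect_equal(res3$density, 30 / 20)
  expect_error(coral_density(d2, period = "during", site = "Nowhere"),
               "no quadrats")
})

test_that("BSI weights genus BRI by percent relative abundance", {
  mk <- function(bri_a, n_a, bri_b, n_b, n_c = 0, bri_c = 100) {
    rec <- dplyr::bind_rows(
      counts_to_records(synthetic_category_counts(n_a, bri = bri_a),
                        "S", "st1", "during", genus = "Aa"),
      counts_to_records(synthetic_category_counts(n_b, bri = bri_b),
                        "S", "st1", "during", genus = "Bb"),
      if (n_c > 0)
        counts_to_records(synthetic_category_counts(n_c, bri = bri_c),
                          "S", "st1", "during", genus = "Cc"))
    survey_dataset(rec)
  }
  # two genera, no exclusions: BSI = (50*60 + 10*40)/2 = 1700
  r <- bsi(mk(50, 60, 10, 40), "S", "during")
  expect_equal(r$bsi, 1700)
  expect_equal(r$n_genera, 2)

  # a 3-colony genus is excluded but still dilutes relative abundance:
  # D_A = 60, D_B = 37 (percent of all 100 colonies). With integer severity
  # weights, BRI 10 at n = 37 is unattainable (steps of 20/37); the
  # construction lands on the nearest weighted sum S = 18, BRI = 360/37, so
  # by hand BSI = (50*60 + (360/37)*37)/2 = (3000 + 360)/2 = 1680
  r2 <- bsi(mk(50, 60, 10, 37, n_c = 3), "S", "during")
  expect_equal(r2$bsi, 1680)
  expect_equal(r2$n_genera, 2)

  # single qualifying all-healthy genus
  d3 <- survey_dataset(counts_to_records(c(30, 0, 0, 0, 0, 0), "S", "st1",
                                         "during", genus = "Aa"))
  expect_equal(bsi(d3, "S", "during")$bsi, 0)

  # min_n = 0, one genus at 100% abundance: BSI = BRI * 100 / 1
  d4 <- survey_dataset(counts_to_records(
    synthetic_category_counts(40, bri = 25), "S", "st1", "during",
    genus = "Aa"))
  expect_equal(bsi(d4, "S", "during", min_n = 0)$bsi, bri(
    category_breakdown(d4, site = "S", period = "during")) * 100)

  # no genus qualifying
  d5 <- survey_dataset(counts_to_records(c(2, 0, 0, 0, 0, 0), "S", "st1",
                                         "during", genus = "Aa"))
  expect_error(bsi(d5, "S", "during"), "minimum")
})

test_that("mortality change is the signed dead-share difference", {
  rec <- dplyr::bind_rows(
    counts_to_records(synthetic_category_counts(200, dead_pct = 5),
                      "S", "st1", "during"),
    counts_to_records(synthetic_category_counts(200, dead_pct = 8.5),
                      "S", "st1", "after"))
  d <- survey_dataset(rec)
  expect_equal(mortality_change(d), 3.5)
  # identical breakdowns give zero
  rec2 <- dplyr::bind_rows(
    counts_to_records(c(10, 2, 2, 0, 0, 1), "S", "st1", "during"),
    counts_to_records(c(10, 2, 2, 0, 0, 1), "S", "st1", "after"))
  expect_equal(mortality_change(survey_dataset(rec2)), 0)
  # antisymmetric under swapping the period order
  expect_equal(mortality_change(d, periods = c("after", "during")),
               -mortality_change(d))
  # missing period is a named error
  d3 <- survey_dataset(counts_to_records(c(10, 0, 0, 0, 0, 0), "S", "st1",
                                         "during"))
  expect_error(mortality_change(d3), "after")
})

test_that("summary tables cover every taxon-period and site-period cell", {
  d <- random_dataset(seed = 9)
  st <- summary_tables(d)
  n_genera <- length(unique(d$records$genus))
  n_sites <- length(unique(d$records$site))
  expect_equal(nrow(st$genus), n_genera * 2)
  expect_equal(nrow(st$site), n_sites * 2)
  expect_equal(sum(st$genus$n), total_colonies(d))
  expect_equal(sum(st$site$abundance), total_colonies(d))
  # ordered by total taxon abundance, descending
  totals <- tapply(st$genus$n, st$genus$genus, sum)[unique(st$genus$genus)]
  expect_true(all(diff(as.numeric(totals)) <= 0))

  # a taxon absent in one period carries n = 0 and a flagged (NA) BRI
  rec <- dplyr::bind_rows(
    counts_to_records(c(5, 0, 0, 0, 0, 0), "S", "st1", "during", genus = "Aa"),
    counts_to_records(c(5, 0, 0, 0, 0, 0), "S", "st1", "after", genus = "Bb"))
  st2 <- summary_tables(survey_dataset(rec))
  gone <- st2$genus[st2$genus$genus == "Aa" & st2$genus$period == "after", ]
  expect_equal(gone$n, 0L)
  expect_true(is.na(gone$bri))
})
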