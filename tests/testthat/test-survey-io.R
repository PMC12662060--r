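test_that("canonical long files parse into validated datasets", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(path, c(
    "Ambola,Manangatse,during,q1,Acropora,C1,4",
    "Ambola,Manangatse,during,q1,Acropora,C5,1",
    "Ambola,Manangatse,during,q1,Pocillopora,C3,2"
  ))
  d <- read_survey(path)
  expect_s3_class(d, "survey_dataset")
  expect_equal(nrow(d$records), 3)
  expect_equal(total_colonies(d), 7)
})

test_that("count column defaults to one row per colony", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,station,period,quadrat,genus,category",
               "Ambola,Manangatse,during,q1,Acropora,C1",
               "Ambola,Manangatse,during,q1,Acropora,C1"), path)
  d <- read_survey(path)
  expect_equal(total_colonies(d), 2)
  # duplicate keys aggregate into one record
  expect_equal(nrow(d$records), 1)
})

test_that("malformed files produce named errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,station,period,quadrat,category,count",
               "A,S,during,q1,C1,4"), path)
  expect_error(read_survey(path), "genus")

  path2 <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(path2, c("A,S,during,q1,Acropora,C1,4",
                         "A,S,during,q1,Acropora,C7,1"))
  expect_error(read_survey(path2), "C7.*2|record 2")

  path3 <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(path3, "A,S,during,q1,Acropora,C1,-3")
  expect_error(read_survey(path3), "negative")
})

test_that("category label normalisation is idempotent and tolerant", {
  x <- c("c1", "C5", "Dead", "3", "healthy")
  once <- normalize_category(x)
  expect_equal(once, c("C1", "C5", "C6", "C3", "C1"))
  expect_equal(normalize_category(once), once)
  expect_true(is.na(normalize_category("C9")))
})

test_that("genus normalisation trims, folds case, keeps growth forms distinct", {
  expect_equal(normalize_genus("  acropora "), "Acropora")
  expect_equal(normalize_genus("MASSIVE   PORITES"), "massive Porites")
  expect_false(normalize_genus("massive Porites") ==
                 normalize_genus("branching porites"))
})

test_that("write/read round-trips any generated dataset exactly", {
  for (seed in c(1, 7)) {
    d <- random_dataset(seed = seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_survey(d, path)
    d2 <- read_survey(path)
    expect_equal(as.data.frame(d2$records), as.data.frame(d$records))
  }
  # empty dataset: header-only file round-trips
  empty <- survey_dataset(toy_records()[0, ],
                          design = survey_design(list(Ambola = "Manangatse")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(empty, path)
  expect_length(readLines(path), 1)
  expect_equal(nrow(read_survey(path)$records), 0)
})

test_that("written file has header plus one line per record", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(toy_dataset(), path)
  expect_length(readLines(path), 4)
})

test_that("supplementary-wide dialect maps seasons and accepts both layouts", {
  # per-colony long layout with a Season column
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Sites,Station,Season,Quadrant,Genera,Category",
               "Ambola,Manangatse,March,1,Acropora,C1",
               "Ambola,Manangatse,August,1,Acropora,C2"), path)
  d <- read_survey(path, dialect = "supplementary-wide")
  expect_setequal(unique(d$records$period), c("during", "after"))

  # wide C1..C6 count columns
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Site,Station,Season,Quadrat,Genus,C1,C2,C3,C4,C5,C6",
               "Ambola,Manangatse,March,1,Acropora,4,0,0,0,1,0",
               "Ambola,Manangatse,March,1,Pocillopora,0,0,2,0,0,0"), path2)
  d2 <- read_survey(path2, dialect = "supplementary-wide")
  expect_equal(total_colonies(d2), 7)
  expect_equal(sort(unique(d2$records$category)), c("C1", "C3", "C5"))
})

test_that("a YAML column-mapping config drives the wide dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("reef,transect,when,plot,taxon,health",
               "Ambola,Manangatse,mars,1,Acropora,C1"), path)
  cfgpath <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("columns:", "  site: reef", "  station: transect",
               "  period: when", "  quadrat: plot", "  genus: taxon",
               "  category: health",
               "period_map:", "  mars: during"), cfgpath)
  d <- read_survey(path, dialect = "supplementary-wide", mapping = cfgpath)
  expect_equal(d$records$period, "during")
  expect_equal(total_colonies(d), 1)
})

test_that("aggregate_counts sums within strata and preserves the total", {
  d <- toy_dataset()
  agg <- aggregate_counts(d, by = c("period", "genus"))
  acro <- agg[agg$genus == "Acropora", ]
  expect_equal(sum(acro$count), 5)
  expect_equal(acro$count[acro$category == "C1"], 4)
  expect_equal(agg$count[agg$genus == "Pocillopora"], 2)

  # conservation across every legal grouping
  d2 <- random_dataset(seed = 3)
  groupings <- list("period", c("period", "site"), c("period", "genus"),
                    c("site", "station", "period", "quadrat", "genus"))
  for (by in groupings) {
    expect_equal(sum(aggregate_counts(d2, by = by)$count),
                 total_colonies(d2))
  }
  # grouping by all keys is the identity on aggregated records
  all_keys <- aggregate_counts(d2, by = c("site", "station", "period",
                                          "quadrat", "genus"))
  expect_equal(sum(all_keys$count), sum(d2$records$count))
  expect_equal(nrow(all_keys), nrow(d2$records))
})

test_that("aggregate_counts rejects empty or period-less groupings", {
  d <- toy_dataset()
  expect_error(aggregate_counts(d, by = character()), "non-empty")
  expect_error(aggregate_counts(d, by = "genus"), "period")
})

test_that("datasets validate stations and periods against the design", {
  design <- survey_design(list(Ambola = "Manangatse"))
  bad <- toy_records()
  bad$station <- "Nowhere"
  expect_error(survey_dataset(bad, design), "not in the design")
  bad2 <- toy_records()
  bad2$period <- "spring"
  expect_error(survey_dataset(bad2, design), "spring")
})

test_that("hydrocorals can be excluded from hard-coral totals", {
  rec <- toy_records()
  rec$genus[3] <- "Millepora"
  d <- survey_dataset(rec)
  expect_equal(total_colonies(d), 7)
  expect_equal(total_colonies(d, exclude_hydrocorals = TRUE), 5)
})
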