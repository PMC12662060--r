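#' Describe a quadrat survey design
#'
#' A design records which stations exist at which sites, how many quadrats
#' are deployed per station per period, and the quadrat area. The default
#' mirrors the common monitoring protocol of 20 haphazardly placed 1 m2
#' quadrats per station, re-deployed in each sampling period.
#'
#' @param stations A data frame with columns `site` and `station` (one row
#'   per station), or a named list/character giving stations per site.
#' @param quadrats_per_station Number of quadrats deployed per station per
#'   period (default 20).
#' @param quadrat_area_m2 Quadrat area in square metres (default 1).
#' @param periods Ordered pair of period labels; the first is the "during
#'   event" survey, the second the "after event" survey.
#' @return A `survey_design` object.
#' @export
survey_design <- function(stations,
                          quadrats_per_station = 20,
                          quadrat_area_m2 = 1,
                          periods = c("during", "after")) {
  if (is.list(stations) && !is.data.frame(stations)) {
    stations <- tibble::tibble(
      site = rep(names(stations), lengths(stations)),
      station = unlist(stations, use.names = FALSE)
    )
  }
  stations <- tibble::as_tibble(stations)
  if (!all(c("site", "station") %in% names(stations))) {
    stop("`stations` must have columns `site` and `station`", call. = FALSE)
  }
  if (!"quadrats" %in% names(stations)) stations$quadrats <- quadrats_per_station
  if (!"area_m2" %in% names(stations)) stations$area_m2 <- quadrat_area_m2
  if (any(stations$area_m2 <= 0)) stop("quadrat area must be > 0", call. = FALSE)
  if (any(stations$quadrats <= 0)) stop("quadrats per station must be > 0", call. = FALSE)
  if (length(periods) != 2) stop("`periods` must be an ordered pair", call. = FALSE)
  structure(
    list(stations = stations[, c("site", "station", "quadrats", "area_m2")],
         periods = as.character(periods)),
    class = "survey_design"
  )
}

#' @export
print.survey_design <- function(x, ...) {
  cat("<survey_design> ", length(unique(x$stations$site)), " sites, ",
      nrow(x$stations), " stations; periods: ",
      paste(x$periods, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Normalise taxon names
#'
#' Trims and collapses whitespace and applies a canonical case: all words
#' lower-case except the final (genus) word, which is capitalised. This keeps
#' growth-form qualifiers as distinct taxa ("massive Porites" vs "branching
#' Porites") while making matching case-insensitive.
#'
#' @param x Character vector of taxon names.
#' @return Canonicalised character vector.
#' @export
normalize_genus <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  vapply(x, function(s) {
    if (!nzchar(s)) return(s)
    w <- tolower(strsplit(s, " ", fixed = TRUE)[[1]])
    n <- length(w)
    substr(w[n], 1, 1) <- toupper(substr(w[n], 1, 1))
    paste(w, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# taxa that are calcareous hydrocorals, not scleractinians
hydrocoral_taxa <- function() "Millepora"

#' Assemble and validate a survey dataset
#'
#' Binds long-format colony records to a survey design and validates them.
#' Duplicate keys (site, station, period, quadrat, genus, category) are
#' aggregated by summing their counts, so a file recording one row per colony
#' and a file recording per-category counts yield the same dataset.
#'
#' @param records Data frame with columns `site`, `station`, `period`,
#'   `quadrat`, `genus`, `category` and optionally `count` (default 1 per
#'   row, i.e. one row per colony).
#' @param design A [survey_design()]; if `NULL`, a default design is inferred
#'   from the records (20 quadrats of 1 m2 per observed station).
#' @return A `survey_dataset` object: list with elements `records` (tibble)
#'   and `design`.
#' @export
survey_dataset <- function(records, design = NULL) {
  records <- tibble::as_tibble(records)
  required <- c("site", "station", "period", "quadrat", "genus", "category")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"count" %in% names(records)) records$count <- 1L

  cat_norm <- normalize_category(records$category)
  if (anyNA(cat_norm) && nrow(records)) {
    bad <- which(is.na(cat_norm))[1]
    stop(sprintf("unknown health category '%s' at record %d",
                 records$category[bad], bad), call. = FALSE)
  }
  records$category <- cat_norm
  if (any(is.na(records$count)) || any(records$count < 0)) {
    bad <- which(is.na(records$count) | records$count < 0)[1]
    stop(sprintf("negative or missing count at record %d", bad), call. = FALSE)
  }
  records$count <- as.integer(records$count)
  records$genus <- normalize_genus(records$genus)
  for (col in c("site", "station", "period", "quadrat")) {
    records[[col]] <- trimws(as.character(records[[col]]))
  }

  if (is.null(design)) {
    stations <- dplyr::distinct(records, .data$site, .data$station)
    periods <- unique(records$period)
    if (length(periods) == 0) periods <- c("during", "after")
    if (length(periods) == 1) periods <- c(periods, setdiff(c("during", "after"), periods)[1])
    if (length(periods) > 2) {
      stop("records contain more than two periods: ",
           paste(periods, collapse = ", "), call. = FALSE)
    }
    if (all(c("during", "after") %in% periods)) periods <- c("during", "after")
    design <- survey_design(stations, periods = periods)
  }
  stopifnot(inherits(design, "survey_design"))

  known <- paste(design$stations$site, design$stations$station, sep = "\r")
  seen <- paste(records$site, records$station, sep = "\r")
  if (nrow(records) && !all(seen %in% known)) {
    bad <- which(!(seen %in% known))[1]
    stop(sprintf("record %d refers to station '%s' at site '%s' not in the design",
                 bad, records$station[bad], records$site[bad]), call. = FALSE)
  }
  if (nrow(records) && !all(records$period %in% design$periods)) {
    bad <- which(!(records$period %in% design$periods))[1]
    stop(sprintf("record %d has period '%s'; design defines %s",
                 bad, records$period[bad],
                 paste(design$periods, collapse = ", ")), call. = FALSE)
  }

  records <- records |>
    dplyr::group_by(.data$site, .data$station, .data$period, .data$quadrat,
                    .data$genus, .data$category) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$site, .data$station, .data$period, .data$quadrat,
                   .data$genus, .data$category)

  structure(list(records = records, design = design), class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset> ", sum(x$records$count), " colonies in ",
      nrow(x$records), " records; ",
      length(unique(x$records$site)), " site(s), periods: ",
      paste(x$design$periods, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Total colony count of a dataset (optionally per period)
#' @param dataset A [survey_dataset()].
#' @param period Optional period label to restrict to.
#' @param exclude_hydrocorals Drop hydrocoral taxa (Millepora) from the total,
#'   restricting to scleractinian ("hard coral") colonies.
#' @return Integer colony count.
#' @export
total_colonies <- function(dataset, period = NULL, exclude_hydrocorals = FALSE) {
  rec <- dataset$records
  if (!is.null(period)) rec <- rec[rec$period == period, ]
  if (exclude_hydrocorals) rec <- rec[!(rec$genus %in% hydrocoral_taxa()), ]
  sum(rec$count)
}

#' Read a colony survey file
#'
#' Reads long-format colony records. Two dialects are supported:
#' `"canonical-long"` expects a header with columns `site, station, period,
#' quadrat, genus, category, count` (`count` may be absent, meaning one
#' colony per row); `"supplementary-wide"` accepts field-workbook layouts
#' with a `Season` column (month names mapped to during/after) and either a
#' per-colony `Category` column or six `C1..C6` count columns.
#'
#' @param path Path to a delimited text file (comma-separated, UTF-8).
#' @param dialect `"canonical-long"` (default) or `"supplementary-wide"`.
#' @param mapping Optional dialect configuration: a named list (or path to a
#'   YAML file) with elements `columns` (named character vector translating
#'   canonical names to file column names) and `period_map` (named character
#'   vector mapping season labels to period labels). Defaults cover the
#'   common workbook layout (`Season` with March -> during, August -> after).
#' @param design Optional [survey_design()] to validate against.
#' @return A validated [survey_dataset()].
#' @export
read_survey <- function(path,
                        dialect = c("canonical-long", "supplementary-wide"),
                        mapping = NULL, design = NULL) {
  dialect <- match.arg(dialect)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "canonical-long") {
    required <- c("site", "station", "period", "quadrat", "genus", "category")
    missing <- setdiff(required, names(raw))
    if (length(missing)) {
      stop("file is missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    return(survey_dataset(raw, design = design))
  }
  read_survey_wide(raw, mapping = mapping, design = design)
}

default_wide_mapping <- function() {
  list(
    columns = c(site = "site", station = "station", period = "season",
                quadrat = "quadrat", genus = "genus", category = "category",
                count = "count"),
    period_map = c(march = "during", august = "after",
                   during = "during", after = "after")
  )
}

# workbook-style adapter: case-insensitive column lookup, season translation,
# and either a long category column or wide C1..C6 count columns
read_survey_wide <- function(raw, mapping = NULL, design = NULL) {
  if (is.character(mapping)) mapping <- yaml::read_yaml(mapping)
  map <- default_wide_mapping()
  if (!is.null(mapping)) {
    if (!is.null(mapping$columns)) {
      map$columns[names(mapping$columns)] <- unlist(mapping$columns)
    }
    if (!is.null(mapping$period_map)) {
      pm <- unlist(mapping$period_map)
      names(pm) <- tolower(names(pm))
      map$period_map <- pm
    }
  }
  lower <- tolower(names(raw))
  find_col <- function(canonical, alternates = character()) {
    for (cand in c(map$columns[[canonical]], canonical, alternates)) {
      i <- match(tolower(cand), lower)
      if (!is.na(i)) return(names(raw)[i])
    }
    NA_character_
  }
  site_c <- find_col("site", "sites")
  station_c <- find_col("station", c("stations", "sampling station"))
  period_c <- find_col("period", c("season", "seasons", "sampling period"))
  quadrat_c <- find_col("quadrat", c("quadrant", "quadrats", "quadrants"))
  genus_c <- find_col("genus", c("genera", "taxa", "taxon"))
  need <- c(site = site_c, station = station_c, period = period_c,
            quadrat = quadrat_c, genus = genus_c)
  if (anyNA(need)) {
    stop("file is missing required column(s): ",
         paste(names(need)[is.na(need)], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    site = as.character(raw[[site_c]]),
    station = as.character(raw[[station_c]]),
    period = as.character(raw[[period_c]]),
    quadrat = as.character(raw[[quadrat_c]]),
    genus = as.character(raw[[genus_c]])
  )
  pm <- map$period_map
  key <- tolower(trimws(out$period))
  mapped <- unname(pm[key])
  if (anyNA(mapped)) {
    bad <- which(is.na(mapped))[1]
    stop(sprintf("unknown season/period label '%s' at row %d",
                 out$period[bad], bad), call. = FALSE)
  }
  out$period <- mapped

  cat_c <- find_col("category", c("bleaching category", "status", "bleaching status"))
  wide_cols <- names(raw)[lower %in% tolower(category_codes())]
  if (!is.na(cat_c)) {
    out$category <- as.character(raw[[cat_c]])
    count_c <- find_col("count", c("n", "abundance", "colonies"))
    out$count <- if (!is.na(count_c)) raw[[count_c]] else 1L
  } else if (length(wide_cols) == 6) {
    out <- dplyr::bind_cols(out, raw[wide_cols])
    names(out)[(ncol(out) - 5):ncol(out)] <- toupper(wide_cols)
    out <- tidyr::pivot_longer(out, cols = dplyr::all_of(toupper(wide_cols)),
                               names_to = "category", values_to = "count")
    out$count[is.na(out$count)] <- 0L
    out <- out[out$count > 0, ]
  } else {
    stop("file has neither a category column nor six C1..C6 count columns",
         call. = FALSE)
  }
  survey_dataset(out, design = design)
}

#' Write a survey dataset in the canonical long format
#'
#' Writes comma-separated UTF-8 text with header
#' `site,station,period,quadrat,genus,category,count`. Reading the file back
#' with [read_survey()] reproduces the dataset exactly.
#'
#' @param dataset A [survey_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(dataset, path) {
  stopifnot(inherits(dataset, "survey_dataset"))
  readr::write_csv(dataset$records, path, progress = FALSE)
  invisible(path)
}

#' Aggregate colony counts over a stratum
#'
#' Sums counts within the requested grouping keys and the health category.
#' The grand total is preserved for every grouping.
#'
#' @param dataset A [survey_dataset()].
#' @param by Grouping keys, a subset of
#'   `c("site", "station", "period", "quadrat", "genus")`; must include
#'   `"period"` so that the two survey passes are never pooled silently.
#' @return A tibble with the grouping columns, `category`, and `count`.
#' @export
aggregate_counts <- function(dataset, by = c("period", "genus")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  allowed <- c("site", "station", "period", "quadrat", "genus")
  if (length(by) == 0 || !all(by %in% allowed)) {
    stop("`by` must be a non-empty subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  if (!"period" %in% by) {
    stop("`by` must include \"period\"", call. = FALSE)
  }
  dataset$records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "category")))) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}
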