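#' Pipeline run configuration
#'
#' Bundles the inputs and analysis options for one end-to-end run. Exactly
#' one of `survey` (a file path or [survey_dataset()]) or `simulate` (a
#' [simulation_config()]) must be supplied.
#'
#' @param survey Path to a canonical-long survey file, or a
#'   [survey_dataset()].
#' @param simulate A [simulation_config()] to generate the survey instead.
#' @param sst Optional path to a daily SST file (see [read_sst()]), or an
#'   [sst_series()] / list of them.
#' @param out_dir Output directory for the report tables.
#' @param min_n Minimum genus count for the BSI (default 5).
#' @param window_days,hotspot_floor DHW accumulation options (defaults 84
#'   days, 1.0 degrees C).
#' @param bleaching_threshold,mortality_threshold DHW alert thresholds
#'   (defaults 4 and 8 degree C-weeks).
#' @param pairing_unit Pairing unit for the period comparison (`"station"`
#'   or `"site"`).
#' @param coverage Cumulative-abundance coverage for the main-genus
#'   grouping (default 0.80).
#' @param fixed_groups Optional explicit character vector of main genera.
#' @param seed Seed recorded in the run log (the simulation carries its own).
#' @return A `run_config` list.
#' @export
run_config <- function(survey = NULL, simulate = NULL, sst = NULL,
                       out_dir = tempfile("reefbleach-run-"),
                       min_n = 5, window_days = 84, hotspot_floor = 1.0,
                       bleaching_threshold = 4, mortality_threshold = 8,
                       pairing_unit = c("station", "site"),
                       coverage = 0.80, fixed_groups = NULL, seed = 1L) {
  if (is.null(survey) == is.null(simulate)) {
    stop("supply exactly one of `survey` or `simulate`", call. = FALSE)
  }
  structure(list(
    survey = survey, simulate = simulate, sst = sst, out_dir = out_dir,
    options = list(min_n = min_n, window_days = window_days,
                   hotspot_floor = hotspot_floor,
                   bleaching_threshold = bleaching_threshold,
                   mortality_threshold = mortality_threshold,
                   pairing_unit = match.arg(pairing_unit),
                   coverage = coverage, fixed_groups = fixed_groups),
    seed = as.integer(seed)
  ), class = "run_config")
}

# delimited table with '#'-prefixed audit header naming the options used
write_report_table <- function(df, path, option_lines) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", option_lines), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

option_header <- function(opts, keys) {
  vapply(keys, function(k) paste0(k, " = ",
                                  paste(format(opts[[k]]), collapse = ",")),
         character(1))
}

#' Run the full survey-analysis pipeline
#'
#' Executes every stage on one input: loads or simulates the survey, builds
#' the genus and site index tables, the period comparison table, and (when
#' SST input is given) the DHW table, and writes each as delimited text with
#' an audit header naming the option values used. Identical configuration
#' and seed produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the tables (`genus`, `site`, `comparison`,
#'   `dhw` or `NULL`), the `dataset`, and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  opts <- config$options
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  dataset <- stage("input", {
    if (!is.null(config$simulate)) simulate_survey(config$simulate)
    else if (inherits(config$survey, "survey_dataset")) config$survey
    else read_survey(config$survey)
  })

  tables <- stage("indices", summary_tables(dataset, min_n = opts$min_n))
  groups <- stage("grouping", main_genus_grouping(dataset,
                                                  coverage = opts$coverage,
                                                  fixed = opts$fixed_groups))
  comparison <- stage("compare", comparison_table(dataset, groups = groups,
                                                  unit = opts$pairing_unit))

  dhw <- NULL
  if (!is.null(config$sst)) {
    dhw <- stage("dhw", {
      sst <- config$sst
      if (is.character(sst)) sst <- read_sst(sst)
      if (inherits(sst, "sst_series")) sst <- list(sst)
      dplyr::bind_rows(lapply(sst, function(s) {
        clim <- monthly_climatology(s)
        dhw_series(s, clim, window_days = opts$window_days,
                   hotspot_floor = opts$hotspot_floor,
                   bleaching_threshold = opts$bleaching_threshold,
                   mortality_threshold = opts$mortality_threshold)
      }))
    })
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  fmt <- function(df) {
    df[] <- lapply(df, function(x) if (is.numeric(x) && !is.integer(x))
      round(x, 6) else x)
    df
  }
  hdr_idx <- option_header(opts, c("min_n"))
  paths$genus <- write_report_table(fmt(tables$genus),
                                    file.path(config$out_dir, "genus_table.csv"),
                                    hdr_idx)
  paths$site <- write_report_table(fmt(tables$site),
                                   file.path(config$out_dir, "site_table.csv"),
                                   hdr_idx)
  paths$comparison <- write_report_table(
    fmt(comparison), file.path(config$out_dir, "comparison_table.csv"),
    option_header(opts, c("pairing_unit", "coverage")))
  if (!is.null(dhw)) {
    paths$dhw <- write_report_table(
      fmt(dhw), file.path(config$out_dir, "dhw_table.csv"),
      option_header(opts, c("window_days", "hotspot_floor",
                            "bleaching_threshold", "mortality_threshold")))
  }
  log_lines <- c(
    paste0("reefbleach version: ", as.character(packageVersion("reefbleach"))),
    paste0("seed: ", config$seed),
    paste0("input: ", if (!is.null(config$simulate)) "simulated" else "file"),
    paste0("colonies: ", sum(dataset$records$count)),
    option_header(opts, setdiff(names(opts), "fixed_groups"))
  )
  paths$log <- file.path(config$out_dir, "run_log.txt")
  writeLines(log_lines, paths$log)

  invisible(list(genus = tables$genus, site = tables$site,
                 comparison = comparison, dhw = dhw,
                 dataset = dataset, paths = paths))
}
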