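panel_stratifiers <- c("national", "residence", "wealth", "education")

#' Read a long-format coverage panel
#'
#' Accepts the documented CSV dialect of health-equity coverage extracts:
#' UTF-8, mandatory header, columns `iso3`, `region`, `year`, `stratifier`,
#' `level`, `value`, `scale`, with `scale` in `{proportion, percent}`.
#' Percent values are divided by 100. Validation is itemised: unknown
#' stratifier labels, out-of-range values and duplicate
#' (country, year, stratifier, level) rows are all reported with row
#' numbers before the reader fails.
#'
#' @param path CSV file path.
#' @return Coverage-panel tibble with columns `country_id`, `region_id`,
#'   `year`, `stratum_type`, `stratum_level`, `cci` (proportion scale).
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("iso3", "region", "year", "stratifier", "level", "value", "scale")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("panel is missing column(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  problems <- character(0)
  bad_strat <- which(!raw$stratifier %in% panel_stratifiers)
  if (length(bad_strat) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unknown stratifier '%s'", bad_strat, raw$stratifier[bad_strat]
    ))
  }
  bad_scale <- which(!raw$scale %in% c("proportion", "percent"))
  if (length(bad_scale) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unknown scale '%s'", bad_scale, raw$scale[bad_scale]
    ))
  }
  hi <- ifelse(raw$scale == "percent", 100, 1)
  bad_val <- which(!is.finite(raw$value) | raw$value < 0 | raw$value > hi)
  if (length(bad_val) > 0) {
    problems <- c(problems, sprintf(
      "row %d: value %s outside [0, %s] for scale '%s'",
      bad_val, format(raw$value[bad_val]), format(hi[bad_val]), raw$scale[bad_val]
    ))
  }
  key <- paste(raw$iso3, raw$year, raw$stratifier, raw$level)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    problems <- c(problems, sprintf(
      "row %d: duplicate observation (%s)", dup, key[dup]
    ))
  }
  if (length(problems) > 0) {
    stop(paste0(
      sprintf("panel validation failed (%d problem(s)):\n", length(problems)),
      paste("  -", problems, collapse = "\n")
    ), call. = FALSE)
  }
  tibble::tibble(
    country_id = raw$iso3,
    region_id = raw$region,
    year = as.integer(raw$year),
    stratum_type = raw$stratifier,
    stratum_level = raw$level,
    cci = ifelse(raw$scale == "percent", raw$value / 100, raw$value)
  )
}

#' Read a country-year covariate table
#'
#' @param path CSV with columns `country_id`, `year` and covariate columns
#'   (`sdi`, `ggdph`, `gdpc`, optionally `dah`, `hrh`, ...).
#' @return Tibble.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("country_id", "year")
  missing <- setdiff(need, names(out))
  if (length(missing) > 0) {
    stop(sprintf(
      "covariate table is missing column(s): %s",
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  out$year <- as.integer(out$year)
  out
}
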